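test_that("network construction is deterministic given a seed", {
  spec <- micro_network_spec()
  a <- build_network(spec, seed = 4)
  b <- build_network(spec, seed = 4)
  expect_identical(a$params, b$params)
  c_ <- build_network(spec, seed = 5)
  expect_false(identical(a$params, c_$params))
})

test_that("forward passes produce the documented shapes", {
  net <- build_network(micro_network_spec(), seed = 1)
  set.seed(2)
  x <- array(rnorm(16 * 16 * 3 * 3), c(16, 16, 3, 3))
  fwd <- seiznet:::net_forward(net, x, training = FALSE)
  expect_equal(dim(fwd$logits), c(3L, 2L))
  expect_equal(dim(fwd$features), c(3L, 32L))
  expect_true(all(is.finite(fwd$logits)))
})

test_that("analytic gradients agree with finite differences through every block", {
  net <- build_network(micro_network_spec(), seed = 3)
  set.seed(7)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1L, 2L)
  loss_fn <- function(n) {
    fwd <- seiznet:::net_forward(n, x, training = TRUE, cache_on = FALSE)
    seiznet:::cross_entropy(fwd$logits, y)$loss
  }
  fwd <- seiznet:::net_forward(net, x, training = TRUE, cache_on = TRUE)
  ce <- seiznet:::cross_entropy(fwd$logits, y)
  grads <- seiznet:::net_backward(net, fwd, ce$dlogits)
  eps <- 1e-5
  set.seed(11)
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    for (i in sample(seq_along(p), min(3L, length(p)))) {
      np <- net; np$params[[nm]][i] <- p[i] + eps; lp <- loss_fn(np)
      nq <- net; nq$params[[nm]][i] <- p[i] - eps; lm <- loss_fn(nq)
      num <- (lp - lm) / (2 * eps)
      err <- abs(num - grads[[nm]][i]) /
        max(1e-6, abs(num), abs(grads[[nm]][i]))
      expect_lt(err, 1e-3, label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("batch-norm inference uses running statistics, not batch statistics", {
  net <- build_network(micro_network_spec(), seed = 6)
  set.seed(8)
  x <- array(rnorm(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  # inference output on a sub-batch must equal the sliced full-batch output
  full <- seiznet:::net_forward(net, x, training = FALSE)$logits
  one <- seiznet:::net_forward(net, x[, , , 1, drop = FALSE],
                               training = FALSE)$logits
  expect_equal(one, full[1, , drop = FALSE], tolerance = 1e-10)
})

test_that("depth features have the spec dimension and feed the softmax head", {
  net <- build_network(micro_network_spec(), seed = 2)
  b <- toy_batch(3, seed = 4)
  feats <- extract_depth_features(net, b)
  expect_equal(dim(feats), c(6L, 32L))
  # logits are an affine map of the depth features
  logits <- feats %*% net$params$fc_w +
    matrix(net$params$fc_b, 6, 2, byrow = TRUE)
  fwd <- seiznet:::net_forward(net, b$x, training = FALSE)
  expect_equal(logits, fwd$logits, tolerance = 1e-10)
})

test_that("a wrong input resolution is rejected with the expected size named", {
  net <- build_network(micro_network_spec(), seed = 2)
  x <- array(0, c(20, 20, 3, 1))
  err <- expect_error(seiznet:::check_resolution(net, x),
                      class = "seiznet_validation_error")
  expect_match(conditionMessage(err), "16x16")
})

test_that("weight archives round trip: loaded networks predict identically", {
  net <- build_network(micro_network_spec(), seed = 9)
  path <- tempfile(fileext = ".rds")
  save_network_weights(net, path)
  fresh <- build_network(micro_network_spec(), seed = 999)
  loaded <- load_pretrained(fresh, path)
  b <- toy_batch(2, seed = 5)
  expect_equal(seiznet:::net_forward(loaded, b$x, training = FALSE)$logits,
               seiznet:::net_forward(net, b$x, training = FALSE)$logits)
  report <- attr(loaded, "load_report")
  expect_setequal(report$loaded, names(net$params))
  expect_length(report$skipped, 0L)
})

test_that("a mismatched classifier head is reinitialized, not loaded", {
  net2 <- build_network(micro_network_spec(), seed = 1)
  path <- tempfile(fileext = ".rds")
  save_network_weights(net2, path)
  spec3 <- micro_network_spec()
  spec3$num_classes <- 3L
  net3 <- build_network(spec3, seed = 2)
  loaded <- load_pretrained(net3, path)
  report <- attr(loaded, "load_report")
  expect_setequal(report$reinitialized_head, c("fc_w", "fc_b"))
  # backbone transferred, head kept fresh
  expect_identical(loaded$params$stem_w, net2$params$stem_w)
  expect_identical(loaded$params$fc_w, net3$params$fc_w)
  expect_error(load_pretrained(net3, path, strict = TRUE),
               class = "seiznet_weight_error")
})

test_that("parameter counts match an independent shape-based tally", {
  spec <- micro_network_spec()
  net <- build_network(spec, seed = 1)
  expect_equal(count_parameters(spec),
               sum(vapply(net$params, length, 0L)))
})
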