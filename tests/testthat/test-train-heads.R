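test_that("training learns a separable toy problem and logs history", {
  net <- build_network(micro_network_spec(), seed = 2)
  tr <- toy_batch(16, seed = 1)
  va <- toy_batch(8, seed = 2)
  fit <- train_network(net, tr, va,
                       hyper = train_config(epochs = 6, batch_size = 8,
                                            patience = 6),
                       seed = 3)
  expect_s3_class(fit, "seiznet_fit")
  expect_s3_class(fit, "seiznet_network")
  h <- fit$history
  expect_equal(names(h), c("epoch", "train_loss", "val_acc"))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_gte(max(h$val_acc), 0.9)
  te <- toy_batch(8, seed = 9)
  expect_gte(mean(as.integer(predict(fit, te)) == te$y), 0.9)
})

test_that("training is deterministic given seeds", {
  tr <- toy_batch(8, seed = 1)
  va <- toy_batch(4, seed = 2)
  run <- function() {
    train_network(build_network(micro_network_spec(), seed = 2), tr, va,
                  hyper = train_config(epochs = 2, batch_size = 8),
                  seed = 5)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("early stopping restores the best-validation weights", {
  net <- build_network(micro_network_spec(), seed = 4)
  tr <- toy_batch(8, seed = 3)
  va <- toy_batch(4, seed = 4)
  fit <- train_network(net, tr, va,
                       hyper = train_config(epochs = 8, batch_size = 8,
                                            patience = 2),
                       seed = 6)
  best_epoch <- fit$history$epoch[which.max(fit$history$val_acc)]
  # stopped no later than best + patience
  expect_lte(nrow(fit$history), best_epoch + 2)
  # restored weights reproduce the best validation accuracy
  acc <- mean(as.integer(predict(fit, va)) == va$y)
  expect_equal(acc, max(fit$history$val_acc), tolerance = 1e-12)
})

test_that("an empty training set is rejected", {
  net <- build_network(micro_network_spec(), seed = 1)
  empty <- list(x = array(0, c(16, 16, 3, 0)), y = integer())
  expect_error(train_network(net, empty, toy_batch(2, 1)),
               class = "seiznet_validation_error")
})

test_that("knn with k = 1 returns the label of a matching training point", {
  set.seed(1)
  tr <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 5), 20))
  lab <- rep(c("nonseizure", "seizure"), each = 20)
  out <- classify_features(tr[c(1, 25), , drop = FALSE], "knn",
                           list(features = tr, labels = lab, k = 1))
  expect_equal(as.character(out$labels), c("nonseizure", "seizure"))
})

test_that("identical test rows receive identical predictions from every head", {
  set.seed(2)
  tr <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 4), 30))
  lab <- rep(c("nonseizure", "seizure"), each = 30)
  te <- tr[c(3, 3, 40, 40), , drop = FALSE]
  for (h in c("knn", "svm")) {
    out <- classify_features(te, h, list(features = tr, labels = lab, k = 3))
    expect_equal(out$labels[1], out$labels[2])
    expect_equal(out$labels[3], out$labels[4])
    expect_equal(out$scores[1, ], out$scores[2, ])
  }
})

test_that("an svm separates linearly separable features perfectly", {
  set.seed(3)
  tr <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 6), 50))
  lab <- rep(c("nonseizure", "seizure"), each = 50)
  out <- classify_features(tr, "svm", list(features = tr, labels = lab))
  expect_equal(mean(out$labels == lab), 1)
})

test_that("the softmax head reproduces the network's own probabilities", {
  net <- build_network(micro_network_spec(), seed = 7)
  b <- toy_batch(4, seed = 8)
  feats <- extract_depth_features(net, b)
  out <- classify_features(feats, "softmax", list(net = net))
  probs <- predict(net, b, type = "prob")
  expect_equal(out$scores, probs, tolerance = 1e-12)
  expect_equal(as.character(out$labels),
               as.character(predict(net, b, type = "class")))
})

test_that("head predictions are deterministic given seeds", {
  set.seed(4)
  tr <- matrix(rnorm(80), 40)
  lab <- rep(c("nonseizure", "seizure"), 20)
  te <- matrix(rnorm(20), 10)
  p <- list(features = tr, labels = lab, k = 3, seed = 5)
  a <- classify_features(te, "knn", p)
  b <- classify_features(te, "knn", p)
  expect_identical(a, b)
})

test_that("applying an unfit head is an error", {
  expect_error(classify_features(matrix(0, 1, 4), "svm"),
               class = "seiznet_validation_error")
  expect_error(classify_features(matrix(0, 1, 4), "softmax"),
               class = "seiznet_validation_error")
  expect_error(classify_features(matrix(0, 1, 4), "knn",
                                 list(features = matrix(0, 2, 4))),
               class = "seiznet_validation_error")
})
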