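# Training loop (Adam + cross-entropy with early stopping on validation
# accuracy), prediction, depth-feature extraction, and weight archives.

label_levels <- function() c("nonseizure", "seizure")

#' Assemble a batch array from network inputs
#'
#' Stacks a list of `net_input` objects (see [to_net_input()]) into the
#' `(H, W, 3, N)` array the network consumes, together with the integer
#' class vector (1 = nonseizure, 2 = seizure).
#'
#' @param inputs list of `net_input` objects with a common resolution.
#' @return a list with elements `x` (array) and `y` (integer vector).
#' @export
net_batch <- function(inputs) {
  stopifnot(length(inputs) >= 1L)
  rs <- vapply(inputs, function(i) i$R, 0L)
  if (length(unique(rs)) != 1L) {
    stop_seiznet("all inputs in a batch must share one resolution",
                 "seiznet_validation_error")
  }
  R <- rs[1L]
  x <- array(0, dim = c(R, R, 3L, length(inputs)))
  for (i in seq_along(inputs)) {
    x[, , , i] <- aperm(inputs[[i]]$tensor, c(2L, 3L, 1L))
  }
  y <- match(vapply(inputs, function(i) i$label %||% "nonseizure", ""),
             label_levels())
  list(x = x, y = y)
}

check_resolution <- function(net, x) {
  R <- net$spec$input_resolution
  if (dim(x)[1] != R || dim(x)[2] != R) {
    stop_seiznet(sprintf(
      "input resolution %dx%d does not match the network's expected %dx%d",
      dim(x)[1], dim(x)[2], R, R), "seiznet_validation_error")
  }
}

as_batch <- function(net, batch) {
  if (is.list(batch) && !is.null(batch$x)) return(batch)
  if (inherits(batch, "net_input")) batch <- list(batch)
  net_batch(batch)
}

#' Extract depth features
#'
#' Runs the network in inference mode and returns the pooled penultimate
#' representation (the layer feeding the classifier head), one row per
#' input, with `spec$feature_dim` columns.
#'
#' @param net a `seiznet_network`.
#' @param batch a list of `net_input` objects, a single `net_input`, or a
#'   batch from [net_batch()].
#' @return numeric matrix, `N x feature_dim`.
#' @export
extract_depth_features <- function(net, batch) {
  stopifnot(inherits(net, "seiznet_network"))
  b <- as_batch(net, batch)
  check_resolution(net, b$x)
  net_forward(net, b$x, training = FALSE)$features
}

#' Predict from a network
#'
#' @param object a `seiznet_network`.
#' @param newdata a list of `net_input` objects or a [net_batch()] result.
#' @param type `"class"` (default) for labels, `"prob"` for class
#'   probabilities, `"logit"` for raw logits, `"feature"` for depth
#'   features.
#' @param ... unused.
#' @return predictions in the requested form.
#' @export
predict.seiznet_network <- function(object, newdata,
                                    type = c("class", "prob", "logit",
                                             "feature"), ...) {
  type <- match.arg(type)
  b <- as_batch(object, newdata)
  check_resolution(object, b$x)
  fwd <- net_forward(object, b$x, training = FALSE)
  switch(type,
    class = factor(label_levels()[max.col(fwd$logits, ties.method = "first")],
                   levels = label_levels()),
    prob = {
      p <- softmax_rows(fwd$logits); colnames(p) <- label_levels(); p
    },
    logit = fwd$logits,
    feature = fwd$features)
}

#' Training configuration
#'
#' @param epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience in epochs without validation
#'   accuracy improvement.
#' @param weight_decay L2 penalty applied to convolution and dense
#'   weights (not to batch-norm parameters or biases).
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 32L, lr = 1e-3,
                         patience = 10L, weight_decay = 0) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience),
                 weight_decay = weight_decay), class = "train_config")
}

decayed <- function(name) {
  grepl("_w$", name) && !grepl("_bn_", name)
}

#' Train a network
#'
#' Minimizes softmax cross-entropy with the Adam optimizer, shuffling the
#' training set each epoch, and keeps the weights (and batch-norm running
#' statistics) of the epoch with the best validation accuracy — the
#' latest such epoch when several tie, since a saturated validation
#' accuracy can no longer discriminate between epochs; stops early after
#' `hyper$patience` epochs without strict improvement. Fully
#' deterministic given `seed`.
#'
#' @param net an untrained (or pretrained) `seiznet_network`.
#' @param train_set,val_set lists of labeled `net_input` objects (or
#'   [net_batch()] results).
#' @param hyper a [train_config()].
#' @param seed integer seed governing shuffling.
#' @param verbose print per-epoch progress.
#' @return the trained network (class `c("seiznet_fit", "seiznet_network")`)
#'   with a `history` data frame (epoch, train_loss, val_acc).
#' @export
train_network <- function(net, train_set, val_set, hyper = train_config(),
                          seed = 1L, verbose = FALSE) {
  stopifnot(inherits(net, "seiznet_network"))
  tr <- as_batch(net, train_set)
  va <- as_batch(net, val_set)
  if (length(tr$y) == 0L) {
    stop_seiznet("empty training set", "seiznet_validation_error")
  }
  check_resolution(net, tr$x)
  n <- length(tr$y)
  bs <- min(hyper$batch_size, n)

  m_state <- lapply(net$params, function(p) p * 0)
  v_state <- lapply(net$params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_acc = numeric())
  best <- list(acc = -Inf, params = net$params, stats = net$bn_stats)
  stall <- 0L

  order_rng <- mix_seed(seed, 11L)
  for (epoch in seq_len(hyper$epochs)) {
    perm <- with_seed(mix_seed(order_rng, epoch), sample.int(n))
    epoch_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      xb <- tr$x[, , , idx, drop = FALSE]
      yb <- tr$y[idx]
      fwd <- net_forward(net, xb, training = TRUE, cache_on = TRUE)
      net$bn_stats <- fwd$bn_stats
      ce <- cross_entropy(fwd$logits, yb)
      epoch_loss <- epoch_loss + ce$loss; n_batches <- n_batches + 1L
      grads <- net_backward(net, fwd, ce$dlogits)
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(net$params)) {
        g <- grads[[nm]]
        if (is.null(g)) next
        if (hyper$weight_decay > 0 && decayed(nm)) {
          g <- g + hyper$weight_decay * net$params[[nm]]
        }
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
        net$params[[nm]] <- net$params[[nm]] -
          hyper$lr * (m_state[[nm]] / bc1) / (sqrt(v_state[[nm]] / bc2) + eps)
      }
    }
    val_logits <- net_forward(net, va$x, training = FALSE)$logits
    val_acc <- mean(max.col(val_logits, ties.method = "first") == va$y)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n_batches, val_acc = val_acc))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, val acc %.3f", epoch,
                      epoch_loss / n_batches, val_acc))
    }
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, params = net$params, stats = net$bn_stats)
      stall <- 0L
    } else {
      if (val_acc >= best$acc - 1e-12) {
        # a tie refreshes the snapshot: once validation accuracy
        # saturates it can no longer discriminate between epochs, and
        # the later epoch has trained longer at no measured cost
        best <- list(acc = best$acc, params = net$params,
                     stats = net$bn_stats)
      }
      stall <- stall + 1L
      if (stall >= hyper$patience) break
    }
  }
  net$params <- best$params
  net$bn_stats <- best$stats
  net$history <- history
  class(net) <- unique(c("seiznet_fit", class(net)))
  net
}

#' @export
summary.seiznet_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("Trained network (%d epochs run)\n", nrow(h)))
  cat(sprintf("  final train loss: %.4f\n", h$train_loss[nrow(h)]))
  cat(sprintf("  best val accuracy: %.2f%% (epoch %d)\n",
              100 * max(h$val_acc), h$epoch[which.max(h$val_acc)]))
  invisible(object)
}

#' @export
plot.seiznet_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_acc, type = "b", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

# ---- weight archives -----------------------------------------------------

#' Save network weights
#'
#' Writes a named-parameter archive (weights, batch-norm statistics, and
#' an architecture fingerprint) that [load_pretrained()] can map onto a
#' compatible network.
#'
#' @param net a `seiznet_network`.
#' @param path output path (RDS container).
#' @return `path`, invisibly.
#' @export
save_network_weights <- function(net, path) {
  stopifnot(inherits(net, "seiznet_network"))
  saveRDS(list(params = net$params, bn_stats = net$bn_stats,
               feature_dim = net$spec$feature_dim,
               num_classes = net$spec$num_classes), path)
  invisible(path)
}

#' Load pretrained weights into a network
#'
#' Copies every archived parameter whose name and shape match onto the
#' network; the classifier head (`fc_w`, `fc_b`) is allowed to mismatch
#' (e.g. a 1000-class pretrained head) and is then left at its fresh
#' initialization for the network's own class count. With
#' `strict = TRUE`, any mismatch or missing parameter is an error listing
#' the offending names.
#'
#' @param net a `seiznet_network`.
#' @param weights a path to an archive from [save_network_weights()], or
#'   the archive list itself.
#' @param strict require every parameter to match in name and shape.
#' @return the network with weights loaded; the load report (elements
#'   `loaded`, `skipped`, `reinitialized_head`) is attached as attribute
#'   `"load_report"`.
#' @export
load_pretrained <- function(net, weights, strict = FALSE) {
  stopifnot(inherits(net, "seiznet_network"))
  if (is.character(weights)) weights <- readRDS(weights)
  archive <- weights$params %||% weights
  head_names <- c("fc_w", "fc_b")
  loaded <- character(); skipped <- character()
  dims_of <- function(p) if (is.null(dim(p))) length(p) else dim(p)
  for (nm in names(net$params)) {
    ap <- archive[[nm]]
    if (!is.null(ap) && identical(as.integer(dims_of(ap)),
                                  as.integer(dims_of(net$params[[nm]])))) {
      net$params[[nm]] <- ap
      loaded <- c(loaded, nm)
    } else {
      skipped <- c(skipped, nm)
    }
  }
  extra <- setdiff(names(archive), names(net$params))
  skipped <- c(skipped, extra)
  if (!is.null(weights$bn_stats)) {
    for (nm in names(net$bn_stats)) {
      sp <- weights$bn_stats[[nm]]
      if (!is.null(sp) && length(sp) == length(net$bn_stats[[nm]])) {
        net$bn_stats[[nm]] <- sp
      }
    }
  }
  offenders <- setdiff(skipped, character(0))
  if (strict && length(offenders) > 0L) {
    stop_seiznet(paste0("strict weight loading failed; mismatched parameters: ",
                        paste(sort(offenders), collapse = ", ")),
                 "seiznet_weight_error")
  }
  attr(net, "load_report") <- list(
    loaded = loaded, skipped = skipped,
    reinitialized_head = intersect(skipped, head_names))
  net
}
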