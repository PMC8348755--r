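# Classifier heads operating on depth features: the network's own
# softmax layer, k-nearest-neighbours, and a support vector machine.

#' Fit a classifier head on depth features
#'
#' The `"softmax"` head is the network's own dense classification layer
#' and therefore needs the (trained) network rather than training
#' features. The `"knn"` and `"svm"` heads are fit on training depth
#' features (rows from [extract_depth_features()]) with one label per
#' row, and are deterministic given `seed`.
#'
#' @param head one of `"softmax"`, `"knn"`, `"svm"`.
#' @param features training feature matrix (knn/svm heads).
#' @param labels training labels, `"nonseizure"`/`"seizure"`, one per
#'   feature row (knn/svm heads).
#' @param net a `seiznet_network` (softmax head).
#' @param k neighbourhood size for knn.
#' @param seed integer seed (knn tie-breaking).
#' @param ... further arguments passed to [e1071::svm()] for the svm head.
#' @return an object of class `seiznet_head`.
#' @export
fit_head <- function(head = c("softmax", "knn", "svm"), features = NULL,
                     labels = NULL, net = NULL, k = 5L, seed = 1L, ...) {
  head <- match.arg(head)
  if (head == "softmax") {
    if (!inherits(net, "seiznet_network")) {
      stop_seiznet("the softmax head is the network's own classifier; supply a trained network via `net`",
                   "seiznet_validation_error")
    }
    return(structure(list(head = head, net = net), class = "seiznet_head"))
  }
  if (is.null(features) || is.null(labels)) {
    stop_seiznet(sprintf("the %s head must be fit on training features and labels",
                         head), "seiznet_validation_error")
  }
  features <- as.matrix(features)
  labels <- factor(as.character(labels), levels = label_levels())
  if (nrow(features) != length(labels) || anyNA(labels)) {
    stop_seiznet("need one nonseizure/seizure label per training feature row",
                 "seiznet_validation_error")
  }
  fitted <- switch(head,
    knn = list(train = features, cl = labels, k = as.integer(k),
               seed = as.integer(seed)),
    svm = list(model = e1071::svm(x = features, y = labels, scale = FALSE,
                                  ...)))
  structure(c(list(head = head), fitted), class = "seiznet_head")
}

#' @export
print.seiznet_head <- function(x, ...) {
  extra <- switch(x$head,
    softmax = sprintf(" (feature dim %d)", x$net$spec$feature_dim),
    knn = sprintf(" (k = %d, %d stored rows)", x$k, nrow(x$train)),
    svm = sprintf(" (%d support vectors)", nrow(x$model$SV)))
  cat(sprintf("seiznet %s head%s\n", x$head, extra))
  invisible(x)
}

#' @export
predict.seiznet_head <- function(object, newdata, ...) {
  classify_features(newdata, object)
}

#' Classify depth features with a head
#'
#' Applies a fitted classifier head to a matrix of depth features.
#' `head` may be a fitted `seiznet_head` (from [fit_head()]), or a head
#' name, in which case `head_params` must hold the fitting material
#' (`net` for softmax; `features`/`labels`, optionally `k`, for knn and
#' svm) — an unfit head is an error.
#'
#' @param features numeric matrix, one row per case, columns as produced
#'   by [extract_depth_features()].
#' @param head a `seiznet_head` or one of `"softmax"`, `"knn"`, `"svm"`.
#' @param head_params list of fitting material when `head` is a name.
#' @return a list with `labels` (factor, levels nonseizure/seizure) and
#'   `scores` (matrix, one column per class; softmax probabilities,
#'   knn neighbour fractions, or svm decision-value logits mapped through
#'   the logistic function).
#' @export
classify_features <- function(features, head, head_params = list()) {
  if (is.character(head)) {
    head <- do.call(fit_head, c(list(head = head), head_params))
  }
  if (!inherits(head, "seiznet_head")) {
    stop_seiznet("`head` must be a seiznet_head or a head name with fitting material",
                 "seiznet_validation_error")
  }
  features <- as.matrix(features)
  lv <- label_levels()
  scores <- switch(head$head,
    softmax = {
      net <- head$net
      if (ncol(features) != net$spec$feature_dim) {
        stop_seiznet(sprintf(
          "feature dimension %d does not match the network's %d",
          ncol(features), net$spec$feature_dim), "seiznet_validation_error")
      }
      logits <- features %*% net$params$fc_w +
        matrix(net$params$fc_b, nrow(features), length(net$params$fc_b),
               byrow = TRUE)
      softmax_rows(logits)
    },
    knn = {
      if (ncol(features) != ncol(head$train)) {
        stop_seiznet("feature dimension does not match the fitted knn head",
                     "seiznet_validation_error")
      }
      pred <- with_seed(head$seed,
                        class::knn(head$train, features, head$cl,
                                   k = head$k, prob = TRUE))
      frac <- attr(pred, "prob")   # fraction of votes for the winning class
      s <- matrix(0, length(pred), 2L)
      win <- as.integer(pred)
      s[cbind(seq_along(pred), win)] <- frac
      s[cbind(seq_along(pred), 3L - win)] <- 1 - frac
      s
    },
    svm = {
      dv <- attr(stats::predict(head$model, features, decision.values = TRUE),
                 "decision.values")
      # positive decision values favour the first class in the column
      # name; orient so positive favours the seizure class
      d <- as.numeric(dv[, 1L])
      if (startsWith(colnames(dv)[1L], "nonseizure")) d <- -d
      cbind(stats::plogis(-d), stats::plogis(d))
    })
  colnames(scores) <- lv
  labels <- factor(lv[max.col(scores, ties.method = "first")], levels = lv)
  list(labels = labels, scores = scores)
}
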