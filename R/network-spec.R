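# Architecture of the compound-scalable classification network: the
# baseline stage table, the per-level scaling coefficients, and the
# rounding rules that map coefficients onto concrete channel counts and
# layer repeats.

#' One stage of the convolutional backbone
#'
#' @param operator `"plain_conv"` (a plain convolution), `"mbconv"` (a
#'   mobile inverted bottleneck block), or `"head"` (the final 1x1
#'   convolution + global pooling + fully-connected classifier).
#' @param expansion MBConv expansion factor (1 or 6); ignored otherwise.
#' @param kernel square kernel size (3 or 5).
#' @param in_resolution input spatial resolution of the stage, pixels.
#' @param out_channels output channel count.
#' @param layers number of block repeats in the stage.
#' @param stride_first stride of the stage's first block (1 or 2);
#'   subsequent repeats always use stride 1.
#' @return an object of class `stage_spec`.
#' @export
stage_spec <- function(operator = c("plain_conv", "mbconv", "head"),
                       expansion = 1L, kernel = 3L, in_resolution = 224L,
                       out_channels, layers = 1L, stride_first = 1L) {
  operator <- match.arg(operator)
  stopifnot(expansion %in% c(1L, 6L), kernel %in% c(1L, 3L, 5L),
            layers >= 1L, stride_first %in% c(1L, 2L), out_channels >= 1L)
  structure(list(operator = operator, expansion = as.integer(expansion),
                 kernel = as.integer(kernel),
                 in_resolution = as.integer(in_resolution),
                 out_channels = as.integer(out_channels),
                 layers = as.integer(layers),
                 stride_first = as.integer(stride_first)),
            class = "stage_spec")
}

#' Baseline network stage table
#'
#' The nine stages of the level-0 (baseline) network: a 3x3 stem
#' convolution, seven MBConv stages with channels
#' (16, 24, 40, 80, 112, 192, 320) and repeats (1, 2, 2, 3, 3, 4, 1), and
#' a head stage (1x1 convolution to 1280 channels, global pooling,
#' fully-connected classifier). Strides follow the stage resolution
#' column: a stage's first block has stride 2 exactly where the next
#' stage's input resolution halves.
#'
#' @return a list of nine [stage_spec()] objects.
#' @export
baseline_spec <- function() {
  list(
    stage_spec("plain_conv", kernel = 3L, in_resolution = 224L,
               out_channels = 32L, layers = 1L, stride_first = 2L),
    stage_spec("mbconv", expansion = 1L, kernel = 3L, in_resolution = 112L,
               out_channels = 16L, layers = 1L, stride_first = 1L),
    stage_spec("mbconv", expansion = 6L, kernel = 3L, in_resolution = 112L,
               out_channels = 24L, layers = 2L, stride_first = 2L),
    stage_spec("mbconv", expansion = 6L, kernel = 5L, in_resolution = 56L,
               out_channels = 40L, layers = 2L, stride_first = 2L),
    stage_spec("mbconv", expansion = 6L, kernel = 3L, in_resolution = 28L,
               out_channels = 80L, layers = 3L, stride_first = 2L),
    stage_spec("mbconv", expansion = 6L, kernel = 5L, in_resolution = 14L,
               out_channels = 112L, layers = 3L, stride_first = 1L),
    stage_spec("mbconv", expansion = 6L, kernel = 5L, in_resolution = 14L,
               out_channels = 192L, layers = 4L, stride_first = 2L),
    stage_spec("mbconv", expansion = 6L, kernel = 3L, in_resolution = 7L,
               out_channels = 320L, layers = 1L, stride_first = 1L),
    stage_spec("head", kernel = 1L, in_resolution = 7L,
               out_channels = 1280L, layers = 1L, stride_first = 1L)
  )
}

#' The compound-scaling coefficient table
#'
#' One row per scaling level 0-7: input resolution, width coefficient,
#' and depth coefficient.
#'
#' @return a data frame with columns `level`, `input_resolution`,
#'   `width_coefficient`, `depth_coefficient`.
#' @export
scaling_table <- function() {
  data.frame(
    level = 0:7,
    input_resolution = c(224L, 240L, 260L, 300L, 380L, 456L, 528L, 600L),
    width_coefficient = c(1.0, 1.0, 1.1, 1.2, 1.4, 1.6, 1.8, 2.0),
    depth_coefficient = c(1.0, 1.1, 1.2, 1.4, 1.8, 2.2, 2.6, 3.1)
  )
}

#' Compound-scaling configuration
#'
#' Returns the input resolution and width/depth coefficients for scaling
#' level 0-7 (levels 1-7 grow the baseline), or a user-supplied
#' combination when `input_resolution`, `width_coefficient` and
#' `depth_coefficient` are given explicitly.
#'
#' @param level integer 0..7 selecting a tabulated configuration.
#' @param input_resolution,width_coefficient,depth_coefficient optional
#'   explicit values overriding the table; coefficients must be `>= 1`.
#' @return an object of class `scaling_config`.
#' @export
scaling_config <- function(level = 0L, input_resolution = NULL,
                           width_coefficient = NULL,
                           depth_coefficient = NULL) {
  tab <- scaling_table()
  if (!level %in% tab$level) {
    stop_seiznet("level must be an integer in 0..7", "seiznet_validation_error")
  }
  row <- tab[tab$level == level, ]
  cfg <- list(
    level = as.integer(level),
    input_resolution = as.integer(input_resolution %||% row$input_resolution),
    width_coefficient = width_coefficient %||% row$width_coefficient,
    depth_coefficient = depth_coefficient %||% row$depth_coefficient
  )
  if (cfg$width_coefficient < 1 || cfg$depth_coefficient < 1) {
    stop_seiznet("width and depth coefficients must be >= 1",
                 "seiznet_validation_error")
  }
  structure(cfg, class = "scaling_config")
}

#' Channel-count rounding under width scaling
#'
#' Multiplies a channel count by the width coefficient and rounds to the
#' nearest multiple of `divisor` (never below `divisor`), bumping up one
#' step if rounding fell below 90% of the unrounded value. This is the
#' canonical compound-scaling convention; it is idempotent at
#' `width_coefficient = 1` on already-rounded counts.
#'
#' @param channels baseline channel count.
#' @param width_coefficient width multiplier, `>= 1` in scaled networks.
#' @param divisor rounding granularity, default 8.
#' @return the scaled, rounded channel count (integer).
#' @export
round_filters <- function(channels, width_coefficient = 1, divisor = 8L) {
  v <- channels * width_coefficient
  new <- max(divisor, as.integer(v + divisor / 2) %/% divisor * divisor)
  if (new < 0.9 * v) new <- new + divisor
  as.integer(new)
}

#' Layer-repeat rounding under depth scaling
#' @param layers baseline repeat count.
#' @param depth_coefficient depth multiplier.
#' @return `ceiling(layers * depth_coefficient)` as integer.
#' @export
round_repeats <- function(layers, depth_coefficient = 1) {
  as.integer(ceiling(layers * depth_coefficient))
}

#' Scale the baseline stage table to a network specification
#'
#' Applies compound scaling: every stage's channel count is
#' `round_filters(out_channels * width_coefficient)`; MBConv stage repeats
#' become `ceiling(layers * depth_coefficient)` (the single-layer stem and
#' head are not depth-scaled); all stage input resolutions are rederived
#' from `cfg$input_resolution`. The depth-feature dimension is
#' `round_filters(1280 * width_coefficient)`.
#'
#' @param baseline a list of [stage_spec()], usually [baseline_spec()].
#' @param cfg a [scaling_config()].
#' @param num_classes number of output classes, default 2.
#' @return an object of class `network_spec` with fields `stages`,
#'   `feature_dim`, `num_classes`, `input_resolution`, `level`.
#' @export
scale_spec <- function(baseline = baseline_spec(), cfg = scaling_config(0L),
                       num_classes = 2L) {
  stopifnot(inherits(cfg, "scaling_config"))
  res <- cfg$input_resolution
  stages <- vector("list", length(baseline))
  for (i in seq_along(baseline)) {
    st <- baseline[[i]]
    layers <- if (st$operator == "mbconv") {
      round_repeats(st$layers, cfg$depth_coefficient)
    } else {
      st$layers
    }
    stages[[i]] <- stage_spec(
      st$operator, expansion = st$expansion, kernel = st$kernel,
      in_resolution = res,
      out_channels = round_filters(st$out_channels, cfg$width_coefficient),
      layers = layers, stride_first = st$stride_first)
    res <- as.integer(ceiling(res / st$stride_first))
  }
  structure(list(
    stages = stages,
    feature_dim = round_filters(1280L, cfg$width_coefficient),
    num_classes = as.integer(num_classes),
    input_resolution = cfg$input_resolution,
    level = cfg$level,
    width_coefficient = cfg$width_coefficient,
    depth_coefficient = cfg$depth_coefficient
  ), class = "network_spec")
}

#' Desk-scale network preset
#'
#' A deliberately small configuration (resolution 64, width coefficient
#' 0.35, depth coefficient 0.5, with the usual ceiling rule on repeats) so
#' that end-to-end training runs on one CPU in minutes. Not one of the
#' tabulated scaling levels; intended for tests and demonstrations only.
#'
#' @param num_classes number of output classes.
#' @return a `network_spec`.
#' @export
tiny_network_spec <- function(num_classes = 2L) {
  base <- baseline_spec()
  res <- 64L
  stages <- vector("list", length(base))
  for (i in seq_along(base)) {
    st <- base[[i]]
    layers <- if (st$operator == "mbconv") {
      round_repeats(st$layers, 0.5)
    } else {
      st$layers
    }
    stages[[i]] <- stage_spec(
      st$operator, expansion = st$expansion, kernel = st$kernel,
      in_resolution = res,
      out_channels = round_filters(st$out_channels, 0.35),
      layers = layers, stride_first = st$stride_first)
    res <- as.integer(ceiling(res / st$stride_first))
  }
  structure(list(
    stages = stages,
    feature_dim = round_filters(1280L, 0.35),
    num_classes = as.integer(num_classes),
    input_resolution = 64L,
    level = NA_integer_,
    width_coefficient = 0.35, depth_coefficient = 0.5
  ), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  lvl <- if (is.na(x$level)) "tiny preset" else paste0("level ", x$level)
  cat(sprintf("<network_spec> %s: input %dx%d, feature dim %d, %d classes\n",
              lvl, x$input_resolution, x$input_resolution, x$feature_dim,
              x$num_classes))
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    op <- switch(st$operator,
                 plain_conv = sprintf("Conv%dx%d", st$kernel, st$kernel),
                 mbconv = sprintf("MBConv%d, k%dx%d", st$expansion,
                                  st$kernel, st$kernel),
                 head = "Conv1x1 + pool + FC")
    cat(sprintf("  stage %d: %-16s in %3dx%-3d ch %4d x%d layer(s), stride %d\n",
                i, op, st$in_resolution, st$in_resolution, st$out_channels,
                st$layers, st$stride_first))
  }
  invisible(x)
}

#' Spatial resolution after each stage
#' @param spec a `network_spec`.
#' @return integer vector, the output resolution of stages 1..8 (the head
#'   preserves resolution before pooling).
#' @export
stage_resolutions <- function(spec) {
  res <- spec$input_resolution
  out <- integer(0)
  for (st in spec$stages) {
    res <- as.integer(ceiling(res / st$stride_first))
    out <- c(out, res)
  }
  out[-length(out)]  # head stage does not change resolution
}
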