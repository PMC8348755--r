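# 2D representation: render feature maps as 3-channel raster images,
# optionally augment by flips/rotations, and convert to normalized network
# input tensors.

# Fixed perceptually-uniform colormap (256-entry viridis ramp from
# grDevices); luminance increases monotonically along the ramp, so value
# rank order in a feature map is preserved in image luminance.
seiznet_colormap <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cols <- grDevices::hcl.colors(256L, "viridis")
      cache <<- t(grDevices::col2rgb(cols))  # 256 x 3, 0..255
    }
    cache
  }
})

new_representation_image <- function(pixels, source_axes = NULL,
                                     label = "nonseizure") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(list(pixels = pixels, source_axes = source_axes, label = label),
            class = "representation_image")
}

#' @export
print.representation_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<representation_image> %d x %d x 3, label=%s\n",
              d[1], d[2], x$label))
  invisible(x)
}

# Map a matrix of level indices (1-based) into an H x W x 3 RGB array.
apply_colormap <- function(idx) {
  cm <- seiznet_colormap()
  array(cm[idx, ], dim = c(dim(idx), 3L))
}

#' Render a scalogram feature map as a filled-contour image
#'
#' Draws the filled-contour representation of a scale x time feature map:
#' time on the horizontal axis, scale (a frequency proxy) on the vertical
#' axis with scale 1 at the bottom, no axes or margins. The field is
#' resampled bilinearly to `out_res` x `out_res` and quantized into
#' `levels` equally spaced bands between the per-map minimum and maximum,
#' each band filled with one colormap entry. Because the bands are
#' computed from the map's own min/max, the rendering is invariant under
#' positive affine transforms of the values, and a constant map renders as
#' a uniform image. Fully deterministic.
#'
#' @param fm a [feature_map()] with `row_axis == "scale"`.
#' @param out_res output resolution in pixels (square), default 224.
#' @param levels number of filled contour bands, default 10.
#' @param label class label carried to the image.
#' @return a [new_representation_image()] of shape
#'   `out_res x out_res x 3`.
#' @export
render_scalogram_image <- function(fm, out_res = 224L, levels = 10L,
                                   label = "nonseizure") {
  stopifnot(inherits(fm, "feature_map"))
  if (fm$row_axis != "scale") {
    stop_seiznet("render_scalogram_image expects a scale x time feature map",
                 "seiznet_validation_error")
  }
  stopifnot(out_res >= 1L, levels >= 1L)
  # scale 1 (row 1) at the bottom of the image
  field <- fm$values[rev(seq_len(nrow(fm$values))), , drop = FALSE]
  grid <- resize_bilinear_matrix(field, out_res, out_res)
  mn <- min(fm$values); mx <- max(fm$values)
  if (mx - mn <= 0) {
    idx <- matrix(1L, out_res, out_res)
  } else {
    band <- floor((grid - mn) / (mx - mn) * levels)
    band[band >= levels] <- levels - 1L          # top edge joins last band
    idx <- matrix(as.integer(band / max(1L, (levels - 1L)) * 255L) + 1L,
                  out_res, out_res)
  }
  new_representation_image(apply_colormap(idx),
                           source_axes = fm[c("row_axis", "col_axis",
                                              "row_labels", "col_labels")],
                           label = label)
}

#' Render a channel-by-frequency feature map as a matrix image
#'
#' One pixel per (channel, frequency) cell: values are min-max scaled to
#' `[0, 255]` per image and mapped through the colormap. A 23 x 23 map
#' yields a 23 x 23 x 3 image; 23 x 46 yields 23 x 46 x 3. A constant map
#' renders as a uniform image.
#'
#' @param fm a [feature_map()] with `row_axis == "channel"`.
#' @param label class label carried to the image.
#' @return a [new_representation_image()] of shape
#'   `channels x bins x 3`.
#' @export
render_matrix_image <- function(fm, label = "nonseizure") {
  stopifnot(inherits(fm, "feature_map"))
  if (fm$row_axis != "channel") {
    stop_seiznet("render_matrix_image expects a channel x frequency feature map",
                 "seiznet_validation_error")
  }
  v <- fm$values
  mn <- min(v); mx <- max(v)
  if (mx - mn <= 0) {
    idx <- matrix(1L, nrow(v), ncol(v))
  } else {
    idx <- matrix(as.integer(round((v - mn) / (mx - mn) * 255)) + 1L,
                  nrow(v), ncol(v))
  }
  new_representation_image(apply_colormap(idx),
                           source_axes = fm[c("row_axis", "col_axis",
                                              "row_labels", "col_labels")],
                           label = label)
}

#' Augment an image by flips and rotations
#'
#' Returns the original image plus one transformed copy per requested
#' operation; labels are preserved. Flips and 180-degree rotation keep the
#' image shape; 90/270-degree rotations transpose it.
#'
#' @param img a representation image.
#' @param ops character vector, a subset of
#'   `c("flip_h", "flip_v", "rot90", "rot180", "rot270")`.
#' @return a list of representation images of length `length(ops) + 1`.
#' @export
augment <- function(img, ops = character()) {
  stopifnot(inherits(img, "representation_image"))
  known <- c("flip_h", "flip_v", "rot90", "rot180", "rot270")
  bad <- setdiff(ops, known)
  if (length(bad) > 0L) {
    stop_seiznet(sprintf("unknown augmentation op(s): %s",
                         paste(bad, collapse = ", ")),
                 "seiznet_validation_error")
  }
  tf <- function(p, op) {
    switch(op,
      flip_h = p[, rev(seq_len(dim(p)[2])), , drop = FALSE],
      flip_v = p[rev(seq_len(dim(p)[1])), , , drop = FALSE],
      rot90 = aperm(p, c(2L, 1L, 3L))[rev(seq_len(dim(p)[2])), , , drop = FALSE],
      rot180 = p[rev(seq_len(dim(p)[1])), rev(seq_len(dim(p)[2])), , drop = FALSE],
      rot270 = aperm(p, c(2L, 1L, 3L))[, rev(seq_len(dim(p)[1])), , drop = FALSE]
    )
  }
  out <- list(img)
  for (op in ops) {
    out[[length(out) + 1L]] <- new_representation_image(
      tf(img$pixels, op), source_axes = img$source_axes, label = img$label)
  }
  out
}

# Bilinear resampling of a matrix to out_h x out_w, half-pixel-center
# convention (identity when the size is unchanged).
resize_bilinear_matrix <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  src <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  ys <- src(out_h, in_h); xs <- src(out_w, in_w)
  y0 <- pmin(floor(ys), in_h - 1); y1 <- pmin(y0 + 1, in_h - 1)
  x0 <- pmin(floor(xs), in_w - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- ys - y0; wx <- xs - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- a * (1 - outer(rep(1, out_h), wx)) + b * outer(rep(1, out_h), wx)
  bot <- c_ * (1 - outer(rep(1, out_h), wx)) + d * outer(rep(1, out_h), wx)
  top * (1 - outer(wy, rep(1, out_w))) + bot * outer(wy, rep(1, out_w))
}

#' Default input normalization constants
#'
#' Per-channel mean and standard deviation (RGB order, on the `[0, 1]`
#' intensity scale) used by backbones pretrained on the large public image
#' corpus; matching them is required when loading such pretrained weights.
#' @return a list with elements `mean` and `sd`, each length 3.
#' @export
imagenet_norm <- function() {
  list(mean = c(0.485, 0.456, 0.406), sd = c(0.229, 0.224, 0.225))
}

#' Convert a representation image to a network input tensor
#'
#' Resizes the image bilinearly to `R x R`, rescales intensities to
#' `[0, 1]`, and standardizes each channel with fixed constants
#' (defaults from [imagenet_norm()]; pass dataset statistics to override).
#'
#' @param img a representation image.
#' @param R target resolution in pixels.
#' @param norm list with `mean` and `sd`, each length 3 (RGB).
#' @return an object of class `net_input` with fields `tensor`
#'   (`3 x R x R` array, channels first) and `R`, plus the image's label.
#' @export
to_net_input <- function(img, R, norm = imagenet_norm()) {
  stopifnot(inherits(img, "representation_image"), R >= 1L)
  tensor <- array(0, dim = c(3L, R, R))
  for (ch in 1:3) {
    plane <- resize_bilinear_matrix(img$pixels[, , ch], R, R) / 255
    tensor[ch, , ] <- (plane - norm$mean[ch]) / norm$sd[ch]
  }
  structure(list(tensor = tensor, R = as.integer(R), label = img$label),
            class = "net_input")
}

#' Write a representation image as PNG with a JSON sidecar
#'
#' @param img a representation image.
#' @param path output PNG path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_representation_image <- function(img, path) {
  stopifnot(inherits(img, "representation_image"))
  png::writePNG(img$pixels / 255, path)
  jsonlite::write_json(
    list(label = img$label, source_axes = img$source_axes),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
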