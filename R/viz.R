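#' Select the activation map with the largest absolute sum
#'
#' The absolute value is applied to every filter's map first; the map whose
#' values sum to the most is taken as the layer's representative map, with
#' ties broken by the lowest filter index.
#'
#' @param stack array `[h, w, n_filters]` of raw activation maps (as
#'   returned by [layer_activations()]).
#' @return An `activation_map`: a non-negative matrix with attributes
#'   `filter_index` and `normalized = FALSE`.
#' @export
select_max_activation_map <- function(stack) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(is.array(stack), length(dim(stack)) == 3L, dim(stack)[3] >= 1L)
  a <- abs(stack)
  sums <- apply(a, 3L, sum)
  idx <- which.max(sums)  # first maximum on ties
  sel <- a[, , idx, drop = FALSE]
  dim(sel) <- dim(a)[1:2]
  structure(sel, filter_index = as.integer(idx), normalized = FALSE,
            class = c("activation_map", "matrix", "array"))
}

#' Normalize a non-negative map to \[0,1\]
#'
#' Divides by the largest value.  An all-zero map is returned unchanged
#' with attribute `zero_map = TRUE` (division by zero would be undefined;
#' a flat zero map carries no localization signal and is flagged rather
#' than inflated).
#'
#' @param map non-negative matrix (absolute values must already be taken).
#' @return The normalized `activation_map`.
#' @export
normalize01 <- function(map) {
  if (min(map) < 0) {
    stop("map has negative values; apply abs() before normalizing",
         call. = FALSE)
  }
  mx <- max(map)
  zero <- mx == 0
  out <- if (zero) map else map / mx
  structure(out, filter_index = attr(map, "filter_index"),
            normalized = TRUE, zero_map = zero,
            class = c("activation_map", "matrix", "array"))
}

#' Sum normalized maps and renormalize
#'
#' Elementwise addition of equally shaped normalized maps followed by
#' [normalize01()]; order of the list is irrelevant.
#'
#' @param maps list of normalized maps of identical shape.
#' @return The aggregated, normalized `activation_map`.
#' @export
aggregate_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1L]]))) {
    stop("all maps must share one shape", call. = FALSE)
  }
  total <- Reduce(`+`, lapply(maps, function(m) unclass_matrix(m)))
  normalize01(total)
}

#' Upsample a coarse activation map to image resolution
#'
#' Nearest-neighbour block expansion aligned to the stride grid: each map
#' pixel is replicated over the input block its receptive field covers
#' (kernel = stride, so blocks tile the image); trailing rows/columns not
#' covered by a full block repeat the nearest block.
#'
#' @param map matrix at convolution-layer resolution.
#' @param target_dim `c(height, width)` of the image.
#' @return Matrix of size `target_dim`.
#' @export
upsample_map <- function(map, target_dim) {
  m <- unclass_matrix(map)
  m[nn_index(nrow(m), target_dim[1]), nn_index(ncol(m), target_dim[2]),
    drop = FALSE]
}

#' Activation-map localization for a set of test images
#'
#' Applies the visualization procedure to each image: per convolution
#' layer, compute all filter maps, take absolute values, keep the map with
#' the largest total, normalize it to \[0,1\], upsample to image
#' resolution; then aggregate across images (sum and renormalize).
#'
#' @param model a trained `cnn_model`.
#' @param ds a [gm_dataset()] (typically the test split).
#' @param layers which convolution layers to aggregate.
#' @return Named list (`layer1`..) of aggregated `activation_map`s at
#'   image resolution.
#' @export
activation_summary <- function(model, ds, layers = 1:3) {
  n <- n_subjects(ds)
  target <- dim(ds$images)[1:2]
  out <- list()
  for (l in layers) {
    acc <- matrix(0, target[1], target[2])
    for (i in seq_len(n)) {
      st <- layer_activations(model, ds$images[, , i], l)
      m <- normalize01(select_max_activation_map(st))
      acc <- acc + upsample_map(m, target)
    }
    out[[paste0("layer", l)]] <- normalize01(acc)
  }
  out
}

#' Coordinates of an activation map's peak
#'
#' All pixels attaining the maximum (block upsampling produces plateaus).
#'
#' @param map an `activation_map` or matrix.
#' @return Two-column matrix of (row, col) positions.
#' @export
map_peak <- function(map) {
  which(unclass_matrix(map) == max(map), arr.ind = TRUE)
}

#' Render an activation overlay as a PNG
#'
#' The grey-matter slice is drawn in greyscale with the activation map
#' (upsampled to slice resolution) added to the red channel, so hot
#' regions appear red.  Output bytes are deterministic for fixed inputs.
#'
#' @param map normalized `activation_map` (any resolution).
#' @param slice a [gm_slice()] or matrix.
#' @param out_path output PNG path.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(map, slice, out_path) {
  s <- clip01(unclass_matrix(slice))
  m <- clip01(upsample_map(map, dim(s)))
  rgb <- array(0, dim = c(dim(s), 3L))
  rgb[, , 1] <- clip01(s + m)   # red carries the activation
  rgb[, , 2] <- s * (1 - 0.6 * m)
  rgb[, , 3] <- s * (1 - 0.6 * m)
  png::writePNG(rgb, out_path)
  invisible(out_path)
}
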