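#' Procedural grey-matter template
#'
#' Builds a 2D coronal-slice grey-matter density template: an elliptical
#' cortical ribbon, a central subcortical nucleus, and two bilateral
#' medial-temporal blobs, plus a low-amplitude smooth texture.  The template
#' is the shared anatomical substrate from which subjects are sampled;
#' region-of-interest (ROI) masks for the structures are carried along so
#' that simulated atrophy can be placed and later recovered.
#'
#' "Left" and "right" refer to image columns below and above the vertical
#' midline respectively; no radiological flip is applied.
#'
#' @param height,width image dimensions in pixels; both must be at least 64
#'   so the ROIs fit.
#' @param seed integer seed controlling the texture; templates are
#'   bit-identical for a fixed seed.
#' @param voxel_size_mm in-plane voxel size in millimetres.
#' @return An object of class `gm_template`: a list with `base_map` (matrix
#'   in \[0,1\]), `roi_masks` (named list of logical matrices:
#'   `left_medial_temporal`, `right_medial_temporal`, `neocortex`,
#'   `subcortical`) and `voxel_size_mm`.
#' @examples
#' tpl <- make_template(64, 64, seed = 1)
#' sum(tpl$roi_masks$left_medial_temporal)
#' @export
make_template <- function(height, width, seed = 0L, voxel_size_mm = 1) {
  if (height < 64L || width < 64L) {
    stop("template dimensions must be at least 64 x 64 to place the ROIs",
         call. = FALSE)
  }
  h <- as.integer(height); w <- as.integer(width)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2

  # cortical ribbon: elliptical annulus
  er <- ((rows - cy) / (0.42 * h))^2 + ((cols - cx) / (0.44 * w))^2
  ei <- ((rows - cy) / (0.30 * h))^2 + ((cols - cx) / (0.33 * w))^2
  ribbon <- er <= 1 & ei >= 1

  disc <- function(r0, c0, rad) (rows - r0)^2 + (cols - c0)^2 <= rad^2
  rad_mt <- max(3, round(0.05 * min(h, w)))
  left_mt  <- disc(0.62 * h, 0.34 * w, rad_mt)
  right_mt <- disc(0.62 * h, 0.66 * w, rad_mt)
  subcort  <- disc(0.46 * h, 0.50 * w, max(4, round(0.07 * min(h, w))))

  base <- matrix(0, h, w)
  base[ribbon]   <- 0.80
  base[subcort]  <- 0.65
  base[left_mt]  <- 0.85
  base[right_mt] <- 0.85

  # smooth seeded texture so subjects are not piecewise-constant
  tex <- with_seed(seed, matrix(stats::rnorm(h * w, sd = 1), h, w))
  tex <- gauss_smooth_array(tex, sigma_px = c(1.5, 1.5))
  brain <- base > 0
  base[brain] <- clip01(base[brain] + 0.04 * tex[brain])

  structure(list(
    base_map = base,
    roi_masks = list(
      left_medial_temporal  = left_mt,
      right_medial_temporal = right_mt,
      neocortex             = ribbon & !left_mt & !right_mt,
      subcortical           = subcort
    ),
    voxel_size_mm = voxel_size_mm
  ), class = "gm_template")
}

#' @export
print.gm_template <- function(x, ...) {
  cat(sprintf("<gm_template %d x %d, voxel %.3g mm, ROIs: %s>\n",
              nrow(x$base_map), ncol(x$base_map), x$voxel_size_mm,
              paste(names(x$roi_masks), collapse = ", ")))
  invisible(x)
}

#' Atrophy and nuisance parameters for one simulated subgroup
#'
#' @param medial_temporal_effect fractional intensity reduction in \[0,1)
#'   applied to the left medial-temporal ROI of TLE subjects.
#' @param extrahippocampal_effect fractional reduction in \[0,1) applied to
#'   the neocortical ribbon of TLE subjects (the weaker, distributed
#'   component of the atrophy pattern).
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param jitter_px maximum absolute integer translation, per axis, applied
#'   to each subject before noise; emulates residual anatomical
#'   misalignment.
#' @param erode_px number of erosion passes applied to the left
#'   medial-temporal blob rim (volume loss in addition to intensity loss).
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(medial_temporal_effect = 0,
                          extrahippocampal_effect = 0,
                          noise_sd = 0,
                          jitter_px = 0L,
                          erode_px = 0L) {
  stopifnot(medial_temporal_effect >= 0, medial_temporal_effect < 1,
            extrahippocampal_effect >= 0, extrahippocampal_effect < 1,
            noise_sd >= 0, jitter_px >= 0, erode_px >= 0)
  structure(list(medial_temporal_effect = medial_temporal_effect,
                 extrahippocampal_effect = extrahippocampal_effect,
                 noise_sd = noise_sd,
                 jitter_px = as.integer(jitter_px),
                 erode_px = as.integer(erode_px)),
            class = "effect_config")
}

erode_mask <- function(mask, passes) {
  for (i in seq_len(passes)) {
    h <- nrow(mask); w <- ncol(mask)
    up <- rbind(mask[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, mask[-h, , drop = FALSE])
    lf <- cbind(mask[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, mask[, -w, drop = FALSE])
    mask <- mask & up & dn & lf & rt
  }
  mask
}

shift_int <- function(img, dr, dc) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dr; src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Sample one subject image from a template
#'
#' TLE subjects get a multiplicative intensity reduction of
#' `medial_temporal_effect` on the left medial-temporal ROI (optionally with
#' rim erosion) and `extrahippocampal_effect` on the neocortical ribbon;
#' healthy controls get no effect.  Every subject then receives a small
#' integer translation drawn uniformly from `[-jitter_px, jitter_px]` per
#' axis and additive Gaussian noise, and is clipped back to \[0,1\].
#'
#' Draws from the current R random stream; seed at a higher level (e.g.
#' [generate_cohort()]) for reproducibility.
#'
#' @param template a [make_template()] object.
#' @param group `"HC"` or `"TLE"`.
#' @param effects an [effect_config()].
#' @return A `gm_slice`: a matrix in \[0,1\] with attributes
#'   `voxel_size_mm`, `smoothed` and (optionally) `plane_index`.
#' @export
sample_subject <- function(template, group, effects) {
  stopifnot(inherits(template, "gm_template"), inherits(effects, "effect_config"))
  group <- match.arg(group, c("HC", "TLE"))
  img <- template$base_map
  if (group == "TLE") {
    mt <- template$roi_masks$left_medial_temporal
    core <- if (effects$erode_px > 0) erode_mask(mt, effects$erode_px) else mt
    img[core] <- img[core] * (1 - effects$medial_temporal_effect)
    rim <- mt & !core
    img[rim] <- img[rim] * (1 - effects$medial_temporal_effect)^2
    nc <- template$roi_masks$neocortex
    img[nc] <- img[nc] * (1 - effects$extrahippocampal_effect)
  }
  if (effects$jitter_px > 0) {
    j <- effects$jitter_px
    sh <- sample.int(2L * j + 1L, 2L, replace = TRUE) - j - 1L
    img <- shift_int(img, sh[1L], sh[2L])
  }
  if (effects$noise_sd > 0) {
    img <- img + stats::rnorm(length(img), sd = effects$noise_sd)
  }
  gm_slice(clip01(img), voxel_size_mm = template$voxel_size_mm)
}

#' Construct a grey-matter slice
#'
#' @param pixels numeric matrix with values in \[0,1\].
#' @param voxel_size_mm positive in-plane voxel size.
#' @param plane_index optional 1-based coronal plane index of origin.
#' @param smoothed has Gaussian smoothing been applied?
#' @return The matrix with class `gm_slice` and metadata attributes.
#' @export
gm_slice <- function(pixels, voxel_size_mm = 1, plane_index = NULL,
                     smoothed = FALSE) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            min(pixels) >= 0, max(pixels) <= 1, voxel_size_mm > 0)
  structure(pixels, voxel_size_mm = voxel_size_mm,
            plane_index = plane_index, smoothed = smoothed,
            class = c("gm_slice", "matrix", "array"))
}
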