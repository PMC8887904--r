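#' Cohort composition and effect sizes for a simulated study
#'
#' Defaults mirror the study design the package emulates: 95 left-TLE
#' patients (48 "lesional", i.e. with visually evident medial-temporal
#' atrophy, and 47 "non-lesional" with subtle effects; 57 seizure-free
#' after surgery, 29 lesional + 28 non-lesional) versus 202 healthy
#' controls, recruited across three sites in the printed per-site
#' proportions.  The lesional subgroup effect must be at least as large as
#' the non-lesional effect.
#'
#' @param n_tle,n_hc group sizes.
#' @param n_lesional number of TLE subjects in the lesional subgroup; the
#'   remaining `n_tle - n_lesional` are non-lesional.
#' @param n_seizure_free_lesional,n_seizure_free_nonlesional counts of
#'   post-surgical seizure-free subjects per subgroup.
#' @param lesional_effects,nonlesional_effects [effect_config()] objects
#'   for the two patient subgroups.
#' @param hc_effects [effect_config()] for controls (no atrophy terms;
#'   jitter and noise only).
#' @param site_weights named numeric vector of relative site sizes.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_tle = 95L, n_hc = 202L, n_lesional = 48L,
                          n_seizure_free_lesional = 29L,
                          n_seizure_free_nonlesional = 28L,
                          lesional_effects = effect_config(
                            medial_temporal_effect = 0.30,
                            extrahippocampal_effect = 0.05,
                            noise_sd = 0.06, jitter_px = 1L),
                          nonlesional_effects = effect_config(
                            medial_temporal_effect = 0.10,
                            extrahippocampal_effect = 0.04,
                            noise_sd = 0.06, jitter_px = 1L),
                          hc_effects = effect_config(
                            noise_sd = 0.06, jitter_px = 1L),
                          site_weights = c(siteA = 30, siteB = 33, siteC = 32)) {
  n_tle <- as.integer(n_tle); n_hc <- as.integer(n_hc)
  n_lesional <- as.integer(n_lesional)
  if (n_tle < 0L || n_hc < 0L || n_lesional < 0L || n_lesional > n_tle) {
    stop("inconsistent cohort counts: need 0 <= n_lesional <= n_tle and n_hc >= 0",
         call. = FALSE)
  }
  n_nonlesional <- n_tle - n_lesional
  if (n_seizure_free_lesional > n_lesional ||
      n_seizure_free_nonlesional > n_nonlesional) {
    stop("seizure-free counts exceed subgroup sizes", call. = FALSE)
  }
  if (lesional_effects$medial_temporal_effect <
      nonlesional_effects$medial_temporal_effect) {
    stop("lesional subgroup effect must be >= non-lesional effect", call. = FALSE)
  }
  structure(list(n_tle = n_tle, n_hc = n_hc, n_lesional = n_lesional,
                 n_nonlesional = n_nonlesional,
                 n_seizure_free_lesional = as.integer(n_seizure_free_lesional),
                 n_seizure_free_nonlesional = as.integer(n_seizure_free_nonlesional),
                 lesional_effects = lesional_effects,
                 nonlesional_effects = nonlesional_effects,
                 hc_effects = hc_effects,
                 site_weights = site_weights),
            class = "cohort_config")
}

# proportional allocation of n slots to sites (largest remainder)
allocate_sites <- function(n, weights) {
  if (n == 0L) return(character(0))
  p <- weights / sum(weights)
  base <- floor(p * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(p * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(weights), times = base)
}

#' Generate a labelled cohort of grey-matter slices
#'
#' Samples `n_tle` patient and `n_hc` control images from a template under
#' a [cohort_config()], attaching subgroup flags and sites.  Fully
#' deterministic for a fixed seed.
#'
#' @param template a [make_template()] object.
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return A [gm_dataset()] whose `records` data frame has columns
#'   `subject_id`, `group` (factor HC/TLE), `label` (0/1), `lesional`,
#'   `seizure_free` (both `NA` for HC), `site`.
#' @examples
#' tpl <- make_template(64, 64, seed = 1)
#' ds <- generate_cohort(tpl, cohort_config(n_tle = 4, n_hc = 6,
#'   n_lesional = 2, n_seizure_free_lesional = 1,
#'   n_seizure_free_nonlesional = 1), seed = 7)
#' table(ds$records$group)
#' @export
generate_cohort <- function(template, config = cohort_config(), seed = 1L) {
  stopifnot(inherits(template, "gm_template"), inherits(config, "cohort_config"))
  n <- config$n_tle + config$n_hc
  if (n < 1L) stop("empty cohort requested", call. = FALSE)
  h <- nrow(template$base_map); w <- ncol(template$base_map)

  lesional <- c(rep(TRUE, config$n_lesional), rep(FALSE, config$n_nonlesional),
                rep(NA, config$n_hc))
  seizure_free <- c(
    rep(c(TRUE, FALSE), c(config$n_seizure_free_lesional,
                          config$n_lesional - config$n_seizure_free_lesional)),
    rep(c(TRUE, FALSE), c(config$n_seizure_free_nonlesional,
                          config$n_nonlesional - config$n_seizure_free_nonlesional)),
    rep(NA, config$n_hc))
  group <- factor(rep(c("TLE", "HC"), c(config$n_tle, config$n_hc)),
                  levels = c("HC", "TLE"))
  site <- c(allocate_sites(config$n_tle, config$site_weights),
            allocate_sites(config$n_hc, config$site_weights))

  images <- array(0, dim = c(h, w, n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      eff <- if (group[i] == "HC") config$hc_effects
             else if (isTRUE(lesional[i])) config$lesional_effects
             else config$nonlesional_effects
      images[, , i] <- sample_subject(template, as.character(group[i]), eff)
    }
  })
  records <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    group = group,
    label = as.integer(group == "TLE"),
    lesional = lesional,
    seizure_free = seizure_free,
    site = site,
    stringsAsFactors = FALSE)
  gm_dataset(images, records, template = template)
}

#' Bundle images and subject records into a labelled dataset
#'
#' @param images numeric array `[height, width, n]` with values in \[0,1\].
#' @param records data frame with one row per image; must contain `label`
#'   (integer 0 = HC, 1 = TLE) and `group`.
#' @param template optional generating [make_template()], kept for ROI
#'   lookups in tests and visualization.
#' @return An object of class `gm_dataset`.
#' @export
gm_dataset <- function(images, records, template = NULL) {
  stopifnot(is.array(images), length(dim(images)) == 3L,
            is.data.frame(records), dim(images)[3] == nrow(records),
            all(records$label %in% c(0L, 1L)))
  structure(list(images = images, records = records, template = template),
            class = "gm_dataset")
}

#' @export
print.gm_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<gm_dataset: %d subjects (%d TLE / %d HC), %d x %d images>\n",
              d[3], sum(x$records$label == 1L), sum(x$records$label == 0L),
              d[1], d[2]))
  invisible(x)
}

#' Number of subjects in a dataset
#' @param ds a [gm_dataset()].
#' @export
n_subjects <- function(ds) dim(ds$images)[3]

#' Subset a dataset by subject index
#' @param ds a [gm_dataset()].
#' @param idx integer index vector.
#' @export
subset_dataset <- function(ds, idx) {
  stopifnot(inherits(ds, "gm_dataset"))
  gm_dataset(ds$images[, , idx, drop = FALSE],
             ds$records[idx, , drop = FALSE],
             template = ds$template)
}

#' Can a dataset be used for supervised training?
#'
#' Requires both classes present (a single-class cohort cannot train a
#' classifier).
#' @param ds a [gm_dataset()].
#' @return logical
#' @export
dataset_trainable <- function(ds) {
  length(unique(ds$records$label)) == 2L
}
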