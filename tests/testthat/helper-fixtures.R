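# Shared reduced-scale fixtures.  64 x 64 templates and small kernel chains
# keep every training run in the suite to fractions of a second while
# preserving the structure of the full-scale study.

tiny_spec <- function() cnn_spec(conv = list(c(8, 16), c(8, 2), c(8, 2)))

tiny_dag_spec <- function() dag_spec(conv = list(c(4, 16), c(8, 2), c(8, 2)))

tiny_train_cfg <- function(seed = 1L, epochs = 15L, lr = 0.05) {
  train_config(learning_rate = lr, epochs = epochs,
               validation_frequency = epochs, seed = seed)
}

# cohort with a clearly separable left medial-temporal effect
strong_cohort <- function(seed = 3L, n_tle = 20L, n_hc = 40L, effect = 0.5,
                          noise = 0.03) {
  tpl <- make_template(64, 64, seed = 1)
  cc <- cohort_config(
    n_tle = n_tle, n_hc = n_hc, n_lesional = n_tle,
    n_seizure_free_lesional = n_tle %/% 2, n_seizure_free_nonlesional = 0,
    lesional_effects = effect_config(effect, 0.05, noise, 1L),
    nonlesional_effects = effect_config(effect, 0.05, noise, 1L),
    hc_effects = effect_config(noise_sd = noise, jitter_px = 1L))
  generate_cohort(tpl, cc, seed = seed)
}

# cohort with realistic subgroup structure and imbalance
study_cohort <- function(seed = 12L, n_tle = 40L, n_hc = 80L) {
  tpl <- make_template(64, 64, seed = 11)
  cc <- cohort_config(n_tle = n_tle, n_hc = n_hc, n_lesional = n_tle %/% 2,
                      n_seizure_free_lesional = n_tle %/% 4,
                      n_seizure_free_nonlesional = n_tle %/% 4)
  generate_cohort(tpl, cc, seed = seed)
}

# raw smoothing operator (no clipping), pixels = mm
gauss_smooth_for_test <- function(x, fwhm) {
  gauss_smooth_array(x, rep(fwhm_to_sigma(fwhm), length(dim(x))))
}

# strip gm_slice attributes for comparison against raw matrices
unclass_matrix_for_test <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

# small labelled dataset from raw arrays, for SMOTE / metric unit tests
array_dataset <- function(images, labels) {
  n <- dim(images)[3]
  gm_dataset(images, data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = factor(ifelse(labels == 1L, "TLE", "HC"), levels = c("HC", "TLE")),
    label = as.integer(labels),
    lesional = NA, seizure_free = NA, site = "siteA",
    stringsAsFactors = FALSE))
}
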