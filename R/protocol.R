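#' Stratified train/test split
#'
#' Per class, `floor(n_class * test_fraction)` subjects are drawn (without
#' replacement) into the test set; the floor rule means 95 TLE / 202 HC at
#' the default 20% yields a 19 + 40 test set.  Partitions are disjoint and
#' exhaustive, and deterministic for a fixed seed.
#'
#' @param ds a [gm_dataset()].
#' @param test_fraction fraction of each class assigned to test.
#' @param seed integer seed.
#' @return List with `train_val` and `test` ([gm_dataset()]s) and the
#'   index vectors `train_idx`, `test_idx`.
#' @export
stratified_split <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "gm_dataset"), test_fraction > 0, test_fraction < 1)
  lab <- ds$records$label
  if (min(table(factor(lab, levels = 0:1))) < 5L) {
    stop("each class needs at least 5 subjects to split", call. = FALSE)
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cl) {
      cls <- which(lab == cl)
      n_test <- floor(length(cls) * test_fraction)
      if (n_test < 1L) stop("test fraction leaves an empty test class",
                            call. = FALSE)
      sort(sample(cls, n_test))
    }))
  })
  train_idx <- setdiff(seq_along(lab), test_idx)
  list(train_val = subset_dataset(ds, train_idx),
       test = subset_dataset(ds, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, k, seed = 1L) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      cls <- which(labels == cl)
      if (length(cls) < k) {
        stop(sprintf("class %s has %d subjects, fewer than %d folds",
                     cl, length(cls), k), call. = FALSE)
      }
      folds[cls[sample.int(length(cls))]] <- rep_len(seq_len(k), length(cls))
    }
  })
  folds
}

#' Hyperparameter grid
#'
#' The Cartesian product of candidate architectures and training settings,
#' enumerated deterministically with the architecture varying slowest, then
#' learning rate, epochs and validation frequency.
#'
#' @param specs list of [cnn_spec()] / [dag_spec()] candidates.
#' @param learning_rate,epochs,validation_frequency candidate vectors.
#' @param batch_size fixed minibatch size.
#' @return An object of class `hyper_grid`: a list of
#'   `list(spec, learning_rate, epochs, validation_frequency, batch_size)`
#'   combinations.
#' @export
hyper_grid <- function(specs, learning_rate = 6e-4, epochs = 160L,
                       validation_frequency = 80L, batch_size = 16L) {
  if (inherits(specs, "cnn_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, length(learning_rate) >= 1L,
            length(epochs) >= 1L, length(validation_frequency) >= 1L)
  combos <- list()
  for (sp in specs) for (lr in learning_rate) for (ep in epochs)
    for (vf in validation_frequency) {
      combos[[length(combos) + 1L]] <- list(
        spec = sp, learning_rate = lr, epochs = as.integer(ep),
        validation_frequency = as.integer(vf),
        batch_size = as.integer(batch_size))
    }
  structure(combos, class = "hyper_grid")
}

combo_cfg <- function(combo, seed) {
  train_config(learning_rate = combo$learning_rate, epochs = combo$epochs,
               validation_frequency = combo$validation_frequency,
               batch_size = combo$batch_size, seed = seed)
}

val_accuracy <- function(model, val_set) {
  mean((predict_scores(model, val_set) >= 0.5) ==
         (val_set$records$label == 1L))
}

#' Stratified k-fold grid search
#'
#' For every grid combination and every fold: the other `k - 1` folds are
#' SMOTE-balanced and used for training, the held-out fold for validation.
#' The (combination, fold) pair with the highest validation accuracy wins;
#' ties go to the first in enumeration order.  Combinations whose kernel
#' chain does not fit the image size are skipped and logged.
#'
#' @param train_val a [gm_dataset()] (the 80% split).
#' @param grid a [hyper_grid()].
#' @param k number of folds.
#' @param seed integer seed.
#' @param smote_cfg a [smote_config()].
#' @return List with `best` (winning combination), `best_fold`,
#'   `best_model` (the winning fold's trained model), `best_accuracy`,
#'   `fold_accuracies` (all `k` validation accuracies of the winning
#'   combination) and `skipped` (integer indices of unbuildable
#'   combinations).
#' @export
grid_search <- function(train_val, grid, k = 10L, seed = 1L,
                        smote_cfg = smote_config()) {
  if (!inherits(grid, "hyper_grid") || length(grid) == 0L) {
    stop("grid must be a non-empty hyper_grid", call. = FALSE)
  }
  lab <- train_val$records$label
  folds <- stratified_folds(lab, k, seed = seed)
  img_dim <- dim(train_val$images)[1:2]

  best <- list(accuracy = -Inf)
  skipped <- integer(0)
  acc_by_combo <- vector("list", length(grid))
  for (ci in seq_along(grid)) {
    combo <- grid[[ci]]
    ok <- tryCatch({ layer_dims(combo$spec, img_dim); TRUE },
                   error = function(e) FALSE)
    if (!ok) { skipped <- c(skipped, ci); next }
    accs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- subset_dataset(train_val, which(folds != f))
      va <- subset_dataset(train_val, which(folds == f))
      sseed <- derive_seed(seed, ci * 1000L + f, stride = 7919)
      bal <- smote_balance(tr, smote_cfg, seed = sseed)
      model <- train_model(combo$spec, bal$dataset, val_set = NULL,
                           cfg = combo_cfg(combo, seed = sseed + 1L))
      accs[f] <- val_accuracy(model, va)
      if (accs[f] > best$accuracy) {
        best <- list(accuracy = accs[f], combo_index = ci, fold = f,
                     model = model)
      }
    }
    acc_by_combo[[ci]] <- accs
  }
  if (!is.finite(best$accuracy)) {
    stop("no buildable combination in the grid", call. = FALSE)
  }
  list(best = grid[[best$combo_index]], best_fold = best$fold,
       best_model = best$model, best_accuracy = best$accuracy,
       fold_accuracies = acc_by_combo[[best$combo_index]],
       skipped = skipped)
}

#' Evaluate a trained model on an untouched test set
#'
#' Builds the 2x2 confusion matrix (TLE positive) at threshold 0.5 and
#' computes PPV, NPV, SEN, SPC, AUC and ACC, plus the same metrics
#' restricted to each TLE subgroup (lesional / non-lesional /
#' seizure-free / non-seizure-free versus all test controls) where the
#' subgroup flags are present.
#'
#' @param model a trained `cnn_model`.
#' @param test a [gm_dataset()] never seen in training or SMOTE.
#' @return List with `confusion`, `metrics` (one-row data frame),
#'   `subgroups` (named list of one-row data frames) and `scores`.
#' @export
evaluate_on_test <- function(model, test) {
  scores <- predict_scores(model, test)
  truth <- as.integer(test$records$label)
  pred <- as.integer(scores >= 0.5)
  cm <- confusion_matrix(truth, pred)
  out <- list(confusion = cm,
              metrics = metrics_summary(cm, scores, truth),
              subgroups = list(), scores = scores)
  rec <- test$records
  flags <- list(lesional = rec$lesional %in% TRUE,
                non_lesional = rec$lesional %in% FALSE,
                seizure_free = rec$seizure_free %in% TRUE,
                non_seizure_free = rec$seizure_free %in% FALSE)
  for (nm in names(flags)) {
    keep <- truth == 0L | flags[[nm]]
    if (sum(flags[[nm]]) == 0L) next
    cm_s <- confusion_matrix(truth[keep], pred[keep])
    out$subgroups[[nm]] <- metrics_summary(cm_s, scores[keep], truth[keep])
  }
  out
}

summarize_distribution <- function(per_repeat) {
  metrics <- c("ppv", "npv", "sen", "spc", "auc", "acc")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_repeat[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) stats::sd(per_repeat[[m]], na.rm = TRUE), 0),
    n_undefined = vapply(metrics, function(m) sum(is.na(per_repeat[[m]])), 0L),
    row.names = NULL)
}

#' Repeated stratified grid-search evaluation
#'
#' One repeat performs the four protocol steps: (1) stratified 80/20
#' split; (2) stratified k-fold grid search on the training+validation
#' split, balancing each fold's training portion with SMOTE; (3) selection
#' of the hyperparameters with the highest validation accuracy; (4) a
#' final model fitted with those hyperparameters (by default retrained on
#' the full SMOTE-balanced training+validation split) and evaluated on the
#' untouched test split.  Repeats use seeds derived from `seed` by a fixed
#' counter scheme, so any repeat can be recomputed in isolation.
#'
#' @param ds a [gm_dataset()].
#' @param grid a [hyper_grid()].
#' @param repeats number of protocol repeats (the full-scale study uses
#'   1000; reduced runs are statistically noisier but unbiased).
#' @param seed master seed.
#' @param k folds for the grid search.
#' @param test_fraction test split fraction.
#' @param smote_cfg a [smote_config()].
#' @param retrain retrain on the full training+validation split with the
#'   winning hyperparameters (default); `FALSE` reuses the winning fold
#'   model directly.
#' @return An object of class `metric_distribution`: list with
#'   `per_repeat` (data frame of the six metrics per repeat), `summary`
#'   (mean/sd per metric), `confusions`, `subgroups` (per-repeat subgroup
#'   metrics), and `audit` (per-repeat test/train subject ids and SMOTE
#'   parent ids, for leakage checks).
#' @export
run_protocol <- function(ds, grid, repeats = 20L, seed = 1L, k = 10L,
                         test_fraction = 0.2, smote_cfg = smote_config(),
                         retrain = TRUE) {
  stopifnot(repeats >= 1L)
  rows <- vector("list", repeats); cms <- vector("list", repeats)
  subg <- vector("list", repeats); audit <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    rs <- derive_seed(seed, i)
    sp <- stratified_split(ds, test_fraction, seed = rs)
    gs <- grid_search(sp$train_val, grid, k = k, seed = rs + 1L,
                      smote_cfg = smote_cfg)
    if (retrain) {
      bal <- smote_balance(sp$train_val, smote_cfg,
                           seed = derive_seed(rs, 2L, stride = 7919))
      final <- train_model(gs$best$spec, bal$dataset, val_set = NULL,
                           cfg = combo_cfg(gs$best,
                                           seed = derive_seed(rs, 3L, stride = 7919)))
      smote_parents <- sp$train_val$records$subject_id[bal$log$parent_index]
    } else {
      final <- gs$best_model
      smote_parents <- character(0)
    }
    ev <- evaluate_on_test(final, sp$test)
    rows[[i]] <- cbind(data.frame(repeat_index = i), ev$metrics)
    cms[[i]] <- ev$confusion
    subg[[i]] <- ev$subgroups
    audit[[i]] <- list(
      test_ids = sp$test$records$subject_id,
      train_ids = sp$train_val$records$subject_id,
      smote_parent_ids = smote_parents)
  }
  per_repeat <- do.call(rbind, rows)
  structure(list(per_repeat = per_repeat,
                 summary = summarize_distribution(per_repeat),
                 confusions = cms, subgroups = subg, audit = audit),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("<metric_distribution over %d repeats>\n", nrow(x$per_repeat)))
  print(x$summary, ...)
  invisible(x)
}

#' Permuted-label null distribution of the evaluation protocol
#'
#' Per repeat: a fresh stratified 80/20 split is drawn, the
#' training+validation labels are randomly permuted, and a stratified
#' k-fold cross-validation (no grid search) is run at the supplied fixed
#' hyperparameters, balancing each fold's training portion with SMOTE on
#' the permuted labels.  The fold model with the highest (permuted-label)
#' validation accuracy is selected and evaluated on the test split with
#' its true labels, yielding one random confusion matrix per repeat.  The
#' resulting metric distribution is the chance reference against which
#' [p_value()] compares the correctly trained models.
#'
#' @param ds a [gm_dataset()].
#' @param params one [hyper_grid()] combination (or a length-1 grid): the
#'   optimal modelling parameters.
#' @param repeats number of null repeats.
#' @param seed master seed.
#' @inheritParams run_protocol
#' @return A `metric_distribution` (no subgroup tables).
#' @export
run_permutation_null <- function(ds, params, repeats = 50L, seed = 1L,
                                 k = 10L, test_fraction = 0.2,
                                 smote_cfg = smote_config()) {
  if (inherits(params, "hyper_grid")) {
    stopifnot(length(params) == 1L)
    params <- params[[1L]]
  }
  stopifnot(repeats >= 1L, !is.null(params$spec))
  rows <- vector("list", repeats); cms <- vector("list", repeats)
  audit <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    rs <- derive_seed(seed, i)
    sp <- stratified_split(ds, test_fraction, seed = rs)
    tv <- sp$train_val
    perm <- with_seed(rs + 1L, sample.int(n_subjects(tv)))
    tv$records$label <- tv$records$label[perm]
    tv$records$group <- tv$records$group[perm]
    folds <- stratified_folds(tv$records$label, k, seed = rs + 2L)
    best_acc <- -Inf; best_model <- NULL
    for (f in seq_len(k)) {
      tr <- subset_dataset(tv, which(folds != f))
      va <- subset_dataset(tv, which(folds == f))
      sseed <- derive_seed(rs, f, stride = 7919)
      bal <- smote_balance(tr, smote_cfg, seed = sseed)
      model <- train_model(params$spec, bal$dataset, val_set = NULL,
                           cfg = combo_cfg(params, seed = sseed + 1L))
      acc <- val_accuracy(model, va)
      if (acc > best_acc) { best_acc <- acc; best_model <- model }
    }
    ev <- evaluate_on_test(best_model, sp$test)
    rows[[i]] <- cbind(data.frame(repeat_index = i), ev$metrics)
    cms[[i]] <- ev$confusion
    audit[[i]] <- list(test_ids = sp$test$records$subject_id,
                       train_ids = tv$records$subject_id)
  }
  per_repeat <- do.call(rbind, rows)
  structure(list(per_repeat = per_repeat,
                 summary = summarize_distribution(per_repeat),
                 confusions = cms, subgroups = NULL, audit = audit),
            class = "metric_distribution")
}
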