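#' SMOTE configuration for image oversampling
#'
#' The displacement multiplier Rd is drawn, in `"as_printed_uniform_mean0_sd1"`
#' mode, from the unique uniform distribution with mean 0 and standard
#' deviation 1, i.e. U(-sqrt(3), sqrt(3)), and the synthetic sample is
#' `Xs = Xm + (Xm - Xhat) * Rd`.  `"classic_uniform01"` mode follows the
#' original SMOTE convention: Rd ~ U(0, 1) and `Xs = Xm + (Xhat - Xm) * Rd`,
#' which places the synthetic sample on the segment between parent and
#' neighbour.  Both are retained because the two conventions differ in the
#' sign of the displacement; the default follows the printed formula.
#'
#' @param k number of nearest neighbours (default 5).
#' @param rd_mode `"as_printed_uniform_mean0_sd1"` or `"classic_uniform01"`.
#' @param parent_order `"round_robin"` (cycle over minority samples, the
#'   default) or `"random"` (parents drawn at random with replacement).
#' @return An object of class `smote_config`.
#' @export
smote_config <- function(k = 5L,
                         rd_mode = c("as_printed_uniform_mean0_sd1",
                                     "classic_uniform01"),
                         parent_order = c("round_robin", "random")) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  structure(list(k = k, rd_mode = match.arg(rd_mode),
                 parent_order = match.arg(parent_order)),
            class = "smote_config")
}

#' Indices of the k nearest neighbours by Euclidean pixel distance
#'
#' Distances are computed over flattened pixel vectors; ties are broken by
#' ascending pool index.  The query must not be a member of `pool` (the
#' caller excludes it).
#'
#' @param sample numeric matrix (query image).
#' @param pool numeric array `[h, w, n]` of candidate images.
#' @param k number of neighbours.
#' @return Integer vector of `k` pool indices, nearest first.
#' @export
nearest_neighbours <- function(sample, pool, k) {
  n <- dim(pool)[3]
  if (n < k) stop(sprintf("pool of %d images is smaller than k = %d", n, k),
                  call. = FALSE)
  pm <- matrix(pool, ncol = n)
  v <- as.numeric(sample)
  d2 <- colSums((pm - v)^2)
  order(d2)[seq_len(k)]  # order() breaks ties by ascending index
}

#' Synthesize one SMOTE sample from a parent and a neighbour
#'
#' @param xm parent minority image (matrix).
#' @param xhat selected neighbour image (matrix, same shape).
#' @param rd displacement multiplier.
#' @param rd_mode see [smote_config()]; decides the displacement sign
#'   convention.
#' @return Matrix of the same shape, clipped to \[0,1\].
#' @export
synthesize_sample <- function(xm, xhat, rd,
                              rd_mode = c("as_printed_uniform_mean0_sd1",
                                          "classic_uniform01")) {
  rd_mode <- match.arg(rd_mode)
  if (!identical(dim(xm), dim(xhat))) {
    stop("parent and neighbour images must have identical shape", call. = FALSE)
  }
  out <- if (rd_mode == "as_printed_uniform_mean0_sd1") {
    xm + (xm - xhat) * rd
  } else {
    xm + (xhat - xm) * rd
  }
  clip01(out)
}

draw_rd <- function(n, rd_mode) {
  if (rd_mode == "as_printed_uniform_mean0_sd1") {
    stats::runif(n, min = -sqrt(3), max = sqrt(3))
  } else {
    stats::runif(n)
  }
}

#' Balance a training set by SMOTE oversampling of the minority class
#'
#' Creates synthetic minority images until class counts are equal.  All
#' original samples are retained and majority samples are never touched.
#' Parents cycle round-robin over the minority class (configurable);
#' for each synthetic sample one of the parent's `k` nearest minority
#' neighbours is selected uniformly at random and the displacement formula
#' of [synthesize_sample()] is applied.  Intended for training data only —
#' applying it before a train/test split leaks synthetic copies of test
#' information into training.
#'
#' @param train_set a [gm_dataset()] with both classes present.
#' @param config a [smote_config()].
#' @param seed integer seed.
#' @return A list with `dataset` (the balanced [gm_dataset()]; synthetic
#'   records get `subject_id` `"smote-<i>"` and minority label) and `log`
#'   (data frame: `parent_index`, `neighbour_index`, `rd` per synthetic
#'   sample, indices into the original dataset).
#' @export
smote_balance <- function(train_set, config = smote_config(), seed = 1L) {
  stopifnot(inherits(train_set, "gm_dataset"), inherits(config, "smote_config"))
  lab <- train_set$records$label
  counts <- table(factor(lab, levels = c(0L, 1L)))
  if (any(counts == 0L)) {
    stop("both classes must be present to balance", call. = FALSE)
  }
  minority_label <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  n_needed <- abs(counts[["0"]] - counts[["1"]])
  empty_log <- data.frame(parent_index = integer(0),
                          neighbour_index = integer(0), rd = numeric(0))
  if (n_needed == 0L) {
    return(list(dataset = train_set, log = empty_log))
  }
  min_idx <- which(lab == minority_label)
  if (length(min_idx) < config$k + 1L) {
    stop(sprintf("minority class (%d samples) too small for k = %d neighbours",
                 length(min_idx), config$k), call. = FALSE)
  }
  h <- dim(train_set$images)[1]; w <- dim(train_set$images)[2]

  # k nearest minority neighbours of each minority sample, self excluded
  nn <- matrix(0L, length(min_idx), config$k)
  for (j in seq_along(min_idx)) {
    pool_members <- min_idx[-j]
    nb <- nearest_neighbours(train_set$images[, , min_idx[j]],
                             train_set$images[, , pool_members, drop = FALSE],
                             config$k)
    nn[j, ] <- pool_members[nb]
  }

  synth <- array(0, dim = c(h, w, n_needed))
  log <- with_seed(seed, {
    parents <- if (config$parent_order == "round_robin") {
      rep_len(seq_along(min_idx), n_needed)
    } else {
      sample.int(length(min_idx), n_needed, replace = TRUE)
    }
    nb_pick <- sample.int(config$k, n_needed, replace = TRUE)
    rd <- draw_rd(n_needed, config$rd_mode)
    for (s in seq_len(n_needed)) {
      xm <- train_set$images[, , min_idx[parents[s]]]
      xhat <- train_set$images[, , nn[parents[s], nb_pick[s]]]
      synth[, , s] <- synthesize_sample(xm, xhat, rd[s], config$rd_mode)
    }
    data.frame(parent_index = min_idx[parents],
               neighbour_index = nn[cbind(parents, nb_pick)],
               rd = rd)
  })

  rec <- train_set$records[rep(min_idx[1L], n_needed), , drop = FALSE]
  rec$subject_id <- sprintf("smote-%04d", seq_len(n_needed))
  rec$label <- minority_label
  rec$lesional <- NA
  rec$seizure_free <- NA
  rownames(rec) <- NULL
  out <- gm_dataset(
    array(c(train_set$images, synth), dim = c(h, w, n_subjects(train_set) + n_needed)),
    rbind(train_set$records, rec),
    template = train_set$template)
  list(dataset = out, log = log)
}

#' Write a SMOTE audit log to CSV
#' @param log the `log` element returned by [smote_balance()].
#' @param path output CSV path.
#' @export
write_smote_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
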