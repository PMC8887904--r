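#' Write a cohort to disk as NIfTI images plus a CSV sidecar
#'
#' One `.nii.gz` per subject (named by `subject_id`) and a
#' `participants.csv` with the subject records.
#'
#' @param ds a [gm_dataset()].
#' @param dir output directory (must exist).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(ds, dir) {
  stopifnot(inherits(ds, "gm_dataset"))
  if (!dir.exists(dir)) {
    stop(sprintf("output directory does not exist: %s", dir), call. = FALSE)
  }
  for (i in seq_len(n_subjects(ds))) {
    RNifti::writeNifti(ds$images[, , i],
                       file.path(dir, paste0(ds$records$subject_id[i], ".nii.gz")))
  }
  utils::write.csv(ds$records, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `participants.csv` and one `.nii.gz`
#'   per subject.
#' @return A [gm_dataset()].
#' @export
read_cohort <- function(dir) {
  csv <- file.path(dir, "participants.csv")
  if (!file.exists(csv)) stop("participants.csv not found in ", dir,
                              call. = FALSE)
  records <- utils::read.csv(csv, stringsAsFactors = FALSE)
  records$group <- factor(records$group, levels = c("HC", "TLE"))
  first <- RNifti::readNifti(file.path(dir, paste0(records$subject_id[1], ".nii.gz")))
  d <- dim(first)
  images <- array(0, dim = c(d[1], d[2], nrow(records)))
  images[, , 1] <- as.array(first)
  for (i in seq_len(nrow(records))[-1]) {
    images[, , i] <- as.array(
      RNifti::readNifti(file.path(dir, paste0(records$subject_id[i], ".nii.gz"))))
  }
  gm_dataset(clip01(images), records)
}
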