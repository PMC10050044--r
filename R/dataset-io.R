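# Tidy choice-dataset and ground-truth CSV readers/writers.  Real task
# exports that meet the same schema can be analysed through the identical
# interface.

#' Read and write tidy choice datasets
#'
#' The dataset CSV has the fixed header
#' `subject,trial,reward_points,effort_label,switch_count,reward_z,reward_z2,effort_z,accepted,success,elapsed_ms,allowed_time_ms`.
#' On read the schema and the row invariants are validated: `accepted` is
#' 0/1 on every row, rejected rows carry no `success`/`elapsed_ms`,
#' accepted rows carry both, and reward/effort levels lie on the design
#' grid.
#'
#' @param dataset Choice data frame (e.g. `simulate_study(...)$choices`).
#' @param file Path to a CSV file.
#' @return `read_dataset()` returns the validated data frame.
#' @export
write_dataset <- function(dataset, file) {
  if (!identical(names(dataset), CHOICES_HEADER)) {
    stop_("dataset columns must be exactly: ",
          paste(CHOICES_HEADER, collapse = ","))
  }
  utils::write.csv(dataset, file, row.names = FALSE, quote = FALSE)
  invisible(dataset)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!identical(names(x), CHOICES_HEADER)) {
    stop_("malformed dataset header; expected ",
          paste(CHOICES_HEADER, collapse = ","), " but found ",
          paste(names(x), collapse = ","))
  }
  validate_dataset(x)
}

validate_dataset <- function(x) {
  if (!all(x$accepted %in% c(0L, 1L))) {
    stop_("column accepted: every row must be 0 or 1")
  }
  bad <- which(x$accepted == 0L & (!is.na(x$success) | !is.na(x$elapsed_ms)))
  if (length(bad) > 0L) {
    stop_("row ", bad[1],
          ": rejected offers must not record success/elapsed_ms")
  }
  bad <- which(x$accepted == 1L & (is.na(x$success) | is.na(x$elapsed_ms)))
  if (length(bad) > 0L) {
    stop_("row ", bad[1],
          ": accepted offers must record success and elapsed_ms")
  }
  bad <- which(!(x$reward_points %in% REWARD_POINTS))
  if (length(bad) > 0L) {
    stop_("row ", bad[1], ", column reward_points: out-of-grid level ",
          x$reward_points[bad[1]])
  }
  normalize_effort(x$effort_label)
  z <- standardize_predictors(x$reward_points, x$effort_label)
  if (max(abs(z$reward_z - x$reward_z), abs(z$reward_z2 - x$reward_z2),
          abs(z$effort_z - x$effort_z)) > 1e-6) {
    stop_("standardised predictor columns are inconsistent with the levels")
  }
  x
}

#' Read and write ground-truth agent parameters
#'
#' Columns: `subject,alpha,beta_reward,beta_reward2,beta_effort,allowed_time_ms`.
#'
#' @param agents Agents data frame (e.g. `simulate_study(...)$agents`).
#' @param file Path to a CSV file.
#' @return `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(agents, file) {
  if (!all(TRUTH_HEADER %in% names(agents))) {
    stop_("ground truth needs columns: ", paste(TRUTH_HEADER, collapse = ","))
  }
  utils::write.csv(agents[, TRUTH_HEADER], file, row.names = FALSE,
                   quote = FALSE)
  invisible(agents)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!identical(names(x), TRUTH_HEADER)) {
    stop_("malformed ground-truth header; expected ",
          paste(TRUTH_HEADER, collapse = ","))
  }
  x
}
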