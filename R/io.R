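#' Read and validate tabular inputs
#'
#' Thin CSV readers for the package's tabular interchange formats. Each
#' validates the required columns and returns a tibble ready for the
#' corresponding analysis function.
#'
#' * Measurements: `subject`, `region`, `value` plus exactly one of
#'   `stage` / `time_years` (optional `assay`, `replicate`) — consumed
#'   by [infer_kappa()].
#' * Stage-age table: long format `age_bin`, `stage`, `count` —
#'   consumed by [conditional_stage_given_age()].
#' * PET records: `S1`, `S2`, `interval_years` (optional `subject`,
#'   `group`) — consumed by [fit_pet()].
#' * Mouse time courses: `region`, `time_months`, `value` — consumed
#'   by [fit_log_linear()].
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @name readers
NULL

.read_csv_cols <- function(path, required) {
  d <- as_tibble(utils::read.csv(path, check.names = FALSE))
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  d
}

#' @rdname readers
#' @export
read_measurements <- function(path) {
  d <- .read_csv_cols(path, c("value"))
  if (!any(c("stage", "time_years") %in% names(d))) {
    abort("measurements need a `stage` or `time_years` column.")
  }
  if (any(d$value <= 0)) abort("measurement values must be positive.")
  d
}

#' @rdname readers
#' @export
read_stage_age_table <- function(path) {
  .read_csv_cols(path, c("age_bin", "stage", "count"))
}

#' @rdname readers
#' @export
read_pet_records <- function(path) {
  .read_csv_cols(path, c("S1", "S2", "interval_years"))
}

#' @rdname readers
#' @export
read_mouse_timecourses <- function(path) {
  .read_csv_cols(path, c("region", "time_months", "value"))
}
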