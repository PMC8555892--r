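#' Retain time points measured in every brain region
#'
#' Mouse seed time courses are unevenly sampled across regions; to
#' avoid biasing the pooled exponential fit, only time points present
#' in every region are retained.
#'
#' @param courses Data frame with columns `region`, `time_months`,
#'   `value` (one row per measurement).
#' @return Sorted numeric vector of time points common to all regions.
#' @export
filter_complete_timepoints <- function(courses) {
  d <- as_tibble(courses)
  stopifnot(all(c("region", "time_months") %in% names(d)))
  times_by_region <- d |>
    distinct(.data$region, .data$time_months) |>
    split(~region) |>
    purrr::map(~ .x$time_months)
  common <- Reduce(intersect, times_by_region)
  if (length(common) == 0) abort("no time point is shared by every region.")
  sort(common)
}

#' Early-phase exponential fit to mouse seed time courses
#'
#' Ordinary least squares of log seeding signal against time, restricted
#' to the complete time points (see [filter_complete_timepoints()]) at
#' or before `early_cutoff` months, the exponential phase before the
#' late-time plateau. The slope in natural-log space is reported as the
#' replication rate kappa (per month); because the logarithm convention
#' behind published mouse rates is ambiguous, the log10 slope
#' (decades per month) and the doubling time implied by each convention
#' are reported alongside, and neither is silently preferred.
#'
#' @param courses Data frame with `region`, `time_months`, `value` (> 0).
#' @param early_cutoff Last month included in the fit (default 4).
#' @param complete_only Restrict to time points present in every region
#'   (default TRUE).
#' @return A `mouse_fit`: list with `kappa` (natural-log slope, per
#'   month), `slope_log10` (decades per month), `intercept_ln`,
#'   `doubling_time_months` (= ln 2 / kappa; independent of the log
#'   convention), `n`, `times_used`.
#' @export
#'
#' @examples
#' fit_log_linear(gen_mouse_timecourses(seed = 1))
fit_log_linear <- function(courses, early_cutoff = 4, complete_only = TRUE) {
  d <- as_tibble(courses)
  stopifnot(all(c("region", "time_months", "value") %in% names(d)))
  if (any(d$value <= 0)) abort("seeding values must be positive.")
  if (complete_only) {
    keep_times <- filter_complete_timepoints(d)
    d <- d |> filter(.data$time_months %in% keep_times)
  }
  d <- d |> filter(.data$time_months <= early_cutoff)
  if (length(unique(d$time_months)) < 2) {
    abort("need at least 2 retained time points at or before the cutoff.")
  }
  fit <- lm(log(value) ~ time_months, data = d)
  kappa <- unname(coef(fit)["time_months"])
  structure(
    list(kappa = kappa,
         slope_log10 = kappa / log(10),
         intercept_ln = unname(coef(fit)["(Intercept)"]),
         doubling_time_months = log(2) / kappa,
         n = nrow(d), times_used = sort(unique(d$time_months)),
         lm = fit),
    class = "mouse_fit"
  )
}

#' @export
print.mouse_fit <- function(x, ...) {
  cat("<mouse_fit>\n")
  cat(sprintf("  kappa (ln slope) = %.3g per month; log10 slope = %.3g decades/month\n",
              x$kappa, x$slope_log10))
  cat(sprintf("  doubling time: %.3g months\n", x$doubling_time_months))
  cat(sprintf("  %d points at months %s\n", x$n,
              paste(x$times_used, collapse = ", ")))
  invisible(x)
}

#' @method tidy mouse_fit
#' @export
tidy.mouse_fit <- function(x, ...) {
  tibble(term = c("kappa_ln", "slope_log10", "intercept_ln"),
         estimate = c(x$kappa, x$slope_log10, x$intercept_ln))
}

#' @method glance mouse_fit
#' @export
glance.mouse_fit <- function(x, ...) {
  tibble(kappa = x$kappa, slope_log10 = x$slope_log10,
         doubling_time_months = x$doubling_time_months, n = x$n)
}

#' Doubling time implied by a printed growth rate
#'
#' A quoted exponential rate is only interpretable together with its
#' logarithm convention: a slope of 0.6 per month in natural-log units
#' implies a doubling time of ln(2)/0.6 = 1.16 months, whereas the same
#' printed number read as decades per month (a log10 slope) implies
#' log10(2)/0.6 = 0.50 months, about two weeks. This helper makes both
#' readings explicit rather than silently choosing one.
#'
#' @param rate Printed slope value.
#' @param convention `"ln"` (rate is a natural-log slope) or `"log10"`
#'   (rate is in decades per unit time).
#' @return Doubling time in the inverse units of `rate`.
#' @export
#'
#' @examples
#' doubling_time_from_printed_rate(0.6, "ln")     # ~1.2 months
#' doubling_time_from_printed_rate(0.6, "log10")  # ~0.5 months
doubling_time_from_printed_rate <- function(rate, convention = c("ln", "log10")) {
  convention <- match.arg(convention)
  if (any(rate <= 0)) abort("`rate` must be > 0.")
  if (convention == "ln") log(2) / rate else log10(2) / rate
}
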