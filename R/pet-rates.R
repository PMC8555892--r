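#' Annualised rate of signal change from a PET visit pair
#'
#' For two SUVr measurements roughly two years apart, the annual rate of
#' change r = (S2 - S1) / interval is used as an estimate of dS/dt, and
#' the signal S is approximated by the average of the two visits.
#'
#' @param records Data frame with columns `S1`, `S2` (> 0) and
#'   `interval_years` (> 0); other columns (e.g. `subject`, `group`)
#'   are carried through.
#' @return The input tibble with `S_avg` and `rate` columns appended.
#' @export
#'
#' @examples
#' annual_rate(tibble::tibble(S1 = 1.0, S2 = 1.2, interval_years = 2))
annual_rate <- function(records) {
  r <- as_tibble(records)
  stopifnot(all(c("S1", "S2", "interval_years") %in% names(r)))
  if (any(r$S1 <= 0 | r$S2 <= 0)) abort("SUVr values must be positive.")
  if (any(r$interval_years <= 0)) abort("visit intervals must be positive.")
  r |> mutate(S_avg = (.data$S1 + .data$S2) / 2,
              rate = (.data$S2 - .data$S1) / .data$interval_years)
}

#' Differentiated logistic rate model for PET signal
#'
#' The rate of SUVr change implied by the logistic accumulation model
#' with baseline b and scale alpha:
#' r(S) = (kappa / alpha) (S - b) (alpha - (S - b)).
#' The rate vanishes at S = b and S = b + alpha and peaks at
#' kappa * alpha / 4 at the midpoint S = b + alpha / 2.
#'
#' @param S Signal (SUVr); vectorised.
#' @param kappa Replication rate, per year.
#' @param alpha Signal scale (plateau above baseline).
#' @param b Baseline signal.
#' @return Rate of change, signal units per year.
#' @export
rate_model <- function(S, kappa, alpha, b) {
  (kappa / alpha) * (S - b) * (alpha - (S - b))
}

#' Fit the rate-versus-signal PET model
#'
#' Constrained least squares of the differentiated logistic model to
#' (S_avg, rate) pairs from longitudinal PET records: kappa > 0, b > 0,
#' and alpha bounded above by `alpha_max` (default 4 SUVr, a
#' conservative ceiling on the plateau height above baseline; the fit
#' reports whether alpha lands on this bound).
#'
#' @param records Data frame accepted by [annual_rate()], or one that
#'   already has `S_avg` and `rate` columns.
#' @param alpha_max Upper bound on alpha (default 4).
#' @param weights Optional per-record weights for the squared error
#'   (default unweighted).
#' @return A `pet_fit`: list with `kappa`, `alpha`, `b`, `residual`,
#'   `alpha_at_bound`, `degenerate`, `n`, and the data used.
#' @export
#'
#' @examples
#' fit_pet(gen_pet_cohort(seed = 1))
fit_pet <- function(records, alpha_max = 4, weights = NULL) {
  r <- as_tibble(records)
  if (!all(c("S_avg", "rate") %in% names(r))) r <- annual_rate(r)
  if (length(unique(r$S_avg)) < 3) {
    abort("need at least 3 records with distinct average signal.")
  }
  w <- weights %||% rep(1, nrow(r))
  degenerate <- all(r$rate == 0)

  sse <- function(par) {
    k <- exp(par[1]); a <- par[2]; b <- exp(par[3])
    sum(w * (rate_model(r$S_avg, k, a, b) - r$rate)^2)
  }
  lower <- c(log(1e-6), 1e-3, log(1e-3))
  upper <- c(log(10), alpha_max, log(max(r$S_avg)))
  starts <- expand.grid(k = log(c(0.02, 0.1, 0.3, 1)),
                        a = alpha_max * c(0.3, 0.6, 1),
                        b = log(pmax(min(r$S_avg) * c(0.5, 0.9), 1.1e-3)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("PET fit failed to converge from any start.")
  kappa <- exp(best$par[1]); alpha <- best$par[2]; b <- exp(best$par[3])
  structure(
    list(kappa = kappa, alpha = alpha, b = b, residual = best$value,
         alpha_at_bound = abs(alpha - alpha_max) < 1e-4 * alpha_max,
         kappa_at_bound = abs(best$par[1] - lower[1]) < 1e-6,
         degenerate = degenerate, alpha_max = alpha_max, n = nrow(r),
         data = r),
    class = "pet_fit"
  )
}

#' @export
print.pet_fit <- function(x, ...) {
  cat("<pet_fit>\n")
  cat(sprintf("  kappa = %.3g /yr (doubling time %.3g yr), alpha = %.3g%s, b = %.3g\n",
              x$kappa, doubling_time(x$kappa), x$alpha,
              if (x$alpha_at_bound) " [at bound]" else "", x$b))
  cat(sprintf("  n = %d records, residual = %.4g%s\n", x$n, x$residual,
              if (x$degenerate) " [degenerate: all rates zero]" else ""))
  invisible(x)
}

#' @method tidy pet_fit
#' @export
tidy.pet_fit <- function(x, ...) {
  tibble(term = c("kappa", "alpha", "b"),
         estimate = c(x$kappa, x$alpha, x$b),
         at_bound = c(x$kappa_at_bound, x$alpha_at_bound, FALSE))
}

#' @method glance pet_fit
#' @export
glance.pet_fit <- function(x, ...) {
  tibble(kappa = x$kappa, alpha = x$alpha, b = x$b,
         doubling_time = doubling_time(x$kappa),
         alpha_at_bound = x$alpha_at_bound, degenerate = x$degenerate,
         residual = x$residual, n = x$n)
}

#' Export a PET fit as JSON
#'
#' @param fit A `pet_fit`.
#' @param path Output path; if `NULL` the JSON string is returned.
#' @return JSON string, invisibly when written.
#' @export
pet_fit_json <- function(fit, path = NULL) {
  x <- list(kappa = fit$kappa, alpha = fit$alpha, b = fit$b,
            alpha_at_bound = fit$alpha_at_bound,
            kappa_at_bound = fit$kappa_at_bound,
            degenerate = fit$degenerate, residual = fit$residual, n = fit$n)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
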