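#' Convert Braak stages to years on the Braak clock
#'
#' @param stage Character vector of stage labels (III-VI by default).
#' @param stage_times Named times from [braak_stage_times()].
#' @return Numeric vector of times in years.
#' @export
stage_to_time_years <- function(stage, stage_times = braak_stage_times()) {
  if (!all(stage %in% names(stage_times))) {
    abort("unknown stage labels; supply `stage_times` covering every stage present.")
  }
  unname(stage_times[as.character(stage)])
}

# Ensure a measurement tibble has a `time_years` column, deriving it
# from `stage` when necessary.
.with_time_years <- function(measurements, stage_times = braak_stage_times()) {
  m <- as_tibble(measurements)
  if (!"time_years" %in% names(m) || (nrow(m) > 0 && all(is.na(m$time_years)))) {
    if (!"stage" %in% names(m)) {
      abort("measurements need either a `time_years` or a `stage` column.")
    }
    m$time_years <- stage_to_time_years(m$stage, stage_times)
  }
  if (any(!is.finite(m$time_years))) abort("measurement times must be finite.")
  m
}

#' Estimate the measurement noise SD from repeat measurements
#'
#' Pools the within-group standard deviation of log10 values over
#' replicate groups (rows sharing subject, region and time point), the
#' noise scale used in the likelihood of [posterior_grid()].
#'
#' @param measurements Data frame with columns `value` (> 0) and any of
#'   `subject`, `region`, `stage`/`time_years`; rows sharing all of
#'   these form a replicate group.
#' @return Pooled SD of log10 signal. Zero (all replicates identical)
#'   is returned with a degeneracy warning.
#' @export
estimate_noise_sd <- function(measurements) {
  m <- as_tibble(measurements)
  if (any(m$value <= 0)) abort("values must be positive to be log-transformed.")
  keys <- intersect(c("subject", "region", "stage", "time_years", "assay"),
                    names(m))
  grp <- m |>
    group_by(across(all_of(keys))) |>
    summarise(n = dplyr::n(),
              ss = sum((log10(.data$value) - mean(log10(.data$value)))^2),
              .groups = "drop") |>
    filter(.data$n >= 2)
  if (nrow(grp) == 0) {
    abort(paste("no replicate groups of size >= 2 found;",
                "pass an explicit noise SD instead."))
  }
  sdev <- sqrt(sum(grp$ss) / sum(grp$n - 1))
  if (sdev == 0) warn("all replicates identical: estimated noise SD is 0 (degenerate).")
  sdev
}

#' Posterior grid specification
#'
#' Defaults follow the inference scheme for seed time courses: a
#' log-spaced replication-rate axis on `[1e-3, 10]` per year with a 1/x
#' prior, a log-spaced initial-fraction axis on `[1e-10, 0.01]`
#' (between roughly one seed per brain and 1% of the final seed
#' concentration) with a 1/x prior, and a flat prior for the signal
#' scale alpha on `[max observed value, alpha_factor * max]` (alpha is
#' the plateau signal, so it must exceed every observation; the default
#' upper factor 10 was set by simulation-based calibration of the
#' combined posterior, see the methods vignette). The alpha axis is
#' log-spaced for resolution but its prior weights are proportional to
#' the cell widths, keeping the prior flat in alpha itself.
#'
#' @param n_kappa,n_f0,n_alpha Grid sizes (default 240, 80, 60; the
#'   kappa axis is fine enough that discretisation error stays below
#'   the width of posteriors combined across six regions).
#' @param kappa_bounds,f0_bounds,alpha_bounds Axis bounds;
#'   `alpha_bounds = NULL` means `[max observed, alpha_factor * max]`.
#' @param alpha_factor Upper bound of the flat alpha prior relative to
#'   the largest observation (default 10).
#' @return A `grid_spec` list.
#' @export
posterior_grid_spec <- function(n_kappa = 240, n_f0 = 80, n_alpha = 60,
                                kappa_bounds = c(1e-3, 10),
                                f0_bounds = c(1e-10, 1e-2),
                                alpha_bounds = NULL, alpha_factor = 10) {
  if (f0_bounds[1] < 1e-10 || f0_bounds[2] > 1e-2) {
    abort("`f0_bounds` must lie within [1e-10, 1e-2].")
  }
  structure(list(n_kappa = n_kappa, n_f0 = n_f0, n_alpha = n_alpha,
                 kappa_bounds = kappa_bounds, f0_bounds = f0_bounds,
                 alpha_bounds = alpha_bounds, alpha_factor = alpha_factor),
            class = "grid_spec")
}

.log_axis <- function(bounds, n) exp(seq(log(bounds[1]), log(bounds[2]), length.out = n))

# Trapezoid cell widths on an arbitrary increasing axis.
.cell_widths <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

#' Grid posterior for the logistic replication model
#'
#' Evaluates the posterior density of (kappa, f0, alpha) for the
#' logistic signal model S(t) = alpha f0 e^(kappa t) / (1 - f0 +
#' f0 e^(kappa t)) under Gaussian noise of SD `sigma` on log10 signal,
#' with a 1/x prior for kappa and f0 and a flat prior for alpha, on the
#' grid given by `spec`. When the measurements carry more than one
#' region label, each region is analysed separately (one grid per
#' region, returned as a named list of grids).
#'
#' @param measurements Data frame with `value` (> 0) and `time_years`
#'   (or `stage`, converted with `stage_times`); optional `region`.
#' @param sigma Noise SD on log10 signal, > 0 (see
#'   [estimate_noise_sd()]).
#' @param spec A [posterior_grid_spec()].
#' @param stage_times Braak clock used for `stage` columns.
#' @param likelihood_space `"log10"` (default) or `"linear"`: scale on
#'   which the Gaussian noise model is evaluated.
#'
#' @return A `tau_posterior_grid` (fields `kappa_axis`, `f0_axis`,
#'   `alpha_axis`, `mass` array summing to 1, `sigma`, `n_obs`, `meta`),
#'   or a named list of them (class `tau_posterior_set`) with one entry
#'   per region.
#' @export
posterior_grid <- function(measurements, sigma, spec = posterior_grid_spec(),
                           stage_times = braak_stage_times(),
                           likelihood_space = c("log10", "linear")) {
  likelihood_space <- match.arg(likelihood_space)
  if (!is.null(sigma) && sigma <= 0) abort("`sigma` must be > 0.")
  m <- .with_time_years(measurements, stage_times)
  if (any(m$value <= 0)) abort("values must be positive.")
  if ("region" %in% names(m) && length(unique(m$region)) > 1) {
    grids <- m |>
      split(m$region) |>
      purrr::map(~ posterior_grid(.x, sigma, spec, stage_times, likelihood_space))
    return(structure(grids, class = "tau_posterior_set"))
  }
  .posterior_grid_one(m, sigma, spec, likelihood_space)
}

.posterior_grid_one <- function(m, sigma, spec, likelihood_space) {
  kappa <- .log_axis(spec$kappa_bounds, spec$n_kappa)
  f0 <- .log_axis(spec$f0_bounds, spec$n_f0)
  alpha_bounds <- spec$alpha_bounds %||%
    (max(m$value) * c(1, spec$alpha_factor %||% 10))
  alpha <- .log_axis(alpha_bounds, spec$n_alpha)

  nk <- length(kappa); nf <- length(f0); na <- length(alpha)
  u_times <- sort(unique(m$time_years))
  t_idx <- match(m$time_years, u_times)
  obs_log <- log10(m$value)
  n_obs <- nrow(m)

  # log10 f(t) for every (kappa, f0) pair at each distinct time
  kk <- rep(kappa, times = nf)              # pair index: kappa fastest
  ll0 <- rep(log(f0) - log1p(-f0), each = nk)
  log10f <- vapply(u_times, function(t) {
    stats::plogis(ll0 + kk * t, log.p = TRUE) / log(10)
  }, numeric(nk * nf))                      # (nk*nf) x n_times

  log_alpha <- log10(alpha)
  if (likelihood_space == "log10") {
    A <- matrix(obs_log, nrow = nk * nf, ncol = n_obs, byrow = TRUE) -
      log10f[, t_idx, drop = FALSE]
    Sa <- rowSums(A)
    Saa <- rowSums(A^2)
    # SSE(pair, alpha) = Saa - 2 c Sa + n c^2 with c = log10 alpha
    loglik <- -(outer(Saa, rep(1, na)) - 2 * outer(Sa, log_alpha) +
                  n_obs * outer(rep(1, nk * nf), log_alpha^2)) / (2 * sigma^2)
  } else {
    f_lin <- 10^log10f[, t_idx, drop = FALSE]
    loglik <- matrix(NA_real_, nk * nf, na)
    for (j in seq_len(na)) {
      R <- alpha[j] * f_lin -
        matrix(m$value, nrow = nk * nf, ncol = n_obs, byrow = TRUE)
      loglik[, j] <- -rowSums(R^2) / (2 * sigma^2)
    }
  }

  # prior x cell-volume weights: 1/x priors on log-spaced kappa/f0 axes
  # give uniform weights; the flat alpha prior weights by cell width.
  w_alpha <- .cell_widths(alpha)
  lw <- sweep(loglik, 2, log(w_alpha), `+`)
  lw <- lw - max(lw)
  mass <- array(exp(lw), dim = c(nk, nf, na))
  mass <- mass / sum(mass)

  meta <- list(warnings = character())
  edge <- sum(mass[c(1, nk), , ]) + sum(mass[, c(1, nf), ]) + sum(mass[, , c(1, na)])
  if (edge > 0.01) {
    meta$warnings <- sprintf(
      "%.1f%% of posterior mass sits on the grid boundary; widen the bounds or refine the grid.",
      100 * edge)
  }
  structure(
    list(kappa_axis = kappa, f0_axis = f0, alpha_axis = alpha, mass = mass,
         sigma = sigma, n_obs = n_obs, likelihood_space = likelihood_space,
         meta = meta),
    class = "tau_posterior_grid"
  )
}

#' @export
print.tau_posterior_grid <- function(x, ...) {
  s <- posterior_summary(marginal_kappa(x))
  cat(sprintf("<tau_posterior_grid> %d x %d x %d grid, %d observations\n",
              length(x$kappa_axis), length(x$f0_axis), length(x$alpha_axis),
              x$n_obs))
  cat(sprintf("  kappa = %.3g +/- %.3g per year\n", s$mean, s$sd))
  if (length(x$meta$warnings)) cat("  note:", x$meta$warnings, "\n")
  invisible(x)
}

#' Marginal posterior of the replication rate
#'
#' Sums the grid posterior over the initial fraction and signal-scale
#' axes, leaving the 1-D posterior of kappa. Applied to a per-region set
#' it returns one marginal per region.
#'
#' @param grid A `tau_posterior_grid` or `tau_posterior_set`.
#' @return A `tau_kappa_posterior` tibble with columns `kappa`, `mass`
#'   (sums to 1) and `density` (per unit kappa); or a named list of
#'   them.
#' @export
marginal_kappa <- function(grid) {
  if (inherits(grid, "tau_posterior_set")) {
    return(purrr::map(unclass(grid), marginal_kappa))
  }
  stopifnot(inherits(grid, "tau_posterior_grid"))
  mass <- apply(grid$mass, 1, sum)
  .kappa_posterior(grid$kappa_axis, mass = mass)
}

#' Construct a 1-D replication-rate posterior
#'
#' Builds a `tau_kappa_posterior` from an axis and either cell masses
#' or a density evaluated on the axis (normalised internally). Useful
#' for combining externally derived posteriors with
#' [combine_marginals()].
#'
#' @param kappa Strictly increasing rate axis, per year.
#' @param mass Probability mass per cell (one of `mass`/`density`).
#' @param density Density per unit kappa.
#' @return A `tau_kappa_posterior` tibble.
#' @export
kappa_posterior <- function(kappa, mass = NULL, density = NULL) {
  if (is.null(mass) == is.null(density)) {
    abort("supply exactly one of `mass` or `density`.")
  }
  if (is.unsorted(kappa, strictly = TRUE)) abort("`kappa` must be strictly increasing.")
  .kappa_posterior(kappa, mass = mass, density = density)
}

.kappa_posterior <- function(kappa, mass = NULL, density = NULL) {
  w <- .cell_widths(kappa)
  if (is.null(mass)) {
    mass <- density * w
    mass <- mass / sum(mass)
  }
  mass <- mass / sum(mass)
  structure(
    tibble(kappa = kappa, mass = mass, density = mass / w),
    class = c("tau_kappa_posterior", "tbl_df", "tbl", "data.frame")
  )
}

#' Summarise a 1-D replication-rate posterior
#'
#' @param posterior A `tau_kappa_posterior`.
#' @param level Credible level (default 0.95).
#' @return A tibble with `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
posterior_summary <- function(posterior, level = 0.95) {
  k <- posterior$kappa
  w <- posterior$mass
  mu <- sum(k * w)
  sdv <- sqrt(max(sum((k - mu)^2 * w), 0))
  cdf <- cumsum(w)
  qf <- function(p) {
    i <- which(cdf >= p)[1]
    if (i == 1) return(k[1])
    k[i - 1] + (k[i] - k[i - 1]) * (p - cdf[i - 1]) / (cdf[i] - cdf[i - 1])
  }
  a <- (1 - level) / 2
  tibble(mean = mu, sd = sdv, ci_lower = qf(a), ci_upper = qf(1 - a))
}

#' @method glance tau_kappa_posterior
#' @export
glance.tau_kappa_posterior <- function(x, ...) posterior_summary(x)

#' Combine independent replication-rate posteriors
#'
#' Pointwise product of posterior densities (equal weight per
#' posterior), renormalised: the Bayesian update for independent
#' datasets constraining a common kappa. Posteriors on different grids
#' are first interpolated onto a common log-spaced axis.
#'
#' @param posteriors List of `tau_kappa_posterior` objects.
#' @param kappa_axis Optional common axis; defaults to the axis of the
#'   first posterior.
#' @return A `tau_kappa_posterior` on the common axis.
#' @export
combine_marginals <- function(posteriors, kappa_axis = NULL) {
  if (inherits(posteriors, "tau_kappa_posterior")) posteriors <- list(posteriors)
  stopifnot(length(posteriors) >= 1)
  kappa_axis <- kappa_axis %||% posteriors[[1]]$kappa
  log_dens <- rep(0, length(kappa_axis))
  for (p in posteriors) {
    d <- approx(p$kappa, p$density, xout = kappa_axis, rule = 1)$y
    d[is.na(d) | d < 0] <- 0
    log_dens <- log_dens + log(d)
  }
  if (all(!is.finite(log_dens))) {
    abort("posteriors have no common support on the combination grid.")
  }
  dens <- exp(log_dens - max(log_dens[is.finite(log_dens)]))
  dens[!is.finite(dens)] <- 0
  if (sum(dens) == 0) abort("posteriors have no common support on the combination grid.")
  .kappa_posterior(kappa_axis, density = dens)
}

#' Least-squares logistic fit to per-time medians
#'
#' Point-estimate companion to the grid posterior: fits the logistic
#' signal model to per-time medians in log10 space, for display parity
#' with the published time-course panels.
#'
#' @param times Observation times in years (>= 3 distinct values).
#' @param medians Median signal at each time, > 0.
#' @param f0_bounds,kappa_bounds Box constraints (defaults as in
#'   [posterior_grid_spec()]).
#' @return A list with `kappa`, `f0`, `alpha`, `residual`.
#' @export
lsq_median_fit <- function(times, medians,
                           kappa_bounds = c(1e-3, 10),
                           f0_bounds = c(1e-10, 1e-2)) {
  stopifnot(length(times) == length(medians))
  if (length(unique(times)) < 3) abort("need at least 3 distinct time points.")
  if (any(medians <= 0)) abort("medians must be positive.")
  obs <- log10(medians)
  sse <- function(par) {
    f <- logistic_fraction(times, exp(par[1]), stats::plogis(par[2]))
    sum((log10(exp(par[3]) * f) - obs)^2)
  }
  lower <- c(log(kappa_bounds[1]), stats::qlogis(f0_bounds[1]), log(max(medians)) - 1)
  upper <- c(log(kappa_bounds[2]), stats::qlogis(f0_bounds[2]),
             log(max(medians)) + log(1e4))
  starts <- expand.grid(k = seq(lower[1], upper[1], length.out = 5),
                        f = seq(lower[2], upper[2], length.out = 5),
                        a = log(max(medians)) + c(0.5, 2.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
            lower = lower, upper = upper, control = list(factr = 1e5)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("least-squares fit did not converge; residual trace unavailable.")
  list(kappa = exp(best$par[1]), f0 = stats::plogis(best$par[2]),
       alpha = exp(best$par[3]), residual = best$value)
}

#' Infer the replication rate from a measurement set
#'
#' End-to-end Bayesian estimate of kappa: estimates the noise SD from
#' replicates (unless given), converts Braak stages to years, evaluates
#' a grid posterior per brain region, marginalises each over f0 and
#' alpha, and combines the per-region marginals into one posterior for
#' the dataset.
#'
#' @inheritParams posterior_grid
#' @param sigma Noise SD of log10 signal; estimated with
#'   [estimate_noise_sd()] when `NULL`.
#' @return A `tau_kappa_inference`: list with `combined`
#'   (`tau_kappa_posterior`), `per_region` (named list), `summary`
#'   (tibble), `sigma`.
#' @export
#'
#' @examples
#' d <- gen_seed_dataset(seed = 1)
#' fit <- infer_kappa(d)
#' fit$summary
infer_kappa <- function(measurements, sigma = NULL,
                        spec = posterior_grid_spec(),
                        stage_times = braak_stage_times(),
                        likelihood_space = "log10") {
  m <- .with_time_years(measurements, stage_times)
  sigma <- sigma %||% estimate_noise_sd(m)
  grids <- posterior_grid(m, sigma, spec, stage_times, likelihood_space)
  if (inherits(grids, "tau_posterior_grid")) {
    grids <- structure(list(all = grids), class = "tau_posterior_set")
  }
  marginals <- marginal_kappa(grids)
  combined <- combine_marginals(marginals)
  structure(
    list(combined = combined, per_region = marginals,
         summary = posterior_summary(combined), sigma = sigma),
    class = "tau_kappa_inference"
  )
}

#' @export
print.tau_kappa_inference <- function(x, ...) {
  s <- x$summary
  cat("<tau_kappa_inference>\n")
  cat(sprintf("  combined kappa = %.3g +/- %.3g per year (95%% CI %.3g-%.3g)\n",
              s$mean, s$sd, s$ci_lower, s$ci_upper))
  cat(sprintf("  doubling time = %.3g years; %d region(s); sigma_log10 = %.3g\n",
              doubling_time(s$mean), length(x$per_region), x$sigma))
  invisible(x)
}

#' @method tidy tau_kappa_inference
#' @export
tidy.tau_kappa_inference <- function(x, ...) {
  purrr::imap(x$per_region, function(p, nm) {
    posterior_summary(p) |> mutate(region = nm, .before = 1)
  }) |> list_rbind()
}

#' @method glance tau_kappa_inference
#' @export
glance.tau_kappa_inference <- function(x, ...) {
  x$summary |> mutate(sigma = x$sigma, n_regions = length(x$per_region))
}
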