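#' Braak stage calibration constants
#'
#' Mean age at each Braak stage (years), 95% confidence intervals, and
#' the implied time to the next stage, from the constrained Gaussian fit
#' to the stage-by-age distribution of 2332 autopsy cases. These are the
#' reference constants used to place Braak-staged measurements on a
#' calendar time axis.
#'
#' @return A tibble with columns `stage`, `mean_age`, `ci_lower`,
#'   `ci_upper`, `duration` (years to next stage; NA for stage VI).
#' @export
#'
#' @examples
#' braak_reference_ages()
braak_reference_ages <- function() {
  tibble(
    stage = c("I", "II", "III", "IV", "V", "VI"),
    mean_age = c(51, 70, 84, 105, 113, 118),
    ci_lower = c(45.3, 65.7, 82.2, 103.3, 108.4, 115.3),
    ci_upper = c(57.1, 73.9, 86.2, 106.5, 116.6, 120.9),
    duration = c(19, 14, 21, 8, 5, NA)
  )
}

#' Cumulative Braak clock
#'
#' Observation times (years) for Braak stages on a clock anchored at a
#' reference stage (default III, the point from which neocortical
#' accumulation is modelled): consecutive differences of the fitted mean
#' ages, accumulated from the anchor.
#'
#' @param means Named vector of per-stage mean ages; default the
#'   reference constants of [braak_reference_ages()].
#' @param anchor Stage defining t = 0 (default `"III"`).
#' @param stages Stages to report (default anchor onwards).
#' @return Named numeric vector of times in years.
#' @export
#'
#' @examples
#' braak_stage_times()   # III = 0, IV = 21, V = 29, VI = 34
braak_stage_times <- function(means = NULL, anchor = "III", stages = NULL) {
  if (is.null(means)) {
    ref <- braak_reference_ages()
    means <- setNames(ref$mean_age, ref$stage)
  }
  if (!anchor %in% names(means)) abort("`anchor` must be one of the stages in `means`.")
  times <- means - means[[anchor]]
  stages <- stages %||% names(means)[means >= means[[anchor]]]
  times[stages]
}

#' Conditional Braak stage distribution given age
#'
#' Normalises a stage-by-age count table within each age bin, yielding
#' the probability of being at each Braak stage given the age decade.
#' Empty age bins are dropped with a warning.
#'
#' @param table Data frame with columns `age_bin` (e.g. `"61-70"`),
#'   `stage`, and `count` (long format), or the object returned by
#'   [gen_stage_age_table()].
#' @return A tibble with columns `age_bin`, `age_mid` (bin midpoint in
#'   years), `stage`, `prob`; probabilities sum to 1 within each bin.
#' @export
conditional_stage_given_age <- function(table) {
  tab <- as_tibble(table)
  stopifnot(all(c("age_bin", "stage", "count") %in% names(tab)))
  if (any(tab$count < 0)) abort("counts must be nonnegative.")
  if (sum(tab$count) == 0) abort("the stage-by-age table is all zero.")
  totals <- tab |> group_by(.data$age_bin) |> summarise(n = sum(.data$count))
  empty <- totals$age_bin[totals$n == 0]
  if (length(empty)) {
    warn(paste("dropping empty age bins:", paste(empty, collapse = ", ")))
    tab <- tab |> filter(!.data$age_bin %in% empty)
  }
  tab |>
    group_by(.data$age_bin) |>
    mutate(prob = .data$count / sum(.data$count)) |>
    ungroup() |>
    mutate(age_mid = .age_bin_midpoint(.data$age_bin)) |>
    select("age_bin", "age_mid", "stage", "prob")
}

# "61-70" -> 65.5
.age_bin_midpoint <- function(bin) {
  parts <- strsplit(as.character(bin), "-", fixed = TRUE)
  vapply(parts, function(p) mean(as.numeric(p)), numeric(1))
}

.BRAAK_FIT_STAGES <- c("I", "II", "III", "IV", "V", "VI")

#' Fit constrained Gaussians to the stage-age distribution
#'
#' Models the probability of being at Braak stage s given age as a
#' Gaussian curve A exp(-(age - m_s)^2 / (2 sigma^2)) with a shared
#' amplitude A and SD sigma. Phase 1 fits (A, sigma) jointly with the
#' means of stages I-III, whose distributions are fully visible below
#' age 100. Phase 2 freezes (A, sigma) and fits the means of stages
#' IV-VI one at a time; because the model is evaluated only on the
#' observed age bins (all at most 100 years), the right-truncation of
#' the data is handled by restriction, and fitted means above 100 years
#' are allowed.
#'
#' @param prob_table Output of [conditional_stage_given_age()].
#' @param max_age Upper age limit of the observed bins (default 100).
#' @return A `braak_gaussian_model`: list with `amplitude`, `sigma`,
#'   `means` (named, stages I-VI), and the per-stage residual sum of
#'   squares.
#' @export
fit_stage_gaussians <- function(prob_table, max_age = 100) {
  tab <- as_tibble(prob_table)
  stopifnot(all(c("age_mid", "stage", "prob") %in% names(tab)))
  if (!all(.BRAAK_FIT_STAGES %in% tab$stage)) {
    abort("stages I-VI must all be present in the probability table.")
  }
  tab <- tab |> filter(.data$age_mid <= max_age)
  curve <- function(age, A, sigma, m) A * exp(-(age - m)^2 / (2 * sigma^2))

  early <- c("I", "II", "III")
  dat_e <- tab |> filter(.data$stage %in% early)
  sse_early <- function(par) {
    A <- exp(par[1]); sigma <- exp(par[2]); m <- par[3:5]
    pred <- curve(dat_e$age_mid, A, sigma, m[match(dat_e$stage, early)])
    sum((pred - dat_e$prob)^2)
  }
  # moment-based starting values from the early-stage curves
  m0 <- vapply(early, function(s) {
    d <- dat_e |> filter(.data$stage == s)
    weighted.mean(d$age_mid, pmax(d$prob, 0))
  }, numeric(1))
  start <- c(log(max(dat_e$prob)), log(15), m0)
  ph1 <- optim(start, sse_early, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (ph1$convergence != 0) {
    abort(sprintf("phase 1 (shared amplitude/SD) did not converge; last SSE %.3g",
                  ph1$value))
  }
  A <- unname(exp(ph1$par[1])); sigma <- unname(exp(ph1$par[2]))
  means <- setNames(numeric(6), .BRAAK_FIT_STAGES)
  means[early] <- ph1$par[3:5]

  rss <- setNames(numeric(6), .BRAAK_FIT_STAGES)
  for (s in early) {
    d <- tab |> filter(.data$stage == s)
    rss[s] <- sum((curve(d$age_mid, A, sigma, means[s]) - d$prob)^2)
  }
  for (s in c("IV", "V", "VI")) {
    d <- tab |> filter(.data$stage == s)
    obj <- function(m) sum((curve(d$age_mid, A, sigma, m) - d$prob)^2)
    opt <- optimize(obj, interval = c(40, max_age + 8 * sigma))
    means[s] <- opt$minimum
    rss[s] <- opt$objective
  }
  if (any(diff(means) <= 0)) {
    warn("fitted stage means are not strictly increasing.")
  }
  structure(
    list(amplitude = A, sigma = sigma, means = means, rss = rss,
         max_age = max_age),
    class = "braak_gaussian_model"
  )
}

#' @export
print.braak_gaussian_model <- function(x, ...) {
  cat("<braak_gaussian_model>\n")
  cat(sprintf("  shared amplitude %.4g, SD %.3g yr\n", x$amplitude, x$sigma))
  cat("  mean ages:", paste(sprintf("%s=%.1f", names(x$means), x$means),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted Braak Gaussian model
#'
#' @param x A `braak_gaussian_model`.
#' @param ... Unused.
#' @return Tibble with one row per stage: `stage`, `mean_age`, `rss`,
#'   plus the shared `amplitude` and `sigma`.
#' @method tidy braak_gaussian_model
#' @export
tidy.braak_gaussian_model <- function(x, ...) {
  tibble(stage = names(x$means), mean_age = unname(x$means),
         rss = unname(x$rss), amplitude = x$amplitude, sigma = x$sigma)
}

#' @method glance braak_gaussian_model
#' @export
glance.braak_gaussian_model <- function(x, ...) {
  tibble(amplitude = x$amplitude, sigma = x$sigma, total_rss = sum(x$rss))
}

#' Duration of each Braak stage
#'
#' Consecutive differences of the per-stage mean ages: the average time
#' spent in each stage before progressing to the next.
#'
#' @param model_or_means A `braak_gaussian_model` or a named numeric
#'   vector of increasing mean ages.
#' @return Named numeric vector of durations in years (one fewer entry
#'   than stages; named after the stage being left).
#' @export
#'
#' @examples
#' ref <- braak_reference_ages()
#' stage_durations(setNames(ref$mean_age, ref$stage))  # 19 14 21 8 5
stage_durations <- function(model_or_means) {
  means <- if (inherits(model_or_means, "braak_gaussian_model")) {
    model_or_means$means
  } else {
    model_or_means
  }
  if (any(diff(means) <= 0)) abort("stage mean ages must be strictly increasing.")
  setNames(diff(means), head(names(means), -1))
}
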