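#' Spatial geometry for the reaction-diffusion model
#'
#' Two geometries are supported: a 1-D `"interval"` discretised on a
#' regular grid, and a `"region_chain"` of equally spaced brain regions
#' (default the six regions sampled with increasing synaptic distance
#' from the entorhinal cortex: EC, H, PHG, AC, VA, PV).
#'
#' @param kind `"interval"` or `"region_chain"`.
#' @param n_points Number of grid points (default 201 for interval, the
#'   number of region labels for region_chain).
#' @param r_max Total domain length (default 1 for interval; for a region
#'   chain, `spacing * (n_points - 1)` with unit spacing).
#' @param region_labels Ordered region names for `region_chain`.
#'
#' @return A `fkpp_geometry` object with fields `kind`, `n_points`,
#'   `spacing`, `r_max`, `region_labels`, `x` (node coordinates).
#' @export
#'
#' @examples
#' fkpp_geometry("interval", n_points = 101)
#' fkpp_geometry("region_chain")
fkpp_geometry <- function(kind = c("interval", "region_chain"),
                          n_points = NULL, r_max = NULL,
                          region_labels = c("EC", "H", "PHG", "AC", "VA", "PV")) {
  kind <- match.arg(kind)
  if (kind == "region_chain") {
    if (anyDuplicated(region_labels)) abort("region labels must be unique.")
    n_points <- n_points %||% length(region_labels)
    if (n_points != length(region_labels)) {
      abort("`n_points` must equal the number of region labels.")
    }
    r_max <- r_max %||% (n_points - 1)
  } else {
    n_points <- n_points %||% 201L
    r_max <- r_max %||% 1
    region_labels <- NULL
  }
  if (n_points < 2) abort("`n_points` must be >= 2.")
  spacing <- r_max / (n_points - 1)
  structure(
    list(kind = kind, n_points = as.integer(n_points), spacing = spacing,
         r_max = r_max, region_labels = region_labels,
         x = seq(0, r_max, length.out = n_points)),
    class = "fkpp_geometry"
  )
}

#' @export
print.fkpp_geometry <- function(x, ...) {
  cat(sprintf("<fkpp_geometry> %s: %d points, spacing %g, r_max %g\n",
              x$kind, x$n_points, x$spacing, x$r_max))
  if (!is.null(x$region_labels)) {
    cat("  regions:", paste(x$region_labels, collapse = " - "), "\n")
  }
  invisible(x)
}

# Path-graph Laplacian with zero-flux (Neumann) boundaries, scaled by
# 1/spacing^2. Symmetric with zero row sums, so pure diffusion conserves
# the total seed mass.
.fkpp_laplacian <- function(geometry) {
  n <- geometry$n_points
  h2 <- geometry$spacing^2
  main <- c(-1, rep(-2, n - 2), -1) / h2
  off <- rep(1, n - 1) / h2
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(off, main, off), symmetric = FALSE)
}

#' Solve the seed replication-spreading equation
#'
#' Numerically integrates the logistic reaction-diffusion equation
#' df/dt = D Laplacian(f) + kappa f (1 - f) with zero-flux boundaries,
#' by Strang splitting: the local logistic reaction is advanced with its
#' exact solution and the diffusion half is advanced implicitly
#' (backward Euler on a sparse Cholesky factor). A spatially uniform
#' field therefore follows the closed-form logistic exactly, and pure
#' diffusion conserves total mass.
#'
#' @param initial_profile Seed fractions in `[0, 1]`, one per grid point.
#' @param D Diffusion coefficient (length^2 per time, in the geometry's
#'   length unit).
#' @param kappa Replication rate (per time).
#' @param geometry A [fkpp_geometry()].
#' @param t_grid Increasing output times starting at 0.
#' @param dt Internal time step; defaults to an accuracy-based step
#'   (reaction resolved to kappa*dt <= 0.05 and the front advancing at
#'   most half a grid cell per step). Supplying a larger `dt` is an
#'   error naming the maximum stable step.
#'
#' @return A `fkpp_trajectory`: list with `times`, `profiles` (matrix,
#'   time x node), `geometry`, `D`, `kappa`.
#' @export
#'
#' @examples
#' geo <- fkpp_geometry("interval", n_points = 51)
#' tr <- fkpp_simulate(rep(0.01, 51), D = 0.001, kappa = 0.17, geo,
#'                     t_grid = seq(0, 10, by = 1))
fkpp_simulate <- function(initial_profile, D, kappa, geometry, t_grid,
                          dt = NULL) {
  stopifnot(inherits(geometry, "fkpp_geometry"))
  n <- geometry$n_points
  if (length(initial_profile) != n) {
    abort("`initial_profile` length must match the geometry.")
  }
  if (any(initial_profile < 0 | initial_profile > 1)) {
    abort("initial seed fractions must lie in [0, 1].")
  }
  if (D < 0) abort("`D` must be >= 0.")
  t_grid <- as.numeric(t_grid)
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE)) {
    abort("`t_grid` must start at 0 and be strictly increasing.")
  }

  dt_max <- .fkpp_dt_max(D, kappa, geometry)
  if (is.null(dt)) {
    dt <- dt_max
  } else if (dt > dt_max * (1 + 1e-12)) {
    abort(sprintf(
      "time step %g exceeds the maximum accurate step %g for this scheme.",
      dt, dt_max))
  }

  L <- .fkpp_laplacian(geometry)
  profiles <- matrix(NA_real_, nrow = length(t_grid), ncol = n)
  f <- as.numeric(initial_profile)
  profiles[1, ] <- f
  t_now <- 0

  solve_diff <- .fkpp_diffusion_solver(L, D)

  for (i in seq_along(t_grid)[-1]) {
    span <- t_grid[i] - t_now
    n_sub <- max(1L, ceiling(span / dt))
    h <- span / n_sub
    step <- solve_diff(h)
    for (s in seq_len(n_sub)) {
      f <- .logistic_step(f, kappa, h / 2)
      f <- step(f)
      f <- .logistic_step(f, kappa, h / 2)
    }
    f <- pmin(pmax(f, 0), 1)
    profiles[i, ] <- f
    t_now <- t_grid[i]
  }

  structure(
    list(times = t_grid, profiles = profiles, geometry = geometry,
         D = D, kappa = kappa),
    class = "fkpp_trajectory"
  )
}

# Accuracy-based default step: resolve the reaction and keep the front
# from crossing more than half a cell per step. Diffusion is implicit,
# so there is no hard stability bound; this is the accuracy criterion
# the solver enforces.
.fkpp_dt_max <- function(D, kappa, geometry) {
  dts <- Inf
  if (kappa > 0) dts <- c(dts, 0.05 / kappa)
  if (D > 0 && kappa > 0) {
    dts <- c(dts, geometry$spacing / (2 * front_speed(D, kappa)))
  } else if (D > 0) {
    dts <- c(dts, geometry$spacing^2 / (2 * D))
  }
  min(dts)
}

# Exact integrator of df/dt = kappa f (1 - f) over a step h, on the
# log-odds scale (exact for f in {0, 1} as well).
.logistic_step <- function(f, kappa, h) {
  if (kappa == 0 || h == 0) return(f)
  interior <- f > 0 & f < 1
  out <- f
  fi <- f[interior]
  out[interior] <- stats::plogis(log(fi) - log1p(-fi) + kappa * h)
  out
}

# Returns a closure caching the solve of (I - h D L) per step size h:
# a dense inverse for small grids (region chains), a sparse Cholesky
# factor otherwise.
.fkpp_diffusion_solver <- function(L, D) {
  n <- nrow(L)
  I <- Matrix::Diagonal(n)
  cache_h <- NA_real_
  cache_solve <- NULL
  function(h) {
    if (D == 0) return(identity)
    if (!identical(h, cache_h)) {
      A <- I - h * D * L
      if (n <= 64) {
        Ainv <- solve(as.matrix(A))
        cache_solve <<- function(f) drop(Ainv %*% f)
      } else {
        fac <- Matrix::Cholesky(Matrix::forceSymmetric(A))
        cache_solve <<- function(f) as.numeric(Matrix::solve(fac, f))
      }
      cache_h <<- h
    }
    cache_solve
  }
}

#' @export
print.fkpp_trajectory <- function(x, ...) {
  cat(sprintf("<fkpp_trajectory> %d times on [%g, %g], %d nodes (D = %g, kappa = %g)\n",
              length(x$times), min(x$times), max(x$times),
              x$geometry$n_points, x$D, x$kappa))
  invisible(x)
}

#' Tidy a simulated trajectory
#'
#' @param x A `fkpp_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `node`, `x` (coordinate),
#'   `region` (for region chains) and `f`.
#' @method tidy fkpp_trajectory
#' @export
tidy.fkpp_trajectory <- function(x, ...) {
  geo <- x$geometry
  out <- tidyr::expand_grid(time = x$times, node = seq_len(geo$n_points))
  out$x <- geo$x[out$node]
  # profiles is time x node; expand_grid is time-major with node fastest
  out$f <- as.vector(t(x$profiles))
  if (!is.null(geo$region_labels)) out$region <- geo$region_labels[out$node]
  out
}

#' Classify the rate-limiting regime of a trajectory
#'
#' At the first time the spatial mean of the seed fraction crosses 0.5,
#' the heterogeneity index chi is the fraction of grid points still
#' essentially seed-free (f < `low`). A large chi means a propagation
#' front is still sweeping the volume (spreading-limited); a small chi
#' means seeds were present everywhere before saturation
#' (replication-limited).
#'
#' @param trajectory A `fkpp_trajectory`.
#' @param low Seed-free threshold on f (default 0.05).
#' @param occupancy chi above which the system is labelled
#'   spreading-limited (default 0.25); chi below `low` is labelled
#'   replication-limited, otherwise intermediate.
#'
#' @return A list with `label` (one of `"spreading_limited"`,
#'   `"replication_limited"`, `"intermediate"`), `chi`, and
#'   `t_half_mean`, the crossing time.
#' @export
classify_regime <- function(trajectory, low = 0.05, occupancy = 0.25) {
  stopifnot(inherits(trajectory, "fkpp_trajectory"))
  means <- rowMeans(trajectory$profiles)
  idx <- which(means >= 0.5)
  if (length(idx) == 0) {
    abort("inconclusive: the spatial mean never reaches 0.5 on the simulated horizon.")
  }
  i <- idx[1]
  chi <- mean(trajectory$profiles[i, ] < low)
  label <- if (chi > occupancy) {
    "spreading_limited"
  } else if (chi < low) {
    "replication_limited"
  } else {
    "intermediate"
  }
  list(label = label, chi = chi, t_half_mean = trajectory$times[i])
}

#' Track the position of the f = level front
#'
#' Linear interpolation of the rightmost downward crossing of `level` in
#' each stored profile; used to measure front speeds.
#'
#' @param trajectory A `fkpp_trajectory`.
#' @param level Level-set value (default 0.5).
#' @return A tibble with `time` and `position` (NA where the profile
#'   never crosses the level).
#' @export
front_position <- function(trajectory, level = 0.5) {
  geo <- trajectory$geometry
  pos <- apply(trajectory$profiles, 1, function(p) {
    above <- p >= level
    if (all(above) || all(!above)) return(NA_real_)
    i <- max(which(above[-length(above)] & !above[-1]))
    x1 <- geo$x[i]; x2 <- geo$x[i + 1]
    x1 + (x2 - x1) * (p[i] - level) / (p[i] - p[i + 1])
  })
  tibble(time = trajectory$times, position = pos)
}

#' Measure the front speed of a simulated trajectory
#'
#' Estimates the asymptotic speed of the f = `level` level set over the
#' window where the front lies in the interior of the domain (between
#' `margin` and `1 - margin` of r_max). Pulled logistic fronts approach
#' their asymptotic speed 2 sqrt(D kappa) with a slow logarithmic
#' transient (the front position behaves like v t - c log t), so by
#' default the fit is position ~ time + log(time) and the time
#' coefficient is reported; `log_correction = FALSE` gives the plain
#' average speed instead.
#'
#' @param trajectory A `fkpp_trajectory`.
#' @param level Level-set value (default 0.5).
#' @param margin Interior fraction excluded at each end (default 0.15).
#' @param log_correction Absorb the logarithmic transient (default TRUE).
#' @return Estimated speed (length per time).
#' @export
measure_front_speed <- function(trajectory, level = 0.5, margin = 0.15,
                                log_correction = TRUE) {
  fp <- front_position(trajectory, level)
  r <- trajectory$geometry$r_max
  keep <- !is.na(fp$position) & fp$time > 0 &
    fp$position > margin * r & fp$position < (1 - margin) * r
  if (sum(keep) < 4) abort("front not tracked long enough to measure a speed.")
  d <- fp[keep, ]
  fit <- if (log_correction) {
    lm(position ~ time + log(time), data = d)
  } else {
    lm(position ~ time, data = d)
  }
  unname(coef(fit)["time"])
}

#' Initial condition with a travelling-wave tail
#'
#' A front-like profile 1 / (1 + exp(lambda (x - x0))) with the pulled
#' front's decay rate lambda = sqrt(kappa / D). Launched from this
#' profile the front moves at its asymptotic speed 2 sqrt(D kappa) from
#' the start, avoiding the slow logarithmic transient that follows a
#' steep initial condition.
#'
#' @param geometry A [fkpp_geometry()].
#' @param D,kappa Model parameters, > 0.
#' @param x0 Initial front position (default `0.1 * r_max`).
#' @return Numeric initial profile.
#' @export
front_initial_condition <- function(geometry, D, kappa,
                                    x0 = 0.1 * geometry$r_max) {
  lambda <- sqrt(kappa / D)
  1 / (1 + exp(pmin(lambda * (geometry$x - x0), 700)))
}

#' Compact Gaussian bump initial condition
#'
#' @param geometry A [fkpp_geometry()].
#' @param amplitude Peak seed fraction (default 1e-3).
#' @param width SD of the bump relative to r_max (default 0.01).
#' @param center Bump centre (default mid-domain).
#' @return Numeric initial profile.
#' @export
bump_initial_condition <- function(geometry, amplitude = 1e-3, width = 0.01,
                                   center = 0.5 * geometry$r_max) {
  w <- width * geometry$r_max
  amplitude * exp(-(geometry$x - center)^2 / (2 * w^2))
}
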