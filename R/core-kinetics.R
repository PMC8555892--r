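#' Kinetic parameter bundle
#'
#' Container for the parameters of the logistic replication model and its
#' reaction-diffusion extension: the effective replication rate `kappa`
#' (per year for human data, per month for mouse data), the effective
#' diffusion coefficient `D` (length^2 per time), the initial seed fraction
#' `f0`, the signal scale `alpha` that converts seed fraction to assay
#' units, the additive signal baseline `b`, and the maximal seed
#' concentration `P_max` in assay units.
#'
#' @param kappa Effective replication rate, > 0.
#' @param D Effective diffusion coefficient, >= 0.
#' @param f0 Initial seed fraction, in (0, 1).
#' @param alpha Signal scale, > 0.
#' @param b Signal baseline, >= 0.
#' @param P_max Maximal seed concentration in assay units, > 0.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @export
#'
#' @examples
#' kinetic_params(kappa = 0.17, f0 = 1e-4, alpha = 100)
kinetic_params <- function(kappa, D = 0, f0 = 1e-4, alpha = 1, b = 0,
                           P_max = alpha + b) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, is.finite(kappa))
  if (kappa <= 0) abort("`kappa` must be > 0.")
  if (f0 <= 0 || f0 >= 1) abort("`f0` must lie strictly inside (0, 1).")
  if (alpha <= 0) abort("`alpha` must be > 0.")
  if (b < 0) abort("`b` must be >= 0.")
  if (D < 0) abort("`D` must be >= 0.")
  structure(
    list(kappa = kappa, D = D, f0 = f0, alpha = alpha, b = b, P_max = P_max),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  cat(sprintf("  kappa = %g per unit time (doubling time %.3g)\n",
              x$kappa, doubling_time(x$kappa)))
  cat(sprintf("  D = %g, f0 = %g, alpha = %g, b = %g, P_max = %g\n",
              x$D, x$f0, x$alpha, x$b, x$P_max))
  invisible(x)
}

#' Logistic seed fraction
#'
#' Closed-form solution of the logistic growth equation
#' df/dt = kappa f (1 - f), the replication-limited limit of the
#' reaction-diffusion model: f(t) = f0 e^(kappa t) / (1 - f0 + f0 e^(kappa t)).
#'
#' @param t Time (same inverse units as `kappa`); vectorised.
#' @param kappa Replication rate.
#' @param f0 Initial seed fraction, in (0, 1).
#'
#' @return Seed fraction in (0, 1), same length as `t`.
#' @export
#'
#' @examples
#' logistic_fraction(0, 0.17, 0.01)     # initial condition
#' logistic_fraction(34, 0.17, 1e-4)    # Braak VI on the Braak clock
logistic_fraction <- function(t, kappa, f0) {
  if (any(f0 <= 0 | f0 >= 1)) abort("`f0` must lie strictly inside (0, 1).")
  stopifnot(all(is.finite(kappa)))
  # computed on the log-odds scale for numerical stability at large kappa*t
  logit0 <- log(f0) - log1p(-f0)
  stats::plogis(logit0 + kappa * t)
}

#' Assay signal from seed fraction
#'
#' Affine map from seed fraction to measured signal, S = alpha * f + b.
#'
#' @param f Seed fraction.
#' @param alpha Signal scale, > 0.
#' @param b Signal baseline, >= 0 (default 0).
#'
#' @return Signal in assay units, in `[b, alpha + b]`.
#' @export
signal_from_fraction <- function(f, alpha, b = 0) {
  if (any(alpha <= 0)) abort("`alpha` must be > 0.")
  if (any(b < 0)) abort("`b` must be >= 0.")
  alpha * f + b
}

#' Seed doubling time
#'
#' Time for the seed number to double during exponential growth,
#' t2 = ln(2) / kappa.
#'
#' @param kappa Replication rate, > 0.
#' @return Doubling time in the inverse units of `kappa`.
#' @export
#'
#' @examples
#' doubling_time(0.14)  # ~5 years
#' doubling_time(0.17)  # ~4 years
doubling_time <- function(kappa) {
  if (any(kappa <= 0)) abort("`kappa` must be > 0.")
  log(2) / kappa
}

#' Fold increase of seed number
#'
#' Exponential-phase fold change e^(kappa t) over a time interval.
#'
#' @param kappa Replication rate.
#' @param t Elapsed time.
#' @return Dimensionless fold increase.
#' @export
fold_increase <- function(kappa, t) exp(kappa * t)

#' Decompose replication into growth and multiplication
#'
#' The effective replication rate is the geometric mean of the growth and
#' multiplication rates, kappa = sqrt(k_growth * k_mult), while the mean
#' aggregate size (in monomers) is their ratio, mu = sqrt(k_growth /
#' k_mult). Given kappa and mu this inverts to k_growth = mu * kappa and
#' k_mult = kappa / mu.
#'
#' @param kappa Replication rate, > 0.
#' @param mu Mean aggregate size in monomer units, >= 1.
#'
#' @return A `rate_decomposition` object: list with `k_growth`, `k_mult`,
#'   `mu`, `kappa`.
#' @export
#'
#' @examples
#' decompose_rates(0.14, 750)
decompose_rates <- function(kappa, mu) {
  if (any(kappa <= 0)) abort("`kappa` must be > 0.")
  if (any(mu < 1)) abort("`mu` must be >= 1.")
  structure(
    list(k_growth = mu * kappa, k_mult = kappa / mu, mu = mu, kappa = kappa),
    class = "rate_decomposition"
  )
}

#' Recombine growth and multiplication rates
#'
#' Inverse of [decompose_rates()]: kappa = sqrt(k_growth * k_mult),
#' mu = sqrt(k_growth / k_mult).
#'
#' @param k_growth Growth rate, > 0.
#' @param k_mult Multiplication rate, > 0.
#' @return Named list with `kappa` and `mu`.
#' @export
recombine_rates <- function(k_growth, k_mult) {
  if (any(k_growth <= 0) || any(k_mult <= 0)) {
    abort("`k_growth` and `k_mult` must be > 0.")
  }
  list(kappa = sqrt(k_growth * k_mult), mu = sqrt(k_growth / k_mult))
}

#' @export
print.rate_decomposition <- function(x, ...) {
  cat("<rate_decomposition>\n")
  cat(sprintf("  kappa = %g, mu = %g monomers\n", x$kappa, x$mu))
  cat(sprintf("  k_growth = %g, k_mult = %g\n", x$k_growth, x$k_mult))
  invisible(x)
}

#' Monomer count of a tau fibril
#'
#' Converts fibril length to monomer count from the beta-sheet layer
#' spacing (0.47 nm) and the number of tau monomers per layer (2 for the
#' paired-helical-filament fold), rounded to the nearest integer.
#'
#' @param length_nm Fibril length in nm.
#' @param layer_spacing_nm Beta-sheet layer spacing in nm (default 0.47).
#' @param monomers_per_layer Monomers per layer (default 2).
#' @return Integer monomer count.
#' @export
#'
#' @examples
#' fibril_monomer_count(176)         # 749, i.e. ~750 monomers
fibril_monomer_count <- function(length_nm, layer_spacing_nm = 0.47,
                                 monomers_per_layer = 2) {
  if (any(length_nm <= 0) || any(layer_spacing_nm <= 0) ||
      any(monomers_per_layer <= 0)) {
    abort("all arguments must be positive.")
  }
  round(monomers_per_layer * length_nm / layer_spacing_nm)
}

#' Critical diffusion coefficient for the regime switch
#'
#' For a compact initial seed distribution the switch between the
#' spreading-limited and replication-limited regimes occurs approximately
#' at D = 0.0025 * kappa * r_max^2, where r_max is the linear size of the
#' reaction volume.
#'
#' @param kappa Replication rate.
#' @param r_max Domain size (length units; the companion converters map
#'   between physical and region units).
#' @param ratio D/kappa coefficient in units of r_max^2; default 0.0025
#'   (the regime-switch value). Use 0.1 for the best-fit ratio of the
#'   regional model.
#' @return Diffusion coefficient in (length units)^2 per inverse-`kappa`
#'   time units.
#' @export
#'
#' @examples
#' critical_diffusion(0.14, 0.1)                  # m^2/yr for r_max = 10 cm
#' m2yr_to_m2s(critical_diffusion(0.14, 0.1))     # ~1e-13 m^2/s
critical_diffusion <- function(kappa, r_max, ratio = 0.0025) {
  stopifnot(all(kappa > 0), all(r_max > 0), all(ratio > 0))
  ratio * kappa * r_max^2
}

#' Unit conversions for diffusion coefficients
#'
#' Convert between m^2/year and m^2/s (year = 365.25 days = 3.15576e7 s),
#' and between physical length and region units given a region spacing.
#'
#' @param x Value to convert.
#' @param region_spacing_m Physical distance corresponding to one region
#'   spacing, in metres.
#' @return Converted value.
#' @name unit_conversions
NULL

#' @rdname unit_conversions
#' @export
m2yr_to_m2s <- function(x) x / .SECONDS_PER_YEAR

#' @rdname unit_conversions
#' @export
m2s_to_m2yr <- function(x) x * .SECONDS_PER_YEAR

#' @rdname unit_conversions
#' @export
m2_to_regions2 <- function(x, region_spacing_m) x / region_spacing_m^2

#' @rdname unit_conversions
#' @export
regions2_to_m2 <- function(x, region_spacing_m) x * region_spacing_m^2

#' Asymptotic front speed of the reaction-diffusion model
#'
#' Speed of the pulled travelling front of the logistic
#' reaction-diffusion equation, v = 2 sqrt(D * kappa): the overall time
#' scale in the spreading-limited regime is set by the geometric mean of
#' replication and spreading rates.
#'
#' @param D Diffusion coefficient, > 0.
#' @param kappa Replication rate, > 0.
#' @return Front speed in length per time.
#' @export
front_speed <- function(D, kappa) {
  stopifnot(all(D > 0), all(kappa > 0))
  2 * sqrt(D * kappa)
}

#' Serialize a kinetic parameter bundle to JSON
#'
#' Writes the parameters together with explicit unit strings so that
#' exported fits are self-describing.
#'
#' @param params A [kinetic_params()] object.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @param time_unit Unit of 1/kappa, e.g. `"year"` or `"month"`.
#' @param length_unit Length unit of sqrt(D), e.g. `"regions"` or `"m"`.
#' @return The JSON string, invisibly if written to `path`.
#' @export
kinetic_params_json <- function(params, path = NULL, time_unit = "year",
                                length_unit = "regions") {
  stopifnot(inherits(params, "kinetic_params"))
  x <- list(
    kappa = params$kappa, kappa_unit = paste0("per_", time_unit),
    D = params$D, D_unit = paste0(length_unit, "2_per_", time_unit),
    f0 = params$f0, f0_unit = "dimensionless",
    alpha = params$alpha, alpha_unit = "assay_units",
    b = params$b, b_unit = "assay_units",
    P_max = params$P_max, P_max_unit = "assay_units"
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
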