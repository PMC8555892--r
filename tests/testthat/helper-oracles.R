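# Shared fixtures built in code.

# Noiseless logistic signal S(t) = alpha * f(t; kappa, f0).
eq_signal <- function(t, kappa, f0, alpha, b = 0) {
  alpha * f0 * exp(kappa * t) / (1 - f0 + f0 * exp(kappa * t)) + b
}

# Stage-resolved regional profiles generated by the simulator itself
# (the oracle for the regional fit): returns the profile table plus the
# generating truth.
make_regional_truth <- function(D = 0.5, P_max = 1000, t_start = 8,
                                kappa = 0.14,
                                obs_III = c(300, 120, 60, 20, 8, 3)) {
  geo <- fkpp_geometry("region_chain")
  tt <- braak_stage_times()
  tau <- pmax(tt - t_start, 0)
  tr <- fkpp_simulate(pmin(obs_III / P_max, 1), D, kappa, geo,
                      sort(unique(c(0, tau))))
  prof <- do.call(rbind, lapply(names(tt), function(s) {
    data.frame(stage = s, region = geo$region_labels,
               value = if (s == "III") obs_III else
                 P_max * tr$profiles[match(tau[[s]], tr$times), ])
  }))
  list(profiles = prof, geometry = geo,
       truth = list(D = D, P_max = P_max, t_start = t_start, kappa = kappa))
}

# Discrete Gaussian density on an axis, as a tau_kappa_posterior.
gaussian_posterior <- function(mean, sd, axis = seq(1e-3, 0.5, length.out = 4000)) {
  kappa_posterior(axis, density = dnorm(axis, mean, sd))
}

# Uniform RGB image (0-255) from an HSB (0-255) triple.
uniform_hsb_image <- function(h, s, b, width = 8, height = 8) {
  col <- grDevices::hsv(h / 255, s / 255, b / 255)
  rgb <- as.integer(grDevices::col2rgb(col))
  img <- array(0, dim = c(width, height, 3))
  for (k in 1:3) img[, , k] <- rgb[k]
  img
}
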