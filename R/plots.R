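#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated seed trajectory
#'
#' Seed fraction against position, one curve per stored time.
#'
#' @param object A `fkpp_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fkpp_trajectory
#' @export
autoplot.fkpp_trajectory <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$x, y = .data$f,
                colour = .data$time, group = .data$time)) +
    geom_line() +
    labs(x = "position", y = "seed fraction f", colour = "time") +
    theme_minimal()
}

#' Plot a replication-rate posterior
#'
#' @param object A `tau_kappa_posterior`.
#' @param ... Unused.
#' @return A ggplot of posterior density against kappa (log axis).
#' @method autoplot tau_kappa_posterior
#' @export
autoplot.tau_kappa_posterior <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$kappa, y = .data$density)) +
    geom_line() +
    scale_x_log10() +
    labs(x = expression(kappa ~ "(per year)"), y = "posterior density") +
    theme_minimal()
}

#' Plot per-region and combined replication-rate posteriors
#'
#' @param object A `tau_kappa_inference`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tau_kappa_inference
#' @export
autoplot.tau_kappa_inference <- function(object, ...) {
  per <- purrr::imap(object$per_region, function(p, nm) {
    as_tibble(p) |> mutate(which = nm)
  }) |> list_rbind()
  comb <- as_tibble(object$combined) |> mutate(which = "combined")
  ggplot(per, aes(x = .data$kappa, y = .data$density, colour = .data$which)) +
    geom_line(alpha = 0.6) +
    geom_line(data = comb, linewidth = 1, colour = "black") +
    scale_x_log10() +
    labs(x = expression(kappa ~ "(per year)"), y = "posterior density",
         colour = "region") +
    theme_minimal()
}

#' Plot observed versus fitted regional profiles
#'
#' The six-region seed profiles per Braak stage with the fitted
#' reaction-diffusion model overlaid.
#'
#' @param object A `regional_fit`.
#' @param ... Unused.
#' @return A ggplot on a log signal axis.
#' @method autoplot regional_fit
#' @export
autoplot.regional_fit <- function(object, ...) {
  d <- tidy(object) |>
    mutate(region = factor(.data$region, levels = object$geometry$region_labels))
  ggplot(d, aes(x = .data$region, group = .data$stage, colour = .data$stage)) +
    geom_point(aes(y = .data$observed)) +
    geom_line(aes(y = .data$fitted)) +
    scale_y_log10() +
    labs(x = "region (distance from EC)", y = "signal (assay units)",
         colour = "Braak stage") +
    theme_minimal()
}

#' Plot the PET rate-versus-signal fit
#'
#' @param object A `pet_fit`.
#' @param ... Unused.
#' @return A ggplot of annual rate against mean signal with the fitted
#'   parabola.
#' @method autoplot pet_fit
#' @export
autoplot.pet_fit <- function(object, ...) {
  d <- object$data
  curve_d <- tibble(
    S = seq(min(d$S_avg), max(d$S_avg), length.out = 200)) |>
    mutate(rate = rate_model(.data$S, object$kappa, object$alpha, object$b))
  ggplot(d, aes(x = .data$S_avg, y = .data$rate)) +
    geom_point(alpha = 0.6) +
    geom_line(data = curve_d, aes(x = .data$S, y = .data$rate),
              colour = "firebrick") +
    labs(x = "SUVr (visit average)", y = "annual rate (SUVr / year)") +
    theme_minimal()
}

#' Plot the fitted Braak stage-age Gaussians
#'
#' @param object A `braak_gaussian_model`.
#' @param ... Optionally `prob_table =` the fitted probability table to
#'   overlay as points.
#' @return A ggplot.
#' @method autoplot braak_gaussian_model
#' @export
autoplot.braak_gaussian_model <- function(object, ...) {
  dots <- list(...)
  ages <- seq(1, object$max_age, by = 1)
  curves <- purrr::imap(as.list(object$means), function(m, s) {
    tibble(stage = s, age = ages,
           prob = object$amplitude * exp(-(ages - m)^2 / (2 * object$sigma^2)))
  }) |> list_rbind()
  p <- ggplot(curves, aes(x = .data$age, y = .data$prob, colour = .data$stage)) +
    geom_line() +
    labs(x = "age (years)", y = "P(stage | age)", colour = "Braak stage") +
    theme_minimal()
  if (!is.null(dots$prob_table)) {
    p <- p + geom_point(data = as_tibble(dots$prob_table) |>
                          filter(.data$stage %in% names(object$means)),
                        aes(x = .data$age_mid, y = .data$prob))
  }
  p
}
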