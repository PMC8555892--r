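#' Synthetic multi-region seed time courses
#'
#' Generates a study-like seed-amplification dataset: per-subject,
#' per-region signals following the logistic replication model on the
#' Braak clock, multiplied by lognormal noise. Regions share the
#' replication rate but differ in initial seed fraction, which decays
#' geometrically with synaptic distance from the entorhinal cortex,
#' emulating the early-stage spatial gradient. Defaults mirror the
#' reference cohort design: subject counts (7, 4, 6, 2) at Braak
#' stages III-VI, six regions, and order-of-magnitude scatter
#' (sigma_log10 = 0.5).
#'
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @param kappa Replication rate, per year (default 0.17).
#' @param f0_ec Initial seed fraction in the entorhinal cortex
#'   (default 1e-3).
#' @param f0_decay Geometric decay factor of f0 per region step
#'   (default 0.3).
#' @param alpha Signal scale in assay units (default 100).
#' @param sigma_log10 Lognormal noise SD on log10 signal (default 0.5).
#' @param subjects_per_stage Named counts for stages III-VI
#'   (default `c(III = 7, IV = 4, V = 6, VI = 2)`).
#' @param regions Region labels ordered by distance from the EC.
#' @param technical_replicates Repeat measurements per subject, region
#'   and time (default 2), which let [estimate_noise_sd()] recover the
#'   noise scale.
#' @param stage_times Braak clock (default [braak_stage_times()]).
#'
#' @return A tibble with columns `subject`, `region`, `stage`,
#'   `time_years`, `replicate`, `value`, `assay`.
#' @export
#'
#' @examples
#' gen_seed_dataset(seed = 1)
gen_seed_dataset <- function(seed, kappa = 0.17, f0_ec = 1e-3,
                             f0_decay = 0.3, alpha = 100, sigma_log10 = 0.5,
                             subjects_per_stage = c(III = 7, IV = 4, V = 6, VI = 2),
                             regions = c("EC", "H", "PHG", "AC", "VA", "PV"),
                             technical_replicates = 2,
                             stage_times = braak_stage_times()) {
  if (any(subjects_per_stage < 1) || any(subjects_per_stage != round(subjects_per_stage))) {
    abort("`subjects_per_stage` must be positive integers.")
  }
  if (!all(names(subjects_per_stage) %in% names(stage_times))) {
    abort("`subjects_per_stage` names must be stages on the Braak clock.")
  }
  f0 <- setNames(f0_ec * f0_decay^(seq_along(regions) - 1), regions)
  if (any(f0 <= 1e-10)) abort("region f0 decayed below the 1e-10 prior bound.")
  withr::with_seed(seed, {
    design <- purrr::imap(subjects_per_stage, function(n, s) {
      tibble(stage = s, subject = paste0(s, "-", seq_len(n)))
    }) |> list_rbind() |>
      tidyr::expand_grid(region = regions,
                         replicate = seq_len(technical_replicates))
    design |>
      mutate(
        time_years = stage_to_time_years(.data$stage, stage_times),
        mean_signal = signal_from_fraction(
          logistic_fraction(.data$time_years, kappa,
                            unname(f0[.data$region])), alpha),
        value = .data$mean_signal * 10^rnorm(dplyr::n(), 0, sigma_log10),
        assay = "seed_amplification"
      ) |>
      select("subject", "region", "stage", "time_years", "replicate",
             "value", "assay")
  })
}

#' Gaussian stage-occupancy probabilities given age
#'
#' Probability of being at each Braak stage given age under the shared
#' amplitude/SD Gaussian model; individuals matching no stage I-VI
#' curve fall in the pooled pre-stage-I group `"0"`.
#'
#' @param age Ages in years.
#' @param means Named per-stage mean ages.
#' @param sigma Shared SD (years).
#' @param amplitude Shared peak probability.
#' @return Matrix of probabilities, one row per age, columns
#'   `"0", "I", ..., "VI"`; rows sum to 1.
#' @export
stage_age_probabilities <- function(age,
                                    means = setNames(braak_reference_ages()$mean_age,
                                                     braak_reference_ages()$stage),
                                    sigma = 15, amplitude = 0.32) {
  p <- sapply(means, function(m) amplitude * exp(-(age - m)^2 / (2 * sigma^2)))
  p <- matrix(p, nrow = length(age), dimnames = list(NULL, names(means)))
  p0 <- 1 - rowSums(p)
  if (any(p0 < 0)) {
    abort("stage probabilities exceed 1; lower `amplitude` or widen the means.")
  }
  cbind(`0` = p0, p)
}

#' Synthetic stage-by-age count table
#'
#' Multinomial draws of Braak stage per age decade from the Gaussian
#' stage model, truncated at 100 years (no bins beyond the tenth
#' decade exist, mirroring the source table). Default cohort size 2332
#' with an autopsy-like age pyramid.
#'
#' @param seed RNG seed.
#' @param n Total number of individuals (default 2332).
#' @param means,sigma,amplitude Passed to [stage_age_probabilities()].
#' @param decade_weights Relative cohort sizes of the ten age decades
#'   1-10, ..., 91-100.
#' @return A tibble with columns `age_bin`, `stage`, `count` (long
#'   format; all decade-stage combinations present).
#' @export
#'
#' @examples
#' gen_stage_age_table(seed = 1)
gen_stage_age_table <- function(seed, n = 2332,
                                means = setNames(braak_reference_ages()$mean_age,
                                                 braak_reference_ages()$stage),
                                sigma = 15, amplitude = 0.32,
                                decade_weights = c(1, 2, 3, 5, 8, 12, 16, 20, 18, 10)) {
  stopifnot(length(decade_weights) == 10)
  lo <- seq(1, 91, by = 10); hi <- seq(10, 100, by = 10)
  bins <- sprintf("%d-%d", lo, hi)
  mids <- (lo + hi) / 2
  n_bin <- round(n * decade_weights / sum(decade_weights))
  probs <- stage_age_probabilities(mids, means, sigma, amplitude)
  withr::with_seed(seed, {
    purrr::map(seq_along(bins), function(i) {
      counts <- as.integer(rmultinom(1, n_bin[i], probs[i, ]))
      tibble(age_bin = bins[i], stage = colnames(probs), count = counts)
    }) |> list_rbind()
  })
}

#' Synthetic longitudinal PET cohort
#'
#' Pairs of SUVr values about two years apart for `n` individuals:
#' baseline signal uniform on `[b, b + span * alpha]`, annual rate from
#' the differentiated logistic model plus Gaussian noise, follow-up
#' signal S2 = S1 + rate * interval. Default truth matches the
#' published PET fit (kappa = 0.17 /yr, alpha = 4, b = 1.06, 101
#' individuals) with group labels in study proportions.
#'
#' @param seed RNG seed.
#' @param n Cohort size (default 101).
#' @param kappa,alpha,b Model truth.
#' @param interval_years Visit interval (default 2).
#' @param rate_noise_sd Gaussian SD of the rate noise, signal/yr
#'   (default 0.01).
#' @param span Fraction of alpha spanned by baselines (default 0.8).
#' @return Tibble with `subject`, `group`, `S1`, `S2`,
#'   `interval_years`.
#' @export
gen_pet_cohort <- function(seed, n = 101, kappa = 0.17, alpha = 4, b = 1.06,
                           interval_years = 2, rate_noise_sd = 0.01,
                           span = 0.8) {
  groups <- c("AD", "MCI", "CN PiB+", "CN PiB-")
  group_n <- round(n * c(4, 7, 27, 63) / 101)
  group_n[4] <- n - sum(group_n[1:3])
  withr::with_seed(seed, {
    S1 <- runif(n, b, b + span * alpha)
    r <- rate_model(S1, kappa, alpha, b) + rnorm(n, 0, rate_noise_sd)
    tibble(
      subject = sprintf("pet-%03d", seq_len(n)),
      group = rep(groups, times = group_n),
      S1 = S1,
      S2 = S1 + r * interval_years,
      interval_years = interval_years
    )
  })
}

#' Synthetic transgenic-mouse seed time courses
#'
#' Exponential early-phase growth of seeding signal per brain region
#' with a shared replication rate and lognormal noise, with a
#' configurable pattern of missing late time points emulating uneven
#' sampling across regions.
#'
#' @param seed RNG seed.
#' @param kappa Replication rate, per month (natural-log convention;
#'   default 0.6).
#' @param regions Region labels.
#' @param times Measurement months.
#' @param baselines Named signal at time 0 per region (defaults spread
#'   over half a decade).
#' @param sigma_ln Lognormal noise SD in natural-log units
#'   (default 0.3).
#' @param missing Named list: time points absent for each region
#'   (default drops month 5 in neocortex and month 6 in frontal lobe,
#'   so months 1-4 are complete).
#' @return Tibble with `region`, `time_months`, `value`.
#' @export
gen_mouse_timecourses <- function(seed, kappa = 0.6,
                                  regions = c("brainstem", "neocortex", "frontal lobe"),
                                  times = 1:6,
                                  baselines = NULL,
                                  sigma_ln = 0.3,
                                  missing = list(neocortex = 5, `frontal lobe` = 6)) {
  baselines <- baselines %||%
    setNames(10^seq(1, 1.5, length.out = length(regions)), regions)
  withr::with_seed(seed, {
    tidyr::expand_grid(region = regions, time_months = times) |>
      filter(purrr::map2_lgl(.data$region, .data$time_months,
                             ~ !(.y %in% (missing[[.x]] %||% numeric())))) |>
      mutate(value = unname(baselines[.data$region]) *
               exp(kappa * .data$time_months) *
               exp(rnorm(dplyr::n(), 0, sigma_ln)))
  })
}

# HSB (0-255) triple -> integer RGB vector 0-255.
.hsb255_to_rgb <- function(h, s, b) {
  col <- grDevices::hsv(h / 255, s / 255, b / 255)
  as.integer(grDevices::col2rgb(col))
}

#' Synthetic AT8 brightfield slide with ground truth
#'
#' Paints a light background, `n_cells` hematoxylin-coloured nuclei
#' disks and `n_tau` DAB-coloured tau blobs at mutually non-touching
#' positions, recording painted-pixel ground truth. The three colours
#' are validated at generation time against the segmentation windows
#' (nucleus colour inside the cell window only, tau colour inside the
#' tau window only, background inside neither); an out-of-window
#' requested colour is a generator error, so the fixture is
#' self-validating.
#'
#' @param seed RNG seed.
#' @param width,height Image size in pixels (default 512).
#' @param n_cells,n_tau Numbers of nuclei disks and tau blobs.
#' @param cell_radius,tau_radius Disk radii in px.
#' @param cell_hsb,tau_hsb,background_hsb HSB (0-255) colour triples.
#' @param overlap_pairs Number of deliberately fused nucleus pairs
#'   (dumbbells) to add, each counting as 2 ground-truth cells
#'   (default 0).
#' @return A list with `image` (width x height x 3 array, 0-255) and
#'   `truth` (list: `n_cells`, `tau_area_px`, `cell_centers`,
#'   `tau_centers`).
#' @export
#'
#' @examples
#' \donttest{
#' slide <- gen_histology_image(seed = 1, n_cells = 20, n_tau = 2)
#' }
gen_histology_image <- function(seed, width = 512, height = 512,
                                n_cells = 50, n_tau = 3,
                                cell_radius = 12, tau_radius = 9,
                                cell_hsb = c(150, 80, 190),
                                tau_hsb = c(20, 150, 120),
                                background_hsb = c(0, 0, 250),
                                overlap_pairs = 0) {
  cw <- cell_hsb_window(); tw <- tau_hsb_window()
  check_color <- function(hsb, what, in_win, out_win) {
    rgb <- .hsb255_to_rgb(hsb[1], hsb[2], hsb[3])
    px <- array(rep(rgb, each = 1), dim = c(1, 1, 3))
    if (!all(hsb_threshold(px, in_win))) {
      abort(sprintf("%s colour fails its own HSB window after RGB round-trip.", what))
    }
    if (any(hsb_threshold(px, out_win))) {
      abort(sprintf("%s colour leaks into the other HSB window.", what))
    }
    rgb
  }
  check_bg <- function(hsb) {
    rgb <- .hsb255_to_rgb(hsb[1], hsb[2], hsb[3])
    px <- array(rgb, dim = c(1, 1, 3))
    if (any(hsb_threshold(px, cw)) || any(hsb_threshold(px, tw))) {
      abort("background colour falls inside a segmentation window.")
    }
    rgb
  }
  cell_rgb <- check_color(cell_hsb, "nucleus", cw, tw)
  tau_rgb <- check_color(tau_hsb, "tau", tw, cw)
  bg_rgb <- check_bg(background_hsb)

  img <- array(0, dim = c(width, height, 3))
  for (k in 1:3) img[, , k] <- bg_rgb[k]
  xg <- matrix(seq_len(width), width, height)
  yg <- matrix(seq_len(height), width, height, byrow = TRUE)

  paint_disk <- function(cx, cy, r, rgb) {
    sel <- (xg - cx)^2 + (yg - cy)^2 <= r^2
    for (k in 1:3) {
      ch <- img[, , k]
      ch[sel] <- rgb[k]
      img[, , k] <<- ch
    }
    sum(sel)
  }

  margin <- max(cell_radius, tau_radius) + 6
  place <- function(n, radius, centers, min_gap) {
    out <- matrix(NA_real_, n, 2)
    tries <- 0
    i <- 1
    while (i <= n) {
      tries <- tries + 1
      if (tries > 20000) abort("could not place all objects without contact; lower the counts.")
      cand <- c(runif(1, margin, width - margin), runif(1, margin, height - margin))
      all_c <- rbind(centers, out[seq_len(i - 1), , drop = FALSE])
      if (nrow(all_c) == 0 ||
          min(sqrt(rowSums(sweep(all_c, 2, cand)^2))) > min_gap) {
        out[i, ] <- cand
        i <- i + 1
      }
    }
    out
  }

  withr::with_seed(seed, {
    gap <- 2 * cell_radius + 8
    cell_centers <- place(n_cells, cell_radius, matrix(numeric(0), 0, 2), gap)
    pair_centers <- NULL
    if (overlap_pairs > 0) {
      anchors <- place(overlap_pairs, cell_radius, cell_centers, 2 * gap)
      pair_centers <- do.call(rbind, lapply(seq_len(overlap_pairs), function(i) {
        rbind(anchors[i, ], anchors[i, ] + c(1.5 * cell_radius, 0))
      }))
      cell_centers <- rbind(cell_centers, pair_centers)
    }
    tau_centers <- place(n_tau, tau_radius, cell_centers,
                         cell_radius + tau_radius + 6)
    for (i in seq_len(nrow(cell_centers))) {
      paint_disk(cell_centers[i, 1], cell_centers[i, 2], cell_radius, cell_rgb)
    }
    tau_area <- 0
    for (i in seq_len(nrow(tau_centers))) {
      tau_area <- tau_area +
        paint_disk(tau_centers[i, 1], tau_centers[i, 2], tau_radius, tau_rgb)
    }
    list(
      image = img,
      truth = list(n_cells = n_cells + 2 * overlap_pairs,
                   tau_area_px = tau_area,
                   cell_centers = cell_centers, tau_centers = tau_centers)
    )
  })
}
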