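# Synthetic two-condition resting-state BOLD generator.
#
# Each ROI series is a sum of band-limited (0.01-0.08 Hz) sinusoidal
# oscillations plus 1/f-shaped ("pink") noise plus white noise. The
# eyes-closed condition carries a multiplicatively larger oscillation
# amplitude in designated effect ROIs, matching the dominant direction of the
# EC > EO low-frequency amplitude effect in sensorimotor cortex.

#' Simulation configuration
#'
#' Defines the acquisition geometry and the ground-truth effect structure of
#' a synthetic cohort. Defaults mirror the study conditions: 24 subjects, two
#' conditions each, TR = 2 s, 240 volumes of which the first 10 are later
#' discarded by the pipeline.
#'
#' @param n_subjects number of subjects (each contributes an EC and an EO
#'   recording).
#' @param tr repetition time in seconds.
#' @param n_volumes number of acquired volumes per recording.
#' @param n_discard number of initial volumes the pipeline will discard
#'   (the generator emits all `n_volumes`; discarding is a pipeline step).
#'   The generator places oscillation frequencies on the DFT grid of the
#'   trimmed window so the band-limited signal stays strictly in band after
#'   trimming.
#' @param effect_rois integer indices (into the template) of ROIs carrying a
#'   condition effect.
#' @param effect_size dimensionless multiplier: oscillation amplitude in
#'   effect ROIs is scaled by `1 + effect_size` under EC relative to EO.
#' @param noise_sigma standard deviation of the additive white noise
#'   (signal units).
#' @param pink_sigma standard deviation of the additive 1/f-shaped noise.
#' @param one_over_f_exponent spectral exponent of the pink noise (power
#'   falls as f^-exponent).
#' @param n_oscillations number of sinusoids summed per ROI.
#' @param osc_amplitude base oscillation amplitude before subject and
#'   condition scaling.
#' @param subject_amp_sd sdlog of the lognormal per-subject amplitude factor
#'   shared by both conditions of a subject (paired heterogeneity).
#' @param seed master integer seed; identical config + seed gives a
#'   bit-identical cohort.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 24, tr = 2, n_volumes = 240,
                       n_discard = 10, effect_rois = 1:10, effect_size = 1,
                       noise_sigma = 1, pink_sigma = 1,
                       one_over_f_exponent = 1, n_oscillations = 5,
                       osc_amplitude = 1, subject_amp_sd = 0.2, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects), tr = tr,
              n_volumes = as.integer(n_volumes),
              n_discard = as.integer(n_discard),
              effect_rois = as.integer(effect_rois),
              effect_size = effect_size, noise_sigma = noise_sigma,
              pink_sigma = pink_sigma,
              one_over_f_exponent = one_over_f_exponent,
              n_oscillations = as.integer(n_oscillations),
              osc_amplitude = osc_amplitude,
              subject_amp_sd = subject_amp_sd, seed = as.integer(seed))
  assert_that(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  assert_that(cfg$tr > 0, "tr must be positive")
  assert_that(cfg$n_discard >= 0 && cfg$n_volumes > cfg$n_discard,
              "need n_volumes > n_discard >= 0")
  assert_that(cfg$effect_size >= 0, "effect_size must be >= 0")
  assert_that(all(cfg$effect_rois >= 1), "effect_rois must be positive indices")
  assert_that(cfg$noise_sigma >= 0 && cfg$pink_sigma >= 0,
              "noise sigmas must be >= 0")
  assert_that(cfg$n_oscillations >= 1, "n_oscillations must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d subjects x 2 conditions, TR = %g s, %d volumes (%d discarded)\n",
    x$n_subjects, x$tr, x$n_volumes, x$n_discard))
  cat(sprintf("  effect: x%.2g amplitude in %d ROI(s) under EC; noise sd white %.3g / pink %.3g (f^-%.2g)\n",
              1 + x$effect_size, length(x$effect_rois), x$noise_sigma,
              x$pink_sigma, x$one_over_f_exponent))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# 1/f-shaped noise: white spectrum reshaped by f^(-exponent/2) amplitude and
# inverted; DC removed; filter normalised so each series has unit variance in
# expectation.
pink_noise <- function(n, n_series, exponent, tr) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr)
  g <- c(0, f[-1]^(-exponent / 2))
  g <- g * sqrt(n / sum(g^2))
  w <- matrix(rnorm(n * n_series), n, n_series)
  Re(mvfft(mvfft(w) * g, inverse = TRUE)) / n
}

# DFT bin frequencies of the trimmed analysis window lying inside [lo, hi).
inband_grid <- function(n_analysis, tr, lo = 0.01, hi = 0.08) {
  k <- seq_len(floor(n_analysis / 2))
  f <- k / (n_analysis * tr)
  f[f >= lo & f < hi]
}

#' Simulate one recording (one subject, one condition)
#'
#' Generates a time x ROI matrix: per ROI, a sum of `n_oscillations`
#' sinusoids at frequencies drawn from the in-band (0.01-0.08 Hz) DFT grid of
#' the trimmed window with random phases, scaled by the subject's lognormal
#' amplitude factor and, in effect ROIs under EC, by `1 + effect_size`; plus
#' 1/f-shaped and white noise. The subject amplitude factor is derived from
#' `subject_seed` alone, so the EC and EO recordings of one subject share it.
#'
#' @param config a [sim_config()].
#' @param template a [roi_template()].
#' @param condition `"EC"` or `"EO"`.
#' @param subject_seed integer seed identifying the subject.
#' @param subject_id optional subject label (default derived from the seed).
#' @return A `subject_recording`: list with `subject_id`, `condition`,
#'   `data` (n_volumes x n_roi matrix, ROI names as column names) and `tr`.
#' @export
simulate_subject_timeseries <- function(config, template, condition,
                                        subject_seed,
                                        subject_id = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(template, "roi_template"))
  condition <- match.arg(condition, c("EC", "EO"))
  n_roi <- nrow(template)
  assert_that(all(config$effect_rois <= n_roi),
              "effect_rois outside template index range")
  n <- config$n_volumes
  k <- config$n_oscillations
  streams <- derive_seeds(subject_seed, 3L)
  amp_subject <- with_seed(streams[1],
                           rlnorm(1, meanlog = 0, sdlog = config$subject_amp_sd))
  stream <- if (condition == "EC") streams[2] else streams[3]
  grid <- inband_grid(n - config$n_discard, config$tr)
  t_sec <- (seq_len(n) - 1) * config$tr
  data <- with_seed(stream, {
    freqs <- matrix(sample(grid, k * n_roi, replace = TRUE), k, n_roi)
    phases <- matrix(runif(k * n_roi, 0, 2 * pi), k, n_roi)
    ang <- 2 * pi * outer(t_sec, as.vector(freqs)) +
      rep(as.vector(phases), each = n)
    osc <- t(rowsum(t(sin(ang)), group = rep(seq_len(n_roi), each = k)))
    gain <- rep(1, n_roi)
    if (condition == "EC" && config$effect_size > 0)
      gain[config$effect_rois] <- 1 + config$effect_size
    scale <- config$osc_amplitude * amp_subject * gain / sqrt(k)
    x <- osc * rep(scale, each = n)
    if (config$pink_sigma > 0)
      x <- x + config$pink_sigma *
        pink_noise(n, n_roi, config$one_over_f_exponent, config$tr)
    if (config$noise_sigma > 0)
      x <- x + matrix(rnorm(n * n_roi, 0, config$noise_sigma), n, n_roi)
    x
  })
  colnames(data) <- template$name
  structure(list(subject_id = subject_id %||% sprintf("sub-%010d", subject_seed),
                 condition = condition, data = data, tr = config$tr),
            class = "subject_recording")
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("Recording %s [%s]: %d volumes x %d ROIs, TR = %g s\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Simulate a full two-condition cohort
#'
#' Every subject contributes one EC and one EO recording; per-subject seeds
#' are derived deterministically from `config$seed`, so cohort generation is
#' a pure function of (config, template).
#'
#' @param config a [sim_config()].
#' @param template a [roi_template()].
#' @return List of `2 * n_subjects` `subject_recording`s, EC/EO interleaved
#'   per subject, with subject ids `sub-01` ... .
#' @export
simulate_cohort <- function(config, template) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, config$n_subjects)
  out <- vector("list", 2L * config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("sub-%02d", i)
    out[[2L * i - 1L]] <- simulate_subject_timeseries(config, template, "EC",
                                                      seeds[i], sid)
    out[[2L * i]] <- simulate_subject_timeseries(config, template, "EO",
                                                 seeds[i], sid)
  }
  out
}
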