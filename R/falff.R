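# ALFF / fALFF spectral estimation.
#
# ALFF is the sum of one-sided FFT amplitudes (square roots of power) over
# the low-frequency band, and fALFF the ratio of that sum to the amplitude
# sum over the entire measurable range (DC excluded). With the series
# detrended, fALFF is a dimensionless fraction in [0, 1].

#' Spectral band bookkeeping
#'
#' @param tr repetition time in seconds; sets the Nyquist frequency
#'   `1/(2*tr)` (0.25 Hz for TR = 2 s), the upper edge of the full band.
#' @param low low-frequency band, Hz (default `c(0.01, 0.08)`); bins are
#'   assigned half-open: included if `low[1] <= f < low[2]`.
#' @param full full band, Hz; must end at the Nyquist frequency (default
#'   `c(0, nyquist)`). The DC bin is always excluded from amplitude sums;
#'   the Nyquist bin is included.
#' @return A `spectral_bands` list with elements `low`, `full`, `nyquist`.
#' @export
spectral_bands <- function(tr, low = c(0.01, 0.08), full = NULL) {
  assert_that(tr > 0, "tr must be positive")
  nyq <- 1 / (2 * tr)
  full <- full %||% c(0, nyq)
  assert_that(length(low) == 2 && low[1] < low[2], "low band must be an interval")
  assert_that(length(full) == 2 && full[1] <= low[1] && low[2] <= full[2],
              "low band must lie within the full band")
  assert_that(isTRUE(all.equal(full[2], nyq)),
              "full band upper edge must equal the Nyquist frequency 1/(2*tr)")
  structure(list(low = low, full = full, nyquist = nyq),
            class = "spectral_bands")
}

#' Remove a least-squares linear trend
#'
#' Fits a straight line by ordinary least squares and returns the residuals,
#' which have exactly zero mean and zero fitted slope; the operation is
#' idempotent. For a matrix, columns are detrended independently.
#'
#' @param x numeric vector (length >= 3) or time x series matrix.
#' @return Object of the same shape as `x`.
#' @export
detrend_linear <- function(x) {
  if (is.matrix(x)) {
    assert_that(nrow(x) >= 3, "need at least 3 time points to detrend")
    assert_that(all(is.finite(x)), "non-finite values in input")
    q <- qr(cbind(1, seq_len(nrow(x))))
    return(qr.resid(q, x))
  }
  assert_that(is.numeric(x) && length(x) >= 3,
              "need at least 3 time points to detrend")
  assert_that(all(is.finite(x)), "non-finite values in input")
  drop(qr.resid(qr(cbind(1, seq_along(x))), matrix(x, ncol = 1)))
}

# One-sided amplitude scaling that satisfies Parseval:
# sum(amplitude^2) == sum(x^2). Interior bins get |X_k| * sqrt(2/N); DC and
# (for even N) Nyquist get |X_k| / sqrt(N).
one_sided_scale <- function(n) {
  half <- floor(n / 2)
  s <- rep(sqrt(2 / n), half + 1)
  s[1] <- 1 / sqrt(n)
  if (n %% 2 == 0) s[half + 1] <- 1 / sqrt(n)
  s
}

#' One-sided amplitude spectrum
#'
#' Fast-Fourier transforms the series and returns the one-sided amplitude
#' (square root of power) at each frequency `k/(N*tr)`, scaled so that the
#' squared amplitudes sum to the time-domain sum of squares (Parseval).
#'
#' @param x numeric vector, length >= 4, finite, typically detrended.
#' @param tr sampling interval in seconds.
#' @return List with `frequency` (Hz) and `amplitude` vectors of length
#'   `floor(N/2) + 1` (DC through Nyquist).
#' @export
amplitude_spectrum <- function(x, tr) {
  assert_that(is.numeric(x) && length(x) >= 4, "series must have length >= 4")
  assert_that(all(is.finite(x)), "non-finite values in input")
  assert_that(tr > 0, "tr must be positive")
  n <- length(x)
  half <- floor(n / 2)
  amp <- Mod(fft(x))[seq_len(half + 1)] * one_sided_scale(n)
  list(frequency = (0:half) / (n * tr), amplitude = amp)
}

# Band bin masks over a one-sided frequency axis. Low band half-open
# [lo, hi); full band excludes DC, includes Nyquist.
band_masks <- function(freq, bands) {
  list(low = freq >= bands$low[1] & freq < bands$low[2],
       full = freq > 0 & freq <= bands$full[2] + 1e-12)
}

#' Compute ALFF and fALFF for one series
#'
#' ALFF is the sum of amplitudes over the low band; fALFF the ratio of that
#' sum to the amplitude sum over the full band excluding DC, a fraction in
#' [0, 1]. With `method = "mean"` both band aggregates are means instead of
#' sums (ratio-of-means convention).
#'
#' A series that is identically zero after detrending has no defined
#' fraction: fALFF is returned as `NA` (flagged missing, never 0/0).
#'
#' @param x numeric series (expected detrended; not detrended internally).
#' @param tr sampling interval, seconds.
#' @param bands a [spectral_bands()] (default derived from `tr`).
#' @param method `"sum"` (default) or `"mean"` band aggregation.
#' @return List with `alff` (signal units) and `falff` (dimensionless).
#' @export
compute_falff <- function(x, tr, bands = spectral_bands(tr),
                          method = c("sum", "mean")) {
  method <- match.arg(method)
  sp <- amplitude_spectrum(x, tr)
  m <- band_masks(sp$frequency, bands)
  agg <- if (method == "sum") sum else mean
  alff <- agg(sp$amplitude[m$low])
  denom <- agg(sp$amplitude[m$full])
  falff <- if (denom > 0) alff / denom else NA_real_
  list(alff = alff, falff = falff)
}

# Vectorised fALFF over the columns of a time x series matrix (one mvfft).
falff_columns <- function(mat, tr, bands = spectral_bands(tr),
                          method = c("sum", "mean")) {
  method <- match.arg(method)
  n <- nrow(mat)
  half <- floor(n / 2)
  amp <- Mod(mvfft(mat))[seq_len(half + 1), , drop = FALSE] * one_sided_scale(n)
  m <- band_masks((0:half) / (n * tr), bands)
  if (method == "sum") {
    alff <- colSums(amp[m$low, , drop = FALSE])
    denom <- colSums(amp[m$full, , drop = FALSE])
  } else {
    alff <- colMeans(amp[m$low, , drop = FALSE])
    denom <- colMeans(amp[m$full, , drop = FALSE])
  }
  falff <- ifelse(denom > 0, alff / denom, NA_real_)
  list(alff = alff, falff = falff)
}

#' Normalise a map by its global mean
#'
#' Divides every value by the mean over the mask, so the masked mean of the
#' output is exactly 1.
#'
#' @param x numeric vector, matrix or array of fALFF values.
#' @param mask logical object of the same shape selecting the values that
#'   define the global mean (default: all finite entries).
#' @return `x / mean(x[mask])`, same shape as `x`.
#' @export
normalize_global_mean <- function(x, mask = NULL) {
  mask <- mask %||% is.finite(x)
  assert_that(any(mask), "mask selects no values")
  g <- mean(x[mask])
  assert_that(is.finite(g) && g > 0,
              "global mean is not positive; cannot normalise")
  x / g
}

#' Per-condition fALFF feature table from a cohort
#'
#' Runs the amplitude pipeline on every recording of one condition: discard
#' the first `n_discard` volumes, detrend each ROI series, compute fALFF per
#' ROI, and (by default) normalise each subject's ROI vector by its global
#' mean. Rows are subjects, columns ROIs.
#'
#' @param cohort list of `subject_recording`s (e.g. from
#'   [simulate_cohort()]); recordings of other conditions are ignored.
#' @param condition `"EC"` or `"EO"`.
#' @param bands a [spectral_bands()]; default derived from the recordings' TR.
#' @param n_discard initial volumes to discard (default 10).
#' @param normalize divide each subject's ROI vector by its global mean
#'   fALFF (default TRUE).
#' @param method band aggregation passed to the fALFF computation.
#' @return A `falff_table`: list with `values` (subjects x ROIs matrix),
#'   `condition`, `subject_ids`, `roi_names`.
#' @export
falff_feature_table <- function(cohort, condition, bands = NULL,
                                n_discard = 10, normalize = TRUE,
                                method = "sum") {
  condition <- match.arg(condition, c("EC", "EO"))
  recs <- Filter(function(r) r$condition == condition, cohort)
  assert_that(length(recs) > 0,
              paste("no recordings with condition", condition))
  tr <- recs[[1]]$tr
  bands <- bands %||% spectral_bands(tr)
  roi_names <- colnames(recs[[1]]$data)
  vals <- t(vapply(recs, function(r) {
    assert_that(identical(colnames(r$data), roi_names),
                "ROI columns differ across recordings")
    assert_that(nrow(r$data) > n_discard,
                "recording shorter than n_discard")
    y <- detrend_linear(r$data[(n_discard + 1):nrow(r$data), , drop = FALSE])
    f <- falff_columns(y, r$tr, bands, method)$falff
    if (normalize) f <- normalize_global_mean(f) else f
  }, numeric(length(roi_names))))
  subject_ids <- vapply(recs, `[[`, character(1), "subject_id")
  assert_that(!anyDuplicated(subject_ids),
              "duplicate subject ids within one condition")
  dimnames(vals) <- list(subject_ids, roi_names)
  structure(list(values = vals, condition = condition,
                 subject_ids = subject_ids, roi_names = roi_names),
            class = "falff_table")
}

#' @export
print.falff_table <- function(x, ...) {
  cat(sprintf("fALFF feature table [%s]: %d subjects x %d ROIs\n",
              x$condition, nrow(x$values), ncol(x$values)))
  invisible(x)
}
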