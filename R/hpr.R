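#' Heart-period pipeline configuration
#'
#' @param ibi_bounds_ms Valid inter-beat-interval range in ms; values outside
#'   the bounds (strictly) are dropped, boundary values kept (configurable
#'   via `bounds_exclusive`).
#' @param bounds_exclusive If `TRUE`, boundary values are dropped too.
#' @param interp_rate_hz Interpolated heart-period trace rate.
#' @param bandpass_hz Band-pass edges for the heart-period trace.
#' @param filter_order Butterworth order.
#' @param refractory_s Minimum spacing between detected R spikes.
#' @param kernel_args Overrides for the canonical heart-period kernel.
#' @return An `hpr_config` list.
#' @export
hpr_config <- function(ibi_bounds_ms = c(400, 1200), bounds_exclusive = FALSE,
                       interp_rate_hz = 10, bandpass_hz = c(0.015, 0.5),
                       filter_order = 4, refractory_s = 0.2,
                       kernel_args = list()) {
  stopifnot(ibi_bounds_ms[1] < ibi_bounds_ms[2],
            bandpass_hz[1] > 0, bandpass_hz[1] < bandpass_hz[2])
  structure(as.list(environment()), class = "hpr_config")
}

#' Detect R spikes with a Pan-Tompkins-type algorithm
#'
#' Classic chain: 5-15 Hz band-pass (zero-phase), differentiation, squaring,
#' 150 ms moving-window integration, adaptive dual thresholds on the
#' integrated signal, refractory rule, and R-time refinement on the
#' band-passed signal. Deterministic.
#'
#' @param ecg A [channel_recording()] at >= 250 Hz.
#' @param config An [hpr_config()].
#' @return Ordered numeric vector of spike times in seconds (empty, with a
#'   warning, for flatline input).
#' @export
detect_r_spikes <- function(ecg, config = hpr_config()) {
  rate <- ch_rate(ecg)
  stopifnot(rate >= 250)
  x <- ecg$value
  if (stats::sd(x) == 0) {
    warning("flatline ECG: no spikes detected")
    return(numeric(0))
  }
  bp <- butter_filtfilt(x, rate, c(5, 15), "pass", 2)
  d <- c(0, diff(bp)) * rate
  sq <- d^2
  w <- round(0.15 * rate)
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  # local maxima of the integrated signal, kept only if dominant within
  # +/-150 ms (suppresses noise bumps riding next to a QRS complex)
  peaks <- which(diff(sign(diff(integ))) == -2) + 1
  dom <- vapply(peaks, function(p) {
    lo <- max(1, p - w)
    hi <- min(length(integ), p + w)
    integ[p] >= max(integ[lo:hi])
  }, logical(1))
  peaks <- peaks[dom]
  if (length(peaks) == 0) {
    warning("no QRS-like peaks found")
    return(numeric(0))
  }
  spki <- max(integ[seq_len(min(length(integ), 2 * rate))]) * 0.5
  npki <- mean(integ[seq_len(min(length(integ), 2 * rate))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  spikes_idx <- integer(0)
  last <- -Inf
  refr <- config$refractory_s * rate
  for (p in peaks) {
    if (integ[p] > thr) {
      if (p - last >= refr) {
        spikes_idx <- c(spikes_idx, p)
        last <- p
        spki <- 0.125 * integ[p] + 0.875 * spki
      }
      # peaks inside the refractory window update neither threshold
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  # refine to the R peak on the raw signal (sharp, unlike the band-passed
  # waveform whose side lobes can outgrow the main lobe under noise)
  half <- round(0.06 * rate)
  refined <- vapply(spikes_idx, function(p) {
    lo <- max(1, p - half)
    hi <- min(length(x), p + half)
    lo + which.max(abs(x[lo:hi])) - 1
  }, numeric(1))
  sort(unique((refined - 1) / rate))
}

#' Build the interpolated, filtered heart-period trace
#'
#' Each inter-beat interval is mapped onto the time of its following R spike;
#' intervals outside the valid range are dropped; the series is linearly
#' interpolated to a uniform grid and band-pass filtered bidirectionally.
#' The unfiltered interpolated trace is kept in attribute `"hp_raw"`.
#'
#' @param spikes Spike times in seconds (from [detect_r_spikes()]).
#' @param duration_s Trace duration; defaults to the last spike time.
#' @param config An [hpr_config()].
#' @return A [channel_recording()] at `interp_rate_hz` in ms.
#' @export
build_hp_trace <- function(spikes, duration_s = NULL, config = hpr_config()) {
  stopifnot(length(spikes) >= 3)
  ibi <- diff(spikes) * 1000
  at <- spikes[-1]
  b <- config$ibi_bounds_ms
  keep <- if (config$bounds_exclusive) ibi > b[1] & ibi < b[2] else
    ibi >= b[1] & ibi <= b[2]
  ibi <- ibi[keep]
  at <- at[keep]
  stopifnot(length(ibi) >= 2)
  duration_s <- duration_s %||% max(spikes)
  grid <- seq(0, duration_s, by = 1 / config$interp_rate_hz)
  hp <- stats::approx(at, ibi, xout = grid, rule = 2)$y
  filt <- butter_filtfilt(hp - mean(hp), config$interp_rate_hz,
                          config$bandpass_hz, "pass", config$filter_order,
                          pad_s = 60)
  rec <- channel_recording(filt, config$interp_rate_hz, units = "ms",
                           channel = "hp")
  attr(rec, "hp_raw") <- hp
  rec
}

#' Conditionwise heart-period convolution GLM
#'
#' Regresses the filtered heart-period trace onto one regressor per CS type
#' (the condition's CS-onset impulse train convolved with the canonical
#' heart-period kernel and passed through the same band-pass filter), plus an
#' intercept, by ordinary least squares.
#'
#' @param hp [channel_recording()] from [build_hp_trace()].
#' @param seq Timed `trial_sequence`.
#' @param config An [hpr_config()].
#' @return Tibble: `cs`, `amplitude` (ms; positive = heart-period
#'   lengthening, i.e. bradycardia).
#' @export
fit_hpr_glm <- function(hp, seq, config = hpr_config()) {
  rate <- ch_rate(hp)
  kern <- do.call(canonical_kernel,
                  c(list(type = "hprf", rate = rate), config$kernel_args))
  n <- nrow(hp)
  conds <- CS_LEVELS
  X <- matrix(0, n, length(conds) + 1)
  for (j in seq_along(conds)) {
    col <- numeric(n)
    for (on in seq$cs_onset_s[seq$cs == conds[j]]) {
      col <- add_wave_at(col, kern$y, round(on * rate) + 1)
    }
    X[, j] <- butter_filtfilt(col, rate, config$bandpass_hz, "pass",
                              config$filter_order, pad_s = 60)
  }
  X[, length(conds) + 1] <- 1
  beta <- qr.coef(qr(X), hp$value)
  tibble::tibble(cs = conds, amplitude = beta[seq_along(conds)])
}
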