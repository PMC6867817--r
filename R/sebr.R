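#' SEBR pipeline configuration
#'
#' Filtering and fitting parameters for startle eye-blink quantification:
#' fourth-order Butterworth band-pass 50-470 Hz, notch filters at the 50 Hz
#' mains harmonics below the upper cutoff, rectification, fourth-order 53.05 Hz
#' low-pass smoothing, and variable-onset regression of the envelope onto the
#' canonical startle kernel.
#'
#' @param bandpass_hz Band-pass edges in Hz.
#' @param filter_order Butterworth order for band-pass and smoothing.
#' @param notch_base_hz Mains base frequency (harmonics below the upper band
#'   edge are notched); `NULL` disables notching.
#' @param notch_q Notch quality factor.
#' @param smooth_cutoff_hz Low-pass smoothing cutoff (53.05 Hz, the 3 ms
#'   time-constant equivalent).
#' @param onset_window_s Onset search interval after the probe (seconds).
#' @param onset_step_s Search grid step.
#' @param kernel_args Overrides for the canonical startle kernel.
#' @return An `emg_config` list.
#' @export
emg_config <- function(bandpass_hz = c(50, 470), filter_order = 4,
                       notch_base_hz = 50, notch_q = 35,
                       smooth_cutoff_hz = 53.05,
                       onset_window_s = c(0, 0.15), onset_step_s = 0.001,
                       kernel_args = list()) {
  stopifnot(bandpass_hz[1] > 0, bandpass_hz[1] < bandpass_hz[2],
            onset_window_s[1] >= 0, onset_window_s[2] <= 0.2)
  structure(as.list(environment()), class = "emg_config")
}

#' Preprocess raw EMG into a rectified smoothed envelope
#'
#' Band-pass filters the electromyogram (zero-phase, bidirectional), notches
#' mains harmonics, rectifies, and smooths with a low-pass filter. The output
#' is a non-negative envelope at the input rate.
#'
#' @param raw A [channel_recording()] with rate at least twice the upper
#'   band-pass cutoff.
#' @param config An [emg_config()].
#' @return A [channel_recording()] holding the envelope.
#' @export
preprocess_emg <- function(raw, config = emg_config()) {
  rate <- ch_rate(raw)
  if (rate < 2 * config$bandpass_hz[2]) {
    stop(sprintf("EMG rate %g Hz below twice the %g Hz cutoff",
                 rate, config$bandpass_hz[2]), call. = FALSE)
  }
  if (anyNA(raw$value)) stop("NaN/NA samples in EMG input", call. = FALSE)
  x <- butter_filtfilt(raw$value, rate, config$bandpass_hz, "pass",
                       config$filter_order)
  if (!is.null(config$notch_base_hz)) {
    harmonics <- config$notch_base_hz * seq_len(
      floor((config$bandpass_hz[2] - 1e-9) / config$notch_base_hz))
    for (f0 in harmonics) x <- notch_filtfilt(x, rate, f0, config$notch_q)
  }
  x <- abs(x)
  x <- butter_filtfilt(x, rate, config$smooth_cutoff_hz, "low",
                       config$filter_order)
  rec <- ch_update(raw, value = pmax(x, 0))
  attr(rec, "channel") <- paste0(ch_name(raw), "_envelope")
  rec
}

#' Fit one trial's startle amplitude by variable-onset kernel regression
#'
#' Slides the canonical startle kernel over a 1 ms onset grid within the
#' search window after the probe and, at each onset, estimates a non-negative
#' amplitude by least squares; the onset minimizing the residual sum of
#' squares wins (ties broken by the earliest onset).
#'
#' @param envelope Envelope [channel_recording()] from [preprocess_emg()].
#' @param probe_onset_s Measured probe (sound) onset in seconds.
#' @param config An [emg_config()].
#' @return One-row tibble: `amplitude` (>= 0), `onset_s` (NA when the segment
#'   is all zero), `fit_r2`.
#' @export
fit_sebr_trial <- function(envelope, probe_onset_s, config = emg_config()) {
  rate <- ch_rate(envelope)
  kern <- do.call(canonical_kernel,
                  c(list(type = "sebr", rate = rate), config$kernel_args))
  k <- kern$y
  offsets <- round(seq(config$onset_window_s[1], config$onset_window_s[2],
                       by = config$onset_step_s) * rate)
  start <- round(probe_onset_s * rate) + 1
  seg_len <- max(offsets) + length(k)
  if (start < 1 || start + seg_len - 1 > nrow(envelope)) {
    stop("probe window exceeds recording", call. = FALSE)
  }
  y <- envelope$value[start:(start + seg_len - 1)]
  if (all(y == 0)) {
    return(tibble::tibble(amplitude = 0, onset_s = NA_real_, fit_r2 = NA_real_))
  }
  kk <- sum(k * k)
  yy <- sum(y * y)
  fits <- vapply(offsets, function(o) {
    dot <- sum(y[(o + 1):(o + length(k))] * k)
    amp <- max(0, dot / kk)
    rss <- yy - 2 * amp * dot + amp^2 * kk
    c(amp, rss)
  }, numeric(2))
  best <- which.min(fits[2, ])  # which.min returns the first (earliest) tie
  tss <- sum((y - mean(y))^2)
  tibble::tibble(amplitude = fits[1, best],
                 onset_s = offsets[best] / rate,
                 fit_r2 = if (tss > 0) 1 - fits[2, best] / tss else NA_real_)
}

#' Trialwise startle amplitudes for a full session
#'
#' Runs [fit_sebr_trial()] at every probe onset of the sequence.
#'
#' @param envelope Envelope [channel_recording()].
#' @param seq A timed `trial_sequence` with probe onsets.
#' @param config An [emg_config()].
#' @return Tibble with one row per trial: `trial`, `cs`, `reinforced`,
#'   `amplitude`, `onset_s`, `fit_r2`.
#' @export
fit_sebr <- function(envelope, seq, config = emg_config()) {
  stopifnot(all(!is.na(seq$probe_onset_s)))
  est <- purrr::map_dfr(seq$probe_onset_s, fit_sebr_trial,
                        envelope = envelope, config = config)
  dplyr::bind_cols(seq[, c("trial", "cs", "reinforced")], est)
}

#' Normalize startle amplitudes by the participant's CS- mean
#'
#' Electrode impedance and muscle anatomy scale the true startle response
#' multiplicatively, so each participant's (or participant-session's)
#' single-trial estimates are divided by that participant's mean amplitude on
#' CS- trials. After normalization the CS- mean equals 1 exactly.
#'
#' @param estimates Tibble with columns `cs` and `amplitude`; grouping columns
#'   in `by` (default any of `participant`, `phase` present) define the
#'   normalization unit.
#' @param by Character vector of grouping columns.
#' @return The input with a `normalized_amplitude` column added.
#' @export
normalize_sebr <- function(estimates,
                           by = intersect(c("participant", "phase"),
                                          names(estimates))) {
  norm_one <- function(d, ...) {
    m <- mean(d$amplitude[d$cs == "CS-"])
    if (!is.finite(m)) stop("no finite CS- amplitudes to normalize by",
                            call. = FALSE)
    if (m == 0) stop("normalization undefined: CS- mean amplitude is 0",
                     call. = FALSE)
    dplyr::mutate(d, normalized_amplitude = .data$amplitude / m)
  }
  if (length(by) == 0) return(norm_one(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(norm_one) |>
    dplyr::ungroup()
}
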