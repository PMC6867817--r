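#' Uniformly sampled physiological channel
#'
#' A `channel_recording` is a tibble with columns `time` (seconds), `value`
#' (channel units) and `valid` (logical sample-validity mask), carrying the
#' sampling rate, units and channel name as attributes. All signal-processing
#' verbs in the package take and return this class so pipelines chain with the
#' pipe.
#'
#' @param value Numeric vector of samples.
#' @param rate Sampling rate in Hz.
#' @param units Unit string (e.g. `"uS"`, `"a.u."`, `"mV"`).
#' @param channel Channel name (e.g. `"emg"`, `"sc"`).
#' @param valid Logical validity mask, recycled to `length(value)`;
#'   defaults to all-valid.
#' @param t0 Time of the first sample in seconds.
#' @param extra Optional named list of additional numeric columns sampled on
#'   the same grid (e.g. gaze coordinates alongside pupil area).
#'
#' @return A tibble of class `channel_recording`.
#' @export
channel_recording <- function(value, rate, units = "a.u.", channel = "signal",
                              valid = TRUE, t0 = 0, extra = NULL) {
  stopifnot(is.numeric(value), rate > 0)
  n <- length(value)
  out <- tibble::tibble(
    time = t0 + (seq_len(n) - 1) / rate,
    value = as.numeric(value),
    valid = rep_len(as.logical(valid), n)
  )
  if (!is.null(extra)) {
    for (nm in names(extra)) out[[nm]] <- rep_len(as.numeric(extra[[nm]]), n)
  }
  attr(out, "rate") <- rate
  attr(out, "units") <- units
  attr(out, "channel") <- channel
  class(out) <- c("channel_recording", class(tibble::tibble()))
  out
}

#' @rdname channel_recording
#' @param x A `channel_recording`.
#' @export
ch_rate <- function(x) attr(x, "rate")

#' @rdname channel_recording
#' @export
ch_units <- function(x) attr(x, "units")

#' @rdname channel_recording
#' @export
ch_name <- function(x) attr(x, "channel")

#' @export
print.channel_recording <- function(x, ...) {
  cat(sprintf("<channel_recording> %s: %d samples @ %g Hz [%s], %.1f%% valid\n",
              ch_name(x), nrow(x), ch_rate(x), ch_units(x),
              100 * mean(x$valid)))
  NextMethod()
}

# rebuild a recording from new values, keeping metadata
ch_update <- function(x, value = x$value, valid = x$valid, rate = ch_rate(x)) {
  channel_recording(value, rate, units = ch_units(x), channel = ch_name(x),
                    valid = valid, t0 = x$time[1])
}

#' Mark interval annotations as invalid samples
#'
#' @param rec A [channel_recording()].
#' @param intervals Tibble with columns `start_s`, `end_s` (and optionally
#'   `label`); samples with `start_s <= time < end_s` are masked invalid.
#' @return The recording with an updated `valid` mask.
#' @export
mask_intervals <- function(rec, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rec)
  if (any(intervals$end_s < intervals$start_s)) {
    stop("mask_intervals(): inverted interval (end_s < start_s)", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(rec))
  for (i in seq_len(nrow(intervals))) {
    keep[rec$time >= intervals$start_s[i] & rec$time < intervals$end_s[i]] <- FALSE
  }
  rec$valid <- rec$valid & keep  # in place: extra columns stay intact
  rec
}

# Linear interpolation across invalid runs (for filtering only; the mask is
# retained so that model inversion ignores interpolated samples).
interp_invalid <- function(value, valid) {
  if (all(valid)) return(value)
  if (!any(valid)) stop("no valid samples to interpolate from", call. = FALSE)
  idx <- seq_along(value)
  stats::approx(idx[valid], value[valid], xout = idx, rule = 2)$y
}

# Zero-phase Butterworth filtering (bidirectional). `pad_s` seconds of
# odd-reflection padding suppress edge transients — essential for high-pass
# corners with time constants of several seconds.
butter_filtfilt <- function(x, rate, cutoff_hz, type = c("pass", "low", "high", "stop"),
                            order = 4, pad_s = 0) {
  type <- match.arg(type)
  ny <- rate / 2
  w <- cutoff_hz / ny
  if (any(w <= 0) || any(w >= 1)) {
    stop(sprintf("cutoff %s Hz invalid for rate %g Hz", paste(cutoff_hz, collapse = "-"),
                 rate), call. = FALSE)
  }
  bf <- signal::butter(order, w, type = type)
  n <- length(x)
  p <- min(n - 1, round(pad_s * rate))
  if (p > 0) {
    x <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  }
  y <- as.numeric(signal::filtfilt(bf, x))
  if (p > 0) y <- y[(p + 1):(p + n)]
  y
}

# Second-order IIR notch (biquad) at f0 with quality factor q, zero phase.
notch_filtfilt <- function(x, rate, f0, q = 35) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  as.numeric(signal::filtfilt(signal::Arma(b = b / a[1], a = a / a[1]), x))
}

# Integer-factor decimation (assumes x already band-limited below the new
# Nyquist by prior filtering).
decimate_by <- function(x, factor) x[seq(1, length(x), by = factor)]
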