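#' Pupil pipeline configuration
#'
#' @param gaze_box_deg Half-angle (degrees) of the accepted gaze box around
#'   screen centre.
#' @param screen_distance_cm Eye-to-monitor distance.
#' @param min_valid_fraction Minimum fraction of available data points in the
#'   10 s after CS onset for a trial to be included (trials at exactly the
#'   threshold are included; the exclusion rule is strictly-less-than).
#' @param trial_window_s Post-CS-onset evaluation window (10 s).
#' @param target_rate_hz Analysis rate after down-sampling.
#' @param max_missing_trials_fraction Per-session warning threshold on the
#'   fraction of excluded trials.
#' @param saccade_velocity_deg_s Velocity threshold for fallback saccade
#'   detection when tracker annotations are absent.
#' @param kernel_args Overrides for the canonical pupil kernel.
#' @return A `pupil_config` list.
#' @export
pupil_config <- function(gaze_box_deg = 5, screen_distance_cm = 70,
                         min_valid_fraction = 0.5, trial_window_s = 10,
                         target_rate_hz = 250,
                         max_missing_trials_fraction = 0.35,
                         saccade_velocity_deg_s = 30,
                         kernel_args = list()) {
  stopifnot(min_valid_fraction > 0, min_valid_fraction <= 1,
            gaze_box_deg > 0, screen_distance_cm > 0)
  structure(as.list(environment()), class = "pupil_config")
}

#' Convert on-screen millimetres to degrees of visual angle
#'
#' @param offset_cm Offset from screen centre in cm (vector).
#' @param screen_distance_cm Viewing distance in cm.
#' @return Visual angle in degrees (`atan(offset / distance)`).
#' @export
gaze_cm_to_deg <- function(offset_cm, screen_distance_cm = 70) {
  atan2(offset_cm, screen_distance_cm) * 180 / pi
}

#' Clean a pupil recording
#'
#' Masks blink/saccade annotation intervals and samples where gaze leaves the
#' accepted box around screen centre; missing runs are linearly interpolated
#' for filtering but stay masked for model inversion. The trace is decimated
#' to the analysis rate. When `blink_saccade_intervals` is `NULL`, saccades
#' are detected from gaze velocity as an approximation of the tracker's
#' online parser.
#'
#' @param area A [channel_recording()] of pupil area with gaze columns `gx`,
#'   `gy` in degrees.
#' @param blink_saccade_intervals Annotation tibble (`start_s`, `end_s`), or
#'   `NULL` to fall back to velocity-based saccade detection.
#' @param config A [pupil_config()].
#' @return A [channel_recording()] at `target_rate_hz` with validity mask.
#' @export
clean_pupil <- function(area, blink_saccade_intervals = NULL,
                        config = pupil_config()) {
  rate <- ch_rate(area)
  if (is.null(blink_saccade_intervals)) {
    v <- sqrt(diff(area$gx)^2 + diff(area$gy)^2) * rate
    rec <- area
    rec$valid <- area$valid & !c(FALSE, v > config$saccade_velocity_deg_s)
  } else {
    rec <- mask_intervals(area, blink_saccade_intervals)
  }
  out_of_box <- abs(rec$gx) > config$gaze_box_deg |
    abs(rec$gy) > config$gaze_box_deg
  valid <- rec$valid & !out_of_box & rec$value > 0
  x <- interp_invalid(rec$value, valid)
  fac <- round(rate / config$target_rate_hz)
  stopifnot(fac >= 1)
  channel_recording(decimate_by(x, fac), rate / fac,
                    units = ch_units(area), channel = ch_name(area),
                    valid = decimate_by(valid, fac))
}

#' Select the eye with fewer missing data points
#'
#' @param left,right Cleaned [channel_recording()]s for each eye.
#' @return The recording with fewer invalid samples; ties go to the left eye.
#' @export
select_eye <- function(left, right) {
  if (sum(!right$valid) < sum(!left$valid)) right else left
}

#' Per-trial exclusion by available-data fraction
#'
#' A trial is excluded if strictly less than `min_valid_fraction` of data
#' points are available during the `trial_window_s` following CS onset.
#' Warns when a participant-session exceeds the missing-trials threshold.
#'
#' @param rec Cleaned [channel_recording()].
#' @param seq Timed `trial_sequence`.
#' @param config A [pupil_config()].
#' @return Tibble: `trial`, `valid_fraction`, `excluded`.
#' @export
exclude_pupil_trials <- function(rec, seq, config = pupil_config()) {
  frac <- vapply(seq$cs_onset_s, function(on) {
    idx <- rec$time >= on & rec$time < on + config$trial_window_s
    mean(rec$valid[idx])
  }, numeric(1))
  excluded <- frac < config$min_valid_fraction
  if (mean(excluded) > config$max_missing_trials_fraction) {
    warning(sprintf("%.0f%% of trials excluded (> %.0f%% threshold)",
                    100 * mean(excluded),
                    100 * config$max_missing_trials_fraction))
  }
  tibble::tibble(trial = seq$trial, valid_fraction = frac, excluded = excluded)
}

#' Single-trial pupil convolution GLM
#'
#' Regresses the cleaned pupil trace onto per-trial impulses at CS onset
#' convolved with the canonical pupil kernel, plus an intercept and a linear
#' drift term, by ordinary least squares on valid samples only. Excluded
#' trials contribute no regressor and receive missing amplitudes.
#'
#' @param rec Cleaned [channel_recording()] at the analysis rate.
#' @param seq Timed `trial_sequence`.
#' @param config A [pupil_config()].
#' @param trial_flags Output of [exclude_pupil_trials()]; computed when
#'   `NULL`.
#' @return Tibble: `trial`, `cs`, `reinforced`, `amplitude` (NA for excluded
#'   trials), `excluded`.
#' @export
fit_pupil_glm <- function(rec, seq, config = pupil_config(),
                          trial_flags = NULL) {
  if (is.null(trial_flags)) trial_flags <- exclude_pupil_trials(rec, seq, config)
  rate <- ch_rate(rec)
  kern <- do.call(canonical_kernel,
                  c(list(type = "psrf", rate = rate), config$kernel_args))
  n <- nrow(rec)
  incl <- which(!trial_flags$excluded)
  X <- matrix(0, n, length(incl) + 2)
  for (j in seq_along(incl)) {
    X[, j] <- add_wave_at(numeric(n), kern$y,
                          round(seq$cs_onset_s[incl[j]] * rate) + 1)
  }
  X[, length(incl) + 1] <- 1
  X[, length(incl) + 2] <- seq_len(n) / n - 0.5
  v <- rec$valid
  qr_x <- qr(X[v, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient pupil design (irreparable trial overlap)")
  }
  beta <- qr.coef(qr_x, rec$value[v])
  amplitude <- rep(NA_real_, nrow(seq))
  amplitude[incl] <- beta[seq_along(incl)]
  tibble::tibble(trial = seq$trial, cs = seq$cs, reinforced = seq$reinforced,
                 amplitude = amplitude, excluded = trial_flags$excluded)
}
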