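#' SCR pipeline configuration
#'
#' First-order bidirectional Butterworth band-pass 0.0159-5 Hz, down-sampling
#' to 10 Hz, linear interpolation of artifact periods shorter than 2 s
#' (longer artifacts exclude the trial), and model inversion with a
#' fixed-dispersion anticipatory response at CS onset (free latency in 0-2 s)
#' plus a fixed-latency evoked response at the potential US onset of every
#' trial.
#'
#' @param bandpass_hz Band-pass edges in Hz.
#' @param filter_order Butterworth order (1, per the preprocessing chain).
#' @param target_rate_hz Analysis rate after down-sampling.
#' @param artifact_interp_max_s Artifacts shorter than this are interpolated;
#'   longer ones exclude overlapping trials.
#' @param latency_bounds_s Anticipatory latency bounds after CS onset.
#' @param latency_step_s Latency profiling grid step.
#' @param dispersion_s SD of the Gaussian anticipatory input function.
#' @param evoked_delay_s Fixed delay of the evoked response after US onset.
#' @param trial_window_s Response window after CS onset used for trial
#'   exclusion and empty-data checks.
#' @param kernel_args Overrides for the canonical skin conductance kernel.
#' @param n_sweeps Latency coordinate-descent sweeps.
#' @return An `scr_config` list.
#' @export
scr_config <- function(bandpass_hz = c(0.0159, 5), filter_order = 1,
                       target_rate_hz = 10, artifact_interp_max_s = 2,
                       latency_bounds_s = c(0, 2), latency_step_s = 0.05,
                       dispersion_s = 0.3, evoked_delay_s = 0,
                       trial_window_s = 5,
                       kernel_args = list(), n_sweeps = 2) {
  stopifnot(bandpass_hz[1] > 0, bandpass_hz[1] < bandpass_hz[2],
            latency_bounds_s[1] >= 0, latency_bounds_s[2] > latency_bounds_s[1])
  structure(as.list(environment()), class = "scr_config")
}

#' Preprocess skin conductance: artifact handling, filtering, down-sampling
#'
#' Artifact samples are masked invalid for model inversion; all invalid runs
#' are linearly interpolated for filtering only. The trace is band-pass
#' filtered bidirectionally and decimated to the analysis rate with the mask
#' propagated. Artifact periods longer than `artifact_interp_max_s` are kept
#' in the attribute `"long_artifacts"` so [invert_scr()] can exclude
#' overlapping trials.
#'
#' @param raw A [channel_recording()] (skin conductance, uS).
#' @param artifacts Annotation tibble (`start_s`, `end_s`, optional `label`);
#'   overlapping or inverted intervals raise an error.
#' @param config An [scr_config()].
#' @return A 10 Hz [channel_recording()] with validity mask.
#' @export
preprocess_scr <- function(raw, artifacts = NULL, config = scr_config()) {
  rate <- ch_rate(raw)
  if (!is.null(artifacts) && nrow(artifacts) > 1) {
    o <- order(artifacts$start_s)
    if (any(artifacts$end_s[o][-nrow(artifacts)] > artifacts$start_s[o][-1])) {
      stop("overlapping artifact intervals", call. = FALSE)
    }
  }
  rec <- mask_intervals(raw, artifacts)
  x <- interp_invalid(rec$value, rec$valid)
  # demean before the high-pass so the tonic level does not excite an edge
  # transient (corner time constant ~10 s)
  x <- butter_filtfilt(x - mean(x), rate, config$bandpass_hz, "pass",
                       config$filter_order, pad_s = 30)
  fac <- round(rate / config$target_rate_hz)
  stopifnot(fac >= 1, abs(rate / fac - config$target_rate_hz) < 1e-9)
  # a decimated sample is valid only if its whole source block is valid
  nblk <- floor(length(x) / fac)
  vblk <- matrix(rec$valid[seq_len(nblk * fac)], nrow = fac)
  valid10 <- as.logical(apply(vblk, 2, all))
  out <- channel_recording(decimate_by(x, fac)[seq_len(nblk)],
                           config$target_rate_hz,
                           units = ch_units(raw), channel = ch_name(raw),
                           valid = valid10)
  long <- if (is.null(artifacts)) NULL else
    artifacts[artifacts$end_s - artifacts$start_s > config$artifact_interp_max_s, ]
  attr(out, "long_artifacts") <- long
  out
}

.scr_basis_cache <- new.env(parent = emptyenv())

# Band-pass-matched design waveforms at the analysis rate: the anticipatory
# composite (per latency) and the evoked kernel, each filtered exactly like
# the data (at the raw rate, then decimated), truncated to `keep_s`. Cached
# per configuration (the basis depends only on the config, not the data).
scr_design_basis <- function(config, raw_rate = 1000, keep_s = 70,
                             pre_s = 10) {
  key <- rlang::hash(list(config, raw_rate, keep_s, pre_s))
  if (!is.null(.scr_basis_cache[[key]])) return(.scr_basis_cache[[key]])
  kern <- do.call(canonical_kernel,
                  c(list(type = "scrf", rate = raw_rate), config$kernel_args))
  pad_s <- 30
  fac <- round(raw_rate / config$target_rate_hz)
  filt_ds <- function(wave) {
    x <- c(numeric(pad_s * raw_rate), wave,
           numeric(max(0, (pad_s + keep_s) * raw_rate - length(wave))))
    x <- butter_filtfilt(x, raw_rate, config$bandpass_hz, "pass",
                         config$filter_order, pad_s = 30)
    x <- decimate_by(x, fac)
    # keep `pre_s` seconds before the event: the zero-phase filter is
    # acausal, so the filtered response starts before its input does
    i0 <- (pad_s - pre_s) * config$target_rate_hz + 1
    x[i0:(i0 + (pre_s + keep_s) * config$target_rate_hz - 1)]
  }
  lats <- seq(config$latency_bounds_s[1], config$latency_bounds_s[2],
              by = config$latency_step_s)
  ant <- lapply(lats, function(l) filt_ds(scr_ant_wave(raw_rate, l, kern,
                                                       config$dispersion_s)))
  out <- list(latencies = lats, ant = ant, ev = filt_ds(kern$y),
              pre = pre_s * config$target_rate_hz)
  .scr_basis_cache[[key]] <- out
  out
}

#' Invert the anticipatory/evoked SCR model over a session
#'
#' Jointly estimates, for every trial, a non-negative anticipatory amplitude
#' with free latency (0-2 s after CS onset) and a non-negative evoked
#' amplitude at the potential US onset — modeled on all trials whether or not
#' a US occurred, so the algorithm is blind to reinforcement. Overlapping
#' responses of neighboring trials are summed in the forward model and
#' resolved by joint non-negative least squares; latencies are profiled on a
#' grid by coordinate descent (amplitudes are linear given the latencies, so
#' the procedure is deterministic). Masked samples are excluded from all
#' inner products; trials overlapped by long artifacts, or with no valid data
#' in their response window, are excluded.
#'
#' @param trace 10 Hz [channel_recording()] from [preprocess_scr()].
#' @param seq Timed `trial_sequence`.
#' @param config An [scr_config()].
#' @return Tibble with one row per trial: `trial`, `cs`, `reinforced`,
#'   `anticipatory_amplitude`, `anticipatory_latency_s`, `evoked_amplitude`,
#'   `excluded`, `reason`.
#' @export
invert_scr <- function(trace, seq, config = scr_config()) {
  rt <- config$target_rate_hz
  n <- nrow(trace)
  nt <- nrow(seq)
  basis <- scr_design_basis(config, raw_rate = 1000)
  klen <- length(basis$ev)
  us_t <- seq$cs_onset_s + seq$cs_duration_s - 0.5 + config$evoked_delay_s
  # columns start `pre` samples before the event (acausal filter response)
  ant_at <- round(seq$cs_onset_s * rt) + 1 - basis$pre
  ev_at <- round(us_t * rt) + 1 - basis$pre
  valid <- trace$valid
  y <- trace$value

  excluded <- rep(FALSE, nt)
  reason <- rep(NA_character_, nt)
  long <- attr(trace, "long_artifacts")
  for (i in seq_len(nt)) {
    w0 <- seq$cs_onset_s[i]
    w1 <- w0 + config$trial_window_s
    if (!is.null(long) && nrow(long) > 0 &&
        any(long$start_s < w1 & long$end_s > w0)) {
      excluded[i] <- TRUE
      reason[i] <- "long-artifact"
    } else {
      idx <- which(trace$time >= w0 & trace$time < w1)
      if (!any(valid[idx])) {
        excluded[i] <- TRUE
        reason[i] <- "no-valid-data"
      }
    }
  }

  place <- function(wave, at) {
    col <- numeric(n)
    add_wave_at(col, wave, at)
  }
  lat_idx <- rep(which.min(abs(basis$latencies - 1)), nt)  # start at 1 s
  X <- matrix(0, n, 2 * nt)
  for (i in seq_len(nt)) {
    if (excluded[i]) next
    X[, i] <- place(basis$ant[[lat_idx[i]]], ant_at[i])
    X[, nt + i] <- place(basis$ev, ev_at[i])
  }
  beta <- numeric(2 * nt)
  # NNLS through the normal equations (Cholesky square root), which is much
  # cheaper than running the active-set solver on the full-length design.
  # Columns span the response plus the slow high-pass undershoot tail, so
  # overlap with several following trials is modeled rather than truncated.
  solve_nnls <- function() {
    live <- which(colSums(abs(X)) > 0)
    Xv <- X[valid, live, drop = FALSE]
    xtx <- crossprod(Xv)
    diag(xtx) <- diag(xtx) * (1 + 1e-10)
    R <- chol(xtx)
    z <- backsolve(R, crossprod(Xv, y[valid]), transpose = TRUE)
    fit <- pracma::lsqnonneg(R, as.numeric(z))
    b <- numeric(2 * nt)
    b[live] <- fit$x
    b
  }
  beta <- solve_nnls()
  for (sweep in seq_len(config$n_sweeps)) {
    fitted <- as.numeric(X %*% beta)
    for (i in seq_len(nt)) {
      if (excluded[i]) next
      r <- y - fitted + X[, i] * beta[i]
      best <- c(rss = Inf, amp = 0, j = lat_idx[i])
      for (j in seq_along(basis$latencies)) {
        at <- ant_at[i]
        idx <- max(1, at):min(n, at + klen - 1)
        idx <- idx[valid[idx]]
        if (length(idx) == 0) next
        w <- basis$ant[[j]][idx - at + 1]
        ww <- sum(w * w)
        if (ww == 0) next
        dot <- sum(w * r[idx])
        amp <- max(0, dot / ww)
        rss <- sum(r[idx]^2) - 2 * amp * dot + amp^2 * ww
        if (rss < best["rss"] - 1e-12) best <- c(rss = rss, amp = amp, j = j)
      }
      if (is.finite(best["rss"]) && best["j"] != lat_idx[i]) {
        lat_idx[i] <- best["j"]
        fitted <- fitted - X[, i] * beta[i]
        X[, i] <- place(basis$ant[[lat_idx[i]]], ant_at[i])
        beta[i] <- best["amp"]
        fitted <- fitted + X[, i] * beta[i]
      }
    }
    beta <- solve_nnls()
  }
  out <- tibble::tibble(
    trial = seq$trial, cs = seq$cs, reinforced = seq$reinforced,
    anticipatory_amplitude = ifelse(excluded, NA_real_, beta[seq_len(nt)]),
    anticipatory_latency_s = ifelse(excluded, NA_real_,
                                    basis$latencies[lat_idx]),
    evoked_amplitude = ifelse(excluded, NA_real_, beta[nt + seq_len(nt)]),
    excluded = excluded, reason = reason
  )
  out
}

#' Keep nonreinforced, non-excluded trials for statistical analysis
#'
#' Reinforced trials are dropped to avoid contamination of the anticipatory
#' estimate by US responses; excluded trials carry no amplitudes. The analyzed
#' measure is the anticipatory amplitude.
#'
#' @param estimates Output of [invert_scr()].
#' @return Filtered tibble with an `amplitude` column (the anticipatory
#'   amplitude); warns when empty.
#' @export
select_scr_trials <- function(estimates) {
  out <- estimates |>
    dplyr::filter(!.data$reinforced, !.data$excluded) |>
    dplyr::mutate(amplitude = .data$anticipatory_amplitude)
  if (nrow(out) == 0) warning("no analyzable SCR trials after selection")
  out
}
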