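#' Simulation configuration for a synthetic conditioning cohort
#'
#' Defines the study conditions the forward simulator emulates: two groups
#' (placebo / drug), three CS types with 50% reinforcement of
#' each CS+, conditioned discrimination on every measure, drug modulation of
#' the retention/relearning CS+ effect, startle habituation and extinction
#' decay, multiplicative per-participant gain on the startle channel, blink
#' gaps in the pupil and motion artifacts in skin conductance.
#'
#' @param n_per_group Participants per group.
#' @param seed Integer seed (mandatory); a config fully determines the cohort.
#' @param rates Per-channel sampling rates in Hz.
#' @param effects Effect structure: `cs_plus_vs_minus` (multiplier on CS+
#'   amplitude relative to CS-), `drug_modulation` (multiplier on the
#'   retention-phase CS+ surplus in the drug group, and its inverse on the
#'   relearning surplus), `extinction_rate` and `habituation_rate` (per-trial
#'   exponential decays).
#' @param base_amplitude Mean CS- response amplitude per measure, in channel
#'   units (SEBR envelope a.u., SCR uS, PSR a.u., HPR ms of heart-period
#'   lengthening).
#' @param noise Channel noise SDs (channel units) and slow-drift magnitudes.
#' @param artifact_rates Artifact incidence: `pupil_blink_per_min`,
#'   `sc_artifact_per_min`.
#' @param participant_gain_sd Lognormal SD of the multiplicative participant
#'   gain (applied to the startle channel only).
#' @param trial_sd_log Lognormal SD of trial-to-trial amplitude variability.
#' @param evoked_scr_factor US-evoked SCR amplitude relative to anticipatory.
#' @param baseline_hp_ms Baseline heart period.
#' @param mains_amplitude 50 Hz mains interference amplitude on the EMG
#'   channel (0 = off).
#' @param kernel_args Optional per-measure list of [canonical_kernel()]
#'   argument overrides, to deliberately mis-specify the generator's kernels
#'   relative to the fitters in robustness tests.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = 10,
                       seed,
                       rates = list(emg = 1000, sc = 1000, pupil = 500, ecg = 1000),
                       effects = list(cs_plus_vs_minus = 2,
                                      drug_modulation = 1.5,
                                      extinction_rate = 0.05,
                                      habituation_rate = 0.02),
                       base_amplitude = list(sebr = 1, scr = 0.4, psr = 0.3, hpr = 8),
                       noise = list(emg = 0.2, sc = 0.02, sc_drift = 0.5,
                                    pupil = 0.05, pupil_drift = 0.1, ecg = 0.05),
                       artifact_rates = list(pupil_blink_per_min = 4,
                                             sc_artifact_per_min = 0.2),
                       participant_gain_sd = 0.4,
                       trial_sd_log = 0.35,
                       evoked_scr_factor = 3,
                       baseline_hp_ms = 900,
                       mains_amplitude = 0,
                       kernel_args = list()) {
  if (missing(seed)) stop("sim_config(): seed is mandatory", call. = FALSE)
  stopifnot(all(unlist(rates) > 0),
            all(unlist(artifact_rates) >= 0),
            effects$cs_plus_vs_minus > 0, effects$drug_modulation > 0,
            effects$extinction_rate >= 0, effects$habituation_rate >= 0,
            all(unlist(noise) >= 0), participant_gain_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

sim_kernel <- function(config, type, rate) {
  do.call(canonical_kernel,
          c(list(type = type, rate = rate), config$kernel_args[[type]]))
}

#' Ground-truth per-trial amplitudes for one participant and phase
#'
#' Encodes the statistical structure the analysis assumes: CS+ > CS-
#' discrimination, drug modulation of the retention CS+ surplus (and reduced
#' relearning in the drug group), exponential habituation across trials and
#' extinction of the CS+ surplus during retention, lognormal trial-to-trial
#' variability, and a multiplicative participant gain on the startle measure.
#'
#' @param seq A timed `trial_sequence`.
#' @param group `"placebo"` or `"drug"`.
#' @param gain Participant gain (applied to the `sebr` measure).
#' @param config A [sim_config()].
#' @return Tibble with one row per trial x measure: columns `trial`, `cs`,
#'   `measure`, `amplitude` (channel units, the value fed to the forward
#'   model).
#' @export
simulate_truth <- function(seq, group, gain, config) {
  phase <- seq_phase(seq)
  ef <- config$effects
  measures <- names(config$base_amplitude)
  # per-CS trial counter (extinction operates within CS)
  tcs <- stats::ave(seq$trial, seq$cs, FUN = seq_along)
  is_plus <- seq$cs %in% CS_PLUS
  drug_factor <- switch(phase,
    retention = if (group == "drug") ef$drug_modulation else 1,
    relearning = if (group == "drug") 1 / ef$drug_modulation else 1,
    1
  )
  surplus <- (ef$cs_plus_vs_minus - 1) * drug_factor
  if (phase == "retention") {
    surplus <- surplus * exp(-ef$extinction_rate * (tcs - 1))
  }
  cs_mult <- 1 + surplus * is_plus
  hab <- exp(-ef$habituation_rate * (seq$trial - 1))
  purrr::map_dfr(measures, function(m) {
    base <- config$base_amplitude[[m]]
    g <- if (m == "sebr") gain else 1
    mu <- base * g * cs_mult * hab
    amp <- mu * exp(stats::rnorm(nrow(seq), 0, config$trial_sd_log))
    tibble::tibble(trial = seq$trial, cs = seq$cs, measure = m, amplitude = amp)
  })
}

session_samples <- function(seq, rate) {
  round((attr(seq, "duration_s")) * rate)
}

#' Forward-simulate the orbicularis oculi EMG channel
#'
#' Each startle probe elicits a blink burst: a 220 Hz carrier whose
#' rectified-smoothed envelope equals the true amplitude times the canonical
#' startle kernel, at an onset jittered uniformly within the fitter's onset
#' search window. Broadband baseline noise and optional 50 Hz mains
#' interference are added.
#'
#' @param seq Timed `trial_sequence` with probe onsets.
#' @param amplitudes Per-trial true amplitudes (length `nrow(seq)`).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param jitter_max_s Maximum onset jitter (default 0.12 s, inside the
#'   0-150 ms search window).
#' @return A [channel_recording()] (1000 Hz by default) with the drawn onsets
#'   stored in attribute `"true_onsets"`.
#' @export
simulate_emg <- function(seq, amplitudes, config, seed, jitter_max_s = 0.12) {
  stopifnot(any(!is.na(seq$probe_onset_s)))
  rate <- config$rates$emg
  n <- session_samples(seq, rate)
  kern <- sim_kernel(config, "sebr", rate)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    x <- stats::rnorm(n, 0, config$noise$emg)
    onsets <- seq$probe_onset_s + stats::runif(nrow(seq), 0, jitter_max_s)
    t_rel <- kern$t
    for (i in seq_len(nrow(seq))) {
      at <- round(onsets[i] * rate) + 1
      # 220 Hz: mid-band for the 50-470 Hz chain, off the mains harmonics
      carrier <- sin(2 * pi * 220 * t_rel + stats::runif(1, 0, 2 * pi))
      burst <- amplitudes[i] * (pi / 2) * kern$y * carrier
      x <- add_wave_at(x, burst, at)
    }
    if (config$mains_amplitude > 0) {
      x <- x + config$mains_amplitude * sin(2 * pi * 50 * seq_len(n) / rate)
    }
    rec <- channel_recording(x, rate, units = "a.u.", channel = "emg")
    attr(rec, "true_onsets") <- onsets
    rec
  })
}

# full linear convolution via FFT, zero-padded to a 2-3-5-smooth length
# (mixed-radix FFT is orders of magnitude slower on lengths with large prime
# factors)
conv_open <- function(x, y) {
  n <- length(x) + length(y) - 1L
  N <- stats::nextn(n, c(2, 3, 5))
  z <- Re(stats::fft(stats::fft(c(x, numeric(N - length(x)))) *
                       stats::fft(c(y, numeric(N - length(y)))),
                     inverse = TRUE)) / N
  z[seq_len(n)]
}

# Composite anticipatory SCR waveform: fixed-dispersion Gaussian input
# convolved with the SCRF, peak-normalized once so the free coefficient is a
# peak amplitude in uS. `latency_s` shifts the input centre after CS onset.
scr_ant_wave <- function(rate, latency_s, kern, dispersion_s = 0.3) {
  pad <- 4 * dispersion_s
  bump <- gaussian_bump(pad + latency_s, dispersion_s, rate,
                        duration_s = pad + 2 + 4 * dispersion_s)
  w <- conv_open(bump, kern$y) / rate
  w <- w / max(conv_open(gaussian_bump(pad, dispersion_s, rate, pad * 2),
                         kern$y) / rate)
  # drop the pre-onset pad so index 1 corresponds to CS onset
  w[-seq_len(round(pad * rate))]
}

#' Forward-simulate the skin conductance channel
#'
#' Tonic baseline with slow drift, anticipatory responses at CS onset (latency
#' drawn uniformly in 0-2 s), US-evoked responses on reinforced trials, step
#' artifacts at the configured rate, and measurement noise.
#'
#' @inheritParams simulate_emg
#' @return A list: `recording` (a [channel_recording()], uS), `artifacts`
#'   (annotation tibble `start_s`, `end_s`, `label`) and `truth` (per-trial
#'   tibble with the drawn anticipatory latency and evoked amplitude).
#' @export
simulate_scr <- function(seq, amplitudes, config, seed) {
  rate <- config$rates$sc
  n <- session_samples(seq, rate)
  kern <- sim_kernel(config, "scrf", rate)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    t <- (seq_len(n) - 1) / rate
    drift <- config$noise$sc_drift *
      (sin(2 * pi * t / 300 + stats::runif(1, 0, 2 * pi)) +
         0.5 * sin(2 * pi * t / 97 + stats::runif(1, 0, 2 * pi)))
    x <- 2 + drift + stats::rnorm(n, 0, config$noise$sc)
    lat <- stats::runif(nrow(seq), 0, 2)
    ev_amp <- ifelse(seq$reinforced, config$evoked_scr_factor * amplitudes, 0)
    for (i in seq_len(nrow(seq))) {
      w <- scr_ant_wave(rate, lat[i], kern)
      x <- add_wave_at(x, amplitudes[i] * w, round(seq$cs_onset_s[i] * rate) + 1)
      if (ev_amp[i] > 0) {
        x <- add_wave_at(x, ev_amp[i] * kern$y, round(seq$us_onset_s[i] * rate) + 1)
      }
    }
    dur_s <- attr(seq, "duration_s")
    n_art <- stats::rpois(1, config$artifact_rates$sc_artifact_per_min * dur_s / 60)
    artifacts <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                                label = character(0))
    if (n_art > 0) {
      starts <- sort(stats::runif(n_art, 0, dur_s - 5))
      lens <- stats::runif(n_art, 0.5, 4)  # around the 2 s interpolation threshold
      for (j in seq_len(n_art)) {
        idx <- which(t >= starts[j] & t < starts[j] + lens[j])
        x[idx] <- x[idx] + stats::runif(1, -1, 1) * 2
      }
      # merge any overlapping draws into disjoint annotation intervals
      s0 <- starts[1]
      e0 <- starts[1] + lens[1]
      merged <- list()
      for (j in seq_len(n_art)[-1]) {
        if (starts[j] <= e0) {
          e0 <- max(e0, starts[j] + lens[j])
        } else {
          merged[[length(merged) + 1]] <- c(s0, e0)
          s0 <- starts[j]
          e0 <- starts[j] + lens[j]
        }
      }
      merged[[length(merged) + 1]] <- c(s0, e0)
      m <- do.call(rbind, merged)
      artifacts <- tibble::tibble(start_s = m[, 1], end_s = m[, 2],
                                  label = "motion")
    }
    list(recording = channel_recording(x, rate, units = "uS", channel = "sc"),
         artifacts = artifacts,
         truth = tibble::tibble(trial = seq$trial, ant_latency_s = lat,
                                evoked_amplitude = ev_amp))
  })
}

#' Forward-simulate pupil area and gaze for both eyes
#'
#' Pupil area is baseline plus linear drift plus per-trial anticipatory
#' impulses convolved with the pupil kernel; blink gaps (missing runs) are
#' inserted per eye at the configured rate, and gaze occasionally wanders
#' beyond the 5 degree box around screen centre.
#'
#' @inheritParams simulate_emg
#' @param blink_rate_mult Length-2 multiplier on the blink rate for
#'   (left, right) eye.
#' @return A list: `left`, `right` ([channel_recording()]s with extra gaze
#'   columns `gx`, `gy` in degrees), `blinks` (annotation tibble with `eye`
#'   column).
#' @export
simulate_pupil <- function(seq, amplitudes, config, seed,
                           blink_rate_mult = c(1, 1)) {
  rate <- config$rates$pupil
  n <- session_samples(seq, rate)
  kern <- sim_kernel(config, "psrf", rate)
  dur_s <- attr(seq, "duration_s")
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    t <- (seq_len(n) - 1) / rate
    base <- 1 + config$noise$pupil_drift * (t / dur_s - 0.5)
    resp <- numeric(n)
    for (i in seq_len(nrow(seq))) {
      resp <- add_wave_at(resp, amplitudes[i] * kern$y,
                          round(seq$cs_onset_s[i] * rate) + 1)
    }
    gx <- stats::rnorm(n, 0, 0.5)
    gy <- stats::rnorm(n, 0, 0.5)
    n_exc <- stats::rpois(1, dur_s / 60)  # ~1 gaze excursion per minute
    exc <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
    if (n_exc > 0) {
      starts <- stats::runif(n_exc, 0, dur_s - 3)
      lens <- stats::runif(n_exc, 0.5, 2)
      for (j in seq_len(n_exc)) {
        idx <- t >= starts[j] & t < starts[j] + lens[j]
        gx[idx] <- gx[idx] + stats::runif(1, 6, 10) * sample(c(-1, 1), 1)
      }
    }
    eyes <- purrr::map(1:2, function(e) {
      area <- base + resp + stats::rnorm(n, 0, config$noise$pupil)
      rate_blinks <- config$artifact_rates$pupil_blink_per_min *
        blink_rate_mult[e] * dur_s / 60
      nb <- stats::rpois(1, rate_blinks)
      blinks <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
      if (nb > 0) {
        starts <- stats::runif(nb, 0, dur_s - 1)
        lens <- stats::runif(nb, 0.1, 0.5)
        blinks <- tibble::tibble(start_s = starts, end_s = starts + lens)
        for (j in seq_len(nb)) {
          area[t >= starts[j] & t < starts[j] + lens[j]] <- 0
        }
      }
      rec <- channel_recording(area, rate, units = "a.u.",
                               channel = c("pupil_left", "pupil_right")[e],
                               extra = list(gx = gx, gy = gy))
      list(rec = rec, blinks = blinks)
    })
    blinks <- dplyr::bind_rows(
      dplyr::mutate(eyes[[1]]$blinks, eye = "left", label = "blink"),
      dplyr::mutate(eyes[[2]]$blinks, eye = "right", label = "blink")
    )
    list(left = eyes[[1]]$rec, right = eyes[[2]]$rec, blinks = blinks)
  })
}

#' Forward-simulate the ECG channel
#'
#' An instantaneous heart-period trace (baseline plus conditionwise
#' heart-period kernel contributions plus respiratory sinus arrhythmia)
#' drives an integrate-and-fire beat generator; a synthetic QRS-T template is
#' placed at each R-spike time and measurement noise added.
#'
#' @inheritParams simulate_emg
#' @param amplitudes Per-trial true heart-period amplitudes in ms (positive =
#'   lengthening / bradycardia).
#' @return A [channel_recording()] (mV-scale a.u.) with true R-spike times in
#'   attribute `"true_spikes"` (seconds).
#' @export
simulate_ecg <- function(seq, amplitudes, config, seed) {
  rate <- config$rates$ecg
  n <- session_samples(seq, rate)
  hp_rate <- 100  # instantaneous heart-period trace resolution
  n_hp <- session_samples(seq, hp_rate)
  kern <- sim_kernel(config, "hprf", hp_rate)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    t_hp <- (seq_len(n_hp) - 1) / hp_rate
    hp <- rep(config$baseline_hp_ms, n_hp) +
      10 * sin(2 * pi * 0.25 * t_hp + stats::runif(1, 0, 2 * pi))
    for (i in seq_len(nrow(seq))) {
      hp <- add_wave_at(hp, amplitudes[i] * kern$y,
                        round(seq$cs_onset_s[i] * hp_rate) + 1)
    }
    # integrate and fire
    spikes <- numeric(0)
    tk <- 0.3
    dur_s <- attr(seq, "duration_s")
    while (tk < dur_s - 0.5) {
      spikes <- c(spikes, tk)
      hp_now <- hp[min(n_hp, floor(tk * hp_rate) + 1)]
      tk <- tk + hp_now / 1000
    }
    x <- stats::rnorm(n, 0, config$noise$ecg)
    tmpl_t <- seq(-0.05, 0.35, by = 1 / rate)
    template <- stats::dnorm(tmpl_t, 0, 0.008) * 0.008 * sqrt(2 * pi) -
      0.15 * stats::dnorm(tmpl_t, -0.025, 0.01) * 0.01 * sqrt(2 * pi) -
      0.15 * stats::dnorm(tmpl_t, 0.025, 0.01) * 0.01 * sqrt(2 * pi) +
      0.2 * stats::dnorm(tmpl_t, 0.25, 0.05) * 0.05 * sqrt(2 * pi)
    for (s in spikes) {
      x <- add_wave_at(x, template, round((s - 0.05) * rate) + 1)
    }
    rec <- channel_recording(x, rate, units = "a.u.", channel = "ecg")
    attr(rec, "true_spikes") <- spikes
    rec
  })
}

#' Forward-simulate a full cohort with known ground truth
#'
#' For each participant and phase, draws a constrained trial sequence, the
#' ground-truth per-trial amplitudes, and the raw physiological channels, and
#' assembles session bundles. Channels follow the study design: skin
#' conductance, pupil and ECG are simulated for acquisition and relearning;
#' EMG (with startle probes) for retention. Identical seeds give identical
#' cohorts.
#'
#' @param config A [sim_config()].
#' @param phases Phases to simulate.
#' @param channels Channels to simulate (subset of
#'   `c("emg", "sc", "pupil", "ecg")`); defaults to the channels the study
#'   analyzes per phase.
#' @return A list: `bundles` (named list of session bundles, see
#'   [write_bundle()]), `truth` (tibble: participant, group, phase, trial,
#'   cs, measure, amplitude, gain), `code_map` (blind-code to group mapping).
#' @export
simulate_cohort <- function(config,
                            phases = c("acquisition", "retention"),
                            channels = NULL) {
  n <- 2 * config$n_per_group
  base_seed <- as.integer(config$seed) %% 100000L
  groups <- rep(c("placebo", "drug"), each = config$n_per_group)
  codes <- withr::with_seed(base_seed, {
    code_of <- sample(c("A", "B"))
    stats::setNames(code_of, c("placebo", "drug"))
  })
  gains <- withr::with_seed(base_seed + 1L,
                            exp(stats::rnorm(n, 0, config$participant_gain_sd)))
  bundles <- list()
  truth <- list()
  for (p in seq_len(n)) {
    for (ph_i in seq_along(phases)) {
      phase <- phases[ph_i]
      sd0 <- base_seed + 1000L * p + 100L * ph_i
      seq <- generate_trial_sequence(phase, seed = sd0)
      tru <- withr::with_seed(sd0 + 1L,
                              simulate_truth(seq, groups[p], gains[p], config))
      chans <- channels %||% switch(phase,
        acquisition = c("sc", "pupil", "ecg"),
        relearning = c("sc", "pupil", "ecg"),
        retention = "emg",
        reminder = character(0)
      )
      amp_of <- function(m) tru$amplitude[tru$measure == m]
      ch_list <- list()
      annotations <- tibble::tibble(channel = character(0), start_s = numeric(0),
                                    end_s = numeric(0), label = character(0))
      if ("emg" %in% chans) {
        ch_list$emg <- simulate_emg(seq, amp_of("sebr"), config, seed = sd0 + 2L)
      }
      if ("sc" %in% chans) {
        scr <- simulate_scr(seq, amp_of("scr"), config, seed = sd0 + 3L)
        ch_list$sc <- scr$recording
        if (nrow(scr$artifacts)) {
          annotations <- dplyr::bind_rows(
            annotations,
            dplyr::mutate(scr$artifacts, channel = "sc")
          )
        }
      }
      if ("pupil" %in% chans) {
        pup <- simulate_pupil(seq, amp_of("psr"), config, seed = sd0 + 4L)
        ch_list$pupil_left <- pup$left
        ch_list$pupil_right <- pup$right
        if (nrow(pup$blinks)) {
          annotations <- dplyr::bind_rows(
            annotations,
            dplyr::mutate(pup$blinks,
                          channel = paste0("pupil_", .data$eye),
                          eye = NULL)
          )
        }
      }
      if ("ecg" %in% chans) {
        ch_list$ecg <- simulate_ecg(seq, amp_of("hpr"), config, seed = sd0 + 5L)
      }
      id <- sprintf("sub-%02d", p)
      bundles[[paste(id, phase, sep = "_")]] <- list(
        manifest = list(version = 1L, participant = id,
                        group_code = unname(codes[groups[p]]), phase = phase,
                        duration_s = attr(seq, "duration_s"),
                        rates = purrr::map(ch_list, ch_rate),
                        units = purrr::map(ch_list, ch_units)),
        channels = ch_list,
        events = tibble::as_tibble(seq),
        annotations = annotations
      )
      truth[[paste(id, phase, sep = "_")]] <-
        dplyr::mutate(tru, participant = id, group = groups[p],
                      phase = phase, gain = gains[p])
    }
  }
  list(bundles = bundles,
       truth = dplyr::bind_rows(truth),
       code_map = tibble::tibble(code = unname(codes),
                                 group = names(codes)))
}
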