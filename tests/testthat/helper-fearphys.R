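# shared fixtures, built in code

# zero-noise, artifact-free configuration for forward-inverse identity checks
noiseless_config <- function(seed = 1, ...) {
  sim_config(
    n_per_group = 1, seed = seed, trial_sd_log = 0,
    participant_gain_sd = 0,
    noise = list(emg = 0, sc = 0, sc_drift = 0, pupil = 0, pupil_drift = 0,
                 ecg = 0),
    artifact_rates = list(pupil_blink_per_min = 0, sc_artifact_per_min = 0),
    ...
  )
}

# minimal single-trial sequence for windowed fitting tests
one_trial_seq <- function(cs_onset_s = 20, duration_s = 60, cs = "CSr+",
                          reinforced = TRUE, phase = "acquisition") {
  seq <- tibble::tibble(
    trial = 1L, cs = cs, reinforced = reinforced, iti_s = 9,
    cs_onset_s = cs_onset_s, cs_duration_s = 4,
    us_onset_s = if (reinforced) cs_onset_s + 3.5 else NA_real_,
    probe_onset_s = NA_real_
  )
  seq <- fearphys:::new_trial_sequence(seq, phase, 1)
  attr(seq, "duration_s") <- duration_s
  seq
}

# trialwise estimate table with a known drug x CS effect (direct generation,
# no signal simulation; for statistical-layer tests)
make_trial_table <- function(n_per_group, b_cs = 0, b_int = 0, sd_p = 0.3,
                             sd_e = 0.5, seed = 1, phase = "retention") {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(2 * n_per_group), function(p) {
      g <- if (p <= n_per_group) "placebo" else "drug"
      s <- generate_trial_sequence(phase, seed = seed * 1000 + p,
                                   timing = FALSE)
      u <- stats::rnorm(1, 0, sd_p)
      tibble::tibble(
        participant = sprintf("p%02d", p), group = g,
        trial = s$trial, cs = s$cs,
        amplitude = 1 + u + b_cs * (s$cs != "CS-") +
          b_int * (s$cs != "CS-") * (g == "drug") +
          stats::rnorm(nrow(s), 0, sd_e)
      )
    })
  })
}

# per-participant CS+/CS- difference table for cross-validation tests
make_diff_table <- function(n_per_group, effect = 0, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      group = rep(c("placebo", "drug"), each = n_per_group),
      diff = stats::rnorm(2 * n_per_group, 0, sd) +
        effect * rep(c(0, 1), each = n_per_group)
    )
  })
}
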