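test_that("gaze geometry matches the trigonometric oracle", {
  off <- c(-10, -2, 0, 3, 15)
  expect_equal(gaze_cm_to_deg(off, 70), atan2(off, 70) * 180 / pi)
  # 5 degrees at 70 cm is about 6.1 cm on screen
  expect_equal(gaze_cm_to_deg(70 * tan(5 * pi / 180), 70), 5)
})

test_that("cleaning masks blinks, out-of-box gaze, and zero-area samples", {
  rate <- 500
  n <- 10 * rate
  gx <- numeric(n)
  gx[(3 * rate):(4 * rate)] <- 6  # 1 s excursion to 6 degrees
  rec <- channel_recording(rep(1, n), rate, channel = "pupil_left",
                           extra = list(gx = gx, gy = numeric(n)))
  blinks <- tibble::tibble(start_s = 7, end_s = 7.3)
  out <- clean_pupil(rec, blinks, pupil_config())
  expect_equal(ch_rate(out), 250)
  expect_false(any(out$valid[out$time >= 3.01 & out$time < 4]))
  expect_false(any(out$valid[out$time >= 7 & out$time < 7.3]))
  expect_true(all(out$valid[out$time < 2.9]))
  clean <- channel_recording(rep(1, n), rate, channel = "pupil_left",
                             extra = list(gx = numeric(n), gy = numeric(n)))
  expect_true(all(clean_pupil(clean, tibble::tibble(start_s = numeric(0),
                                                    end_s = numeric(0)))$valid))
})

test_that("eye selection takes fewer missing samples, tie goes left", {
  mk <- function(nbad, channel) {
    v <- rep(TRUE, 100)
    if (nbad > 0) v[seq_len(nbad)] <- FALSE
    channel_recording(rep(1, 100), 250, channel = channel, valid = v)
  }
  expect_equal(ch_name(select_eye(mk(10, "pupil_left"), mk(5, "pupil_right"))),
               "pupil_right")
  expect_equal(ch_name(select_eye(mk(5, "pupil_left"), mk(5, "pupil_right"))),
               "pupil_left")
  # asymmetric blink rates in the generator lead to the less blinky eye
  cfg <- sim_config(n_per_group = 1, seed = 4,
                    artifact_rates = list(pupil_blink_per_min = 6,
                                          sc_artifact_per_min = 0))
  s <- generate_trial_sequence("acquisition", seed = 8)
  amp <- rep(0.3, nrow(s))
  pup <- simulate_pupil(s, amp, cfg, seed = 2, blink_rate_mult = c(2, 0.5))
  cl <- function(side, eye_rec) {
    clean_pupil(eye_rec, pup$blinks[pup$blinks$eye == side, ])
  }
  sel <- select_eye(cl("left", pup$left), cl("right", pup$right))
  expect_equal(ch_name(sel), "pupil_right")
})

test_that("trial exclusion implements the strict <50%-in-10-s rule", {
  rate <- 250
  seq1 <- one_trial_seq(5, duration_s = 30)
  mk <- function(frac_valid) {
    v <- rep(TRUE, 30 * rate)
    win <- which(seq(0, by = 1 / rate, length.out = 30 * rate) >= 5 &
                   seq(0, by = 1 / rate, length.out = 30 * rate) < 15)
    v[win[seq_len(round((1 - frac_valid) * length(win)))]] <- FALSE
    channel_recording(rep(1, 30 * rate), rate, channel = "pupil_left", valid = v)
  }
  expect_false(exclude_pupil_trials(mk(1.0), seq1)$excluded)
  # a 49.9%-valid trial is excluded (and trips the session-level warning on
  # this one-trial toy); exactly 50% is included
  expect_warning(ex <- exclude_pupil_trials(mk(0.499), seq1), "excluded")
  expect_true(ex$excluded)
  expect_false(exclude_pupil_trials(mk(0.5), seq1)$excluded) # boundary included
  # exclusion counts equal an independent mask recount on simulated data
  cfg <- sim_config(n_per_group = 1, seed = 9,
                    artifact_rates = list(pupil_blink_per_min = 40,
                                          sc_artifact_per_min = 0))
  s <- generate_trial_sequence("acquisition", seed = 10)
  pup <- simulate_pupil(s, rep(0.3, nrow(s)), cfg, seed = 3)
  cl <- clean_pupil(pup$left, pup$blinks[pup$blinks$eye == "left", ])
  flags <- suppressWarnings(exclude_pupil_trials(cl, s))
  recount <- vapply(s$cs_onset_s, function(on) {
    mean(cl$valid[cl$time >= on & cl$time < on + 10]) < 0.5
  }, logical(1))
  expect_equal(flags$excluded, recount)
})

test_that("noiseless convolution GLM recovers amplitudes to numerical precision", {
  cfg <- noiseless_config(seed = 2)
  s <- generate_trial_sequence("acquisition", seed = 21)
  amp <- withr::with_seed(4, stats::rlnorm(nrow(s), log(0.3), 0.3))
  pup <- simulate_pupil(s, amp, cfg, seed = 9)
  cl <- clean_pupil(pup$left, pup$blinks[pup$blinks$eye == "left", ])
  est <- fit_pupil_glm(cl, s)
  expect_equal(est$amplitude, amp, tolerance = 1e-8)
})

test_that("GLM equals the explicit normal-equation oracle on a 3-trial toy session", {
  rate <- 250
  seq3 <- tibble::tibble(
    trial = 1:3, cs = c("CS-", "CSr+", "CSn+"), reinforced = FALSE,
    iti_s = 9, cs_onset_s = c(5, 18, 31), cs_duration_s = 4,
    us_onset_s = NA_real_, probe_onset_s = NA_real_
  )
  seq3 <- fearphys:::new_trial_sequence(seq3, "acquisition", 1)
  attr(seq3, "duration_s") <- 50
  kern <- canonical_kernel("psrf", rate)
  n <- 50 * rate
  amp <- c(0.4, 0.9, 0.6)
  x <- 2 + 0.3 * (seq_len(n) / n - 0.5)
  for (i in 1:3) {
    x <- fearphys:::add_wave_at(x, amp[i] * kern$y,
                                round(seq3$cs_onset_s[i] * rate) + 1)
  }
  rec <- channel_recording(x, rate, channel = "pupil_left")
  est <- fit_pupil_glm(rec, seq3)
  # explicit normal equations
  X <- cbind(
    vapply(1:3, function(i) {
      fearphys:::add_wave_at(numeric(n), kern$y,
                             round(seq3$cs_onset_s[i] * rate) + 1)
    }, numeric(n)),
    1, seq_len(n) / n - 0.5
  )
  beta <- solve(t(X) %*% X, t(X) %*% x)
  expect_equal(est$amplitude, as.numeric(beta[1:3]), tolerance = 1e-8)
  expect_equal(est$amplitude, amp, tolerance = 1e-8)
})

test_that("excluded trials carry missing amplitudes and trigger the session warning", {
  rate <- 250
  seq1 <- one_trial_seq(5, duration_s = 30)
  v <- rep(TRUE, 30 * rate)
  t <- seq(0, by = 1 / rate, length.out = 30 * rate)
  v[t >= 5 & t < 14] <- FALSE  # 90% of the 10 s window missing
  rec <- channel_recording(rep(1, 30 * rate), rate, channel = "pupil_left",
                           valid = v)
  expect_warning(flags <- exclude_pupil_trials(rec, seq1), "excluded")
  est <- fit_pupil_glm(rec, seq1, trial_flags = flags)
  expect_true(is.na(est$amplitude[1]))
})
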