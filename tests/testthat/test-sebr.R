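test_that("EMG preprocessing: zero in, zero out; mains harmonics rejected", {
  zero <- channel_recording(numeric(5000), 1000, channel = "emg")
  expect_equal(max(preprocess_emg(zero)$value), 0)
  t <- (0:9999) / 1000
  for (f0 in c(50, 150)) {
    tone <- channel_recording(sin(2 * pi * f0 * t), 1000, channel = "emg")
    out <- preprocess_emg(tone)$value
    mid <- out[2000:8000] # away from filter edges
    expect_lt(sqrt(mean(mid^2)), 0.01 * sqrt(0.5))
  }
})

test_that("EMG envelope of an in-band tone equals the rectified-sine mean 2A/pi", {
  t <- (0:9999) / 1000
  A <- 3
  tone <- channel_recording(A * sin(2 * pi * 220 * t), 1000, channel = "emg")
  env <- preprocess_emg(tone)$value[3000:7000]
  # within passband ripple of the band-pass + harmonic notches
  expect_equal(mean(env), 2 * A / pi, tolerance = 0.03)
})

test_that("EMG preprocessing rejects too-low rates and NaN input", {
  expect_error(preprocess_emg(channel_recording(numeric(100), 500, channel = "emg")),
               "below twice")
  bad <- channel_recording(c(1, NaN, 3), 1000, channel = "emg")
  expect_error(preprocess_emg(bad), "NaN")
})

test_that("variable-onset regression recovers amplitude and onset exactly on a clean envelope", {
  rate <- 1000
  kern <- canonical_kernel("sebr", rate)
  env <- numeric(3 * rate)
  at <- round((1 + 0.040) * rate) + 1
  env[at:(at + length(kern$y) - 1)] <- 2 * kern$y
  rec <- channel_recording(env, rate, channel = "emg_envelope")
  est <- fit_sebr_trial(rec, probe_onset_s = 1)
  expect_equal(est$amplitude, 2, tolerance = 1e-6)
  expect_equal(est$onset_s, 0.040)
  expect_gt(est$fit_r2, 0.999)
})

test_that("fit matches an exhaustive brute-force onset grid on a compound envelope", {
  rate <- 1000
  kern <- canonical_kernel("sebr", rate)
  env <- numeric(3 * rate)
  for (o in c(0.040, 0.045)) {
    at <- round((1 + o) * rate) + 1
    env[at:(at + length(kern$y) - 1)] <-
      env[at:(at + length(kern$y) - 1)] + kern$y
  }
  rec <- channel_recording(env, rate, channel = "emg_envelope")
  est <- fit_sebr_trial(rec, probe_onset_s = 1)
  # independent brute force: grid over offsets, closed-form LS per offset
  cfg <- emg_config()
  offs <- seq(0, 0.15, by = 0.001)
  y <- env[(1 * rate + 1):(1 * rate + round(0.15 * rate) + length(kern$y))]
  brute <- t(vapply(offs, function(o) {
    k <- numeric(length(y))
    at <- round(o * rate) + 1
    k[at:(at + length(kern$y) - 1)] <- kern$y
    amp <- max(0, sum(k * y) / sum(k * k))
    c(amp = amp, rss = sum((y - amp * k)^2))
  }, numeric(2)))
  best <- which.min(brute[, "rss"])
  expect_equal(est$onset_s, offs[best])
  expect_equal(est$amplitude, unname(brute[best, "amp"]), tolerance = 1e-8)
})

test_that("all-zero segment yields amplitude 0 with undefined onset; window errors are raised", {
  rec <- channel_recording(numeric(2000), 1000, channel = "emg_envelope")
  est <- fit_sebr_trial(rec, probe_onset_s = 0.5)
  expect_equal(est$amplitude, 0)
  expect_true(is.na(est$onset_s))
  expect_error(fit_sebr_trial(rec, probe_onset_s = 1.9), "exceeds")
})

test_that("one estimate per trial on a probed session, none missing", {
  cfg <- noiseless_config()
  s <- generate_trial_sequence("retention", seed = 6)
  amp <- rep(c(1, 2, 0.5), length.out = nrow(s))
  emg <- simulate_emg(s, amp, cfg, seed = 2)
  est <- fit_sebr(preprocess_emg(emg), s)
  expect_equal(nrow(est), 45)
  expect_true(all(is.finite(est$amplitude)))
  expect_equal(est$amplitude, amp, tolerance = 0.05)
})

test_that("CS- normalization: contract, arithmetic, errors", {
  tbl <- tibble::tibble(
    participant = "p1",
    cs = c("CS-", "CS-", "CS-", "CSr+"),
    amplitude = c(1, 2, 3, 4)
  )
  out <- normalize_sebr(tbl)
  expect_equal(mean(out$normalized_amplitude[out$cs == "CS-"]), 1)
  expect_equal(out$normalized_amplitude[4], 2)
  allc <- dplyr::mutate(tbl, amplitude = 7)
  expect_equal(normalize_sebr(allc)$normalized_amplitude, rep(1, 4))
  zero <- dplyr::mutate(tbl, amplitude = c(0, 0, 0, 4))
  expect_error(normalize_sebr(zero), "undefined")
  # random tables: CS- mean is 1 to machine precision, per participant
  withr::with_seed(8, {
    big <- tibble::tibble(
      participant = rep(c("a", "b"), each = 30),
      cs = rep(c("CS-", "CSr+", "CSn+"), 20),
      amplitude = stats::rexp(60) + 0.1
    )
  })
  nb <- normalize_sebr(big)
  ms <- tapply(nb$normalized_amplitude[nb$cs == "CS-"],
               nb$participant[nb$cs == "CS-"], mean)
  expect_equal(as.numeric(ms), c(1, 1))
})

test_that("normalized amplitudes are invariant to a multiplicative channel gain", {
  cfg <- noiseless_config()
  s <- generate_trial_sequence("retention", seed = 3)
  amp <- withr::with_seed(1, stats::rlnorm(nrow(s), 0, 0.3))
  emg <- simulate_emg(s, amp, cfg, seed = 5)
  est1 <- fit_sebr(preprocess_emg(emg), s) |>
    dplyr::mutate(participant = "p") |> normalize_sebr()
  est2 <- fit_sebr(preprocess_emg(ch_update(emg, value = emg$value * 10)), s) |>
    dplyr::mutate(participant = "p") |> normalize_sebr()
  expect_equal(est1$normalized_amplitude, est2$normalized_amplitude,
               tolerance = 1e-8)
})
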