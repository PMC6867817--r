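test_that("SCR preprocessing: DC removed, artifacts masked, rate 10 Hz", {
  const <- channel_recording(rep(5, 60000), 1000, units = "uS", channel = "sc")
  out <- preprocess_scr(const)
  expect_equal(ch_rate(out), 10)
  expect_lt(max(abs(out$value)), 1e-6)
  art <- tibble::tibble(start_s = c(10, 30), end_s = c(11.5, 33), label = "m")
  out2 <- preprocess_scr(const, art)
  expect_false(any(out2$valid[out2$time >= 10 & out2$time < 11.5]))
  long <- attr(out2, "long_artifacts")
  expect_equal(nrow(long), 1)
  expect_equal(long$start_s, 30)
  expect_error(
    preprocess_scr(const, tibble::tibble(start_s = c(1, 2), end_s = c(3, 4))),
    "overlapping"
  )
})

test_that("short artifacts keep the trial; long artifacts inside a trial exclude it", {
  seq2 <- dplyr::bind_rows(one_trial_seq(20), one_trial_seq(40))
  seq2$trial <- 1:2
  seq2 <- fearphys:::new_trial_sequence(seq2, "acquisition", 1)
  attr(seq2, "duration_s") <- 80
  rate <- 1000
  kern <- canonical_kernel("scrf", rate)
  x <- numeric(80 * rate)
  for (on in c(20, 40)) {
    x <- fearphys:::add_wave_at(x, fearphys:::scr_ant_wave(rate, 0.5, kern),
                                on * rate + 1)
  }
  rec <- channel_recording(x + 2, rate, units = "uS", channel = "sc")
  art <- tibble::tibble(start_s = c(21, 41), end_s = c(22.5, 44), label = "m")
  est <- invert_scr(preprocess_scr(rec, art), seq2)
  expect_false(est$excluded[1])  # 1.5 s artifact: interpolated, retained
  expect_true(est$excluded[2])   # 3 s artifact: excluded
  expect_equal(est$reason[2], "long-artifact")
  expect_true(is.na(est$anticipatory_amplitude[2]))
})

test_that("noiseless single-trial inversion recovers amplitude, latency and evoked response", {
  seq1 <- one_trial_seq(20)
  rate <- 1000
  kern <- canonical_kernel("scrf", rate)
  x <- numeric(60 * rate)
  x <- fearphys:::add_wave_at(x, 1 * fearphys:::scr_ant_wave(rate, 0.5, kern),
                              20 * rate + 1)
  x <- fearphys:::add_wave_at(x, 1.5 * kern$y, round(23.5 * rate) + 1)
  rec <- channel_recording(x + 2, rate, units = "uS", channel = "sc")
  est <- invert_scr(preprocess_scr(rec), seq1)
  expect_equal(est$anticipatory_amplitude, 1, tolerance = 0.05)
  expect_equal(est$anticipatory_latency_s, 0.5, tolerance = 0.1)
  expect_equal(est$evoked_amplitude, 1.5, tolerance = 0.1)
})

test_that("overlapping anticipatory + evoked match a brute-force grid oracle", {
  seq1 <- one_trial_seq(20)
  rate <- 1000
  kern <- canonical_kernel("scrf", rate)
  x <- numeric(60 * rate)
  x <- fearphys:::add_wave_at(x, 0.5 * fearphys:::scr_ant_wave(rate, 1.2, kern),
                              20 * rate + 1)
  x <- fearphys:::add_wave_at(x, 1.5 * kern$y, round(23.5 * rate) + 1)
  rec <- channel_recording(x + 2, rate, units = "uS", channel = "sc")
  tr <- preprocess_scr(rec)
  est <- invert_scr(tr, seq1)
  # oracle: exhaustive (latency x the two amplitudes by closed-form LS)
  basis <- fearphys:::scr_design_basis(scr_config())
  n <- nrow(tr)
  ev_col <- fearphys:::add_wave_at(numeric(n), basis$ev,
                                   round(23.5 * 10) + 1 - basis$pre)
  best <- list(rss = Inf)
  for (j in seq_along(basis$latencies)) {
    ant_col <- fearphys:::add_wave_at(numeric(n), basis$ant[[j]],
                                      20 * 10 + 1 - basis$pre)
    X <- cbind(ant_col, ev_col)
    beta <- pmax(0, qr.coef(qr(X), tr$value))
    rss <- sum((tr$value - X %*% beta)^2)
    if (rss < best$rss) best <- list(rss = rss, beta = beta,
                                     lat = basis$latencies[j])
  }
  expect_equal(est$anticipatory_amplitude, unname(best$beta[1]), tolerance = 0.02)
  expect_equal(est$anticipatory_latency_s, best$lat, tolerance = 0.051)
  expect_equal(est$evoked_amplitude, unname(best$beta[2]), tolerance = 0.02)
  expect_equal(unname(best$beta[1]), 0.5, tolerance = 0.05)
  expect_equal(unname(best$beta[2]), 1.5, tolerance = 0.1)
})

test_that("the inversion is blind to reinforcement: evoked modeled on unreinforced trials", {
  seq1 <- one_trial_seq(20, reinforced = FALSE)
  rate <- 1000
  kern <- canonical_kernel("scrf", rate)
  x <- numeric(60 * rate)
  # a response at the would-be US time despite no US flag
  x <- fearphys:::add_wave_at(x, 0.8 * kern$y, round(23.5 * rate) + 1)
  rec <- channel_recording(x + 2, rate, units = "uS", channel = "sc")
  est <- invert_scr(preprocess_scr(rec), seq1)
  expect_equal(est$evoked_amplitude, 0.8, tolerance = 0.1)
})

test_that("masked samples have no influence on the estimates", {
  seq1 <- one_trial_seq(20)
  rate <- 1000
  kern <- canonical_kernel("scrf", rate)
  x <- numeric(60 * rate)
  x <- fearphys:::add_wave_at(x, fearphys:::scr_ant_wave(rate, 0.8, kern),
                              20 * rate + 1)
  rec <- channel_recording(x + 2, rate, units = "uS", channel = "sc")
  art <- tibble::tibble(start_s = 26, end_s = 27.5, label = "m")
  est1 <- invert_scr(preprocess_scr(rec, art), seq1)
  wild <- rec
  idx <- wild$time >= 26.2 & wild$time < 27.2  # strictly inside the mask
  wild$value[idx] <- wild$value[idx] + 50
  est2 <- invert_scr(preprocess_scr(wild, art), seq1)
  expect_equal(est1$anticipatory_amplitude, est2$anticipatory_amplitude,
               tolerance = 1e-6)
  expect_equal(est1$anticipatory_latency_s, est2$anticipatory_latency_s)
})

test_that("latency estimates never leave the 0-2 s bounds", {
  cfg <- sim_config(n_per_group = 1, seed = 3)
  s <- generate_trial_sequence("acquisition", seed = 17)
  amp <- withr::with_seed(2, stats::rlnorm(nrow(s), log(0.4), 0.35))
  sim <- simulate_scr(s, amp, cfg, seed = 4)
  est <- invert_scr(preprocess_scr(sim$recording, sim$artifacts), s)
  ok <- !est$excluded
  expect_true(all(est$anticipatory_latency_s[ok] >= 0))
  expect_true(all(est$anticipatory_latency_s[ok] <= 2))
  expect_true(all(est$anticipatory_amplitude[ok] >= 0))
})

test_that("trial selection keeps nonreinforced non-excluded trials only", {
  est <- tibble::tibble(
    trial = 1:4, cs = c("CS-", "CSr+", "CSn+", "CSr+"),
    reinforced = c(FALSE, TRUE, FALSE, FALSE),
    anticipatory_amplitude = c(1, 2, 3, NA),
    anticipatory_latency_s = 1, evoked_amplitude = 0,
    excluded = c(FALSE, FALSE, FALSE, TRUE), reason = NA_character_
  )
  out <- select_scr_trials(est)
  expect_equal(out$trial, c(1, 3))
  expect_equal(out$amplitude, c(1, 3))
  allr <- dplyr::mutate(est, reinforced = TRUE)
  expect_warning(select_scr_trials(allr), "no analyzable")
})
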