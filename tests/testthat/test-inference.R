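test_that("CS contrast codes are orthogonal and give the stated toy values", {
  tbl <- tibble::tibble(cs = c("CSr+", "CSn+", "CS-"), mean = c(2, 2, 1))
  out <- build_contrasts(tbl)
  expect_equal(sum(out$c_cs * out$mean), 1)  # mean(CS+) - CS-
  expect_equal(sum(out$c_rn * out$mean), 0)
  balanced <- build_contrasts(tibble::tibble(cs = rep(c("CS-", "CSr+", "CSn+"), 10)))
  expect_equal(sum(balanced$c_cs * balanced$c_rn), 0)
  expect_equal(sum(balanced$c_cs), 0)
  expect_equal(sum(balanced$c_rn), 0)
})

test_that("trialwise LME reproduces the retention-model row structure", {
  tbl <- make_trial_table(8, b_cs = 0.5, b_int = 0.4, seed = 2)
  m <- suppressMessages(fit_lme(tbl, time = "across_cs"))
  eff <- tidy(m)
  expect_setequal(
    eff$effect,
    c("Drug", "CS+ vs CS-", "Drug × (CS+ vs CS-)", "Trial", "Drug × trial",
      "Trial × (CS+ vs CS-)", "Drug × trial × (CS+ vs CS-)",
      "CSr+ vs CSn+", "Drug × (CSr+ vs CSn+)",
      "Drug × trial × (CSr+ vs CSn+)")
  )
  expect_true(all(eff$F >= 0, na.rm = TRUE))
  expect_true(all(eff$p > 0 & eff$p <= 1, na.rm = TRUE))
  expect_equal(eff$df_num[eff$effect == "Trial"], 44)
  # the CSr+/CSn+ contrast uses only CS+ trials: smaller denominator df
  expect_lt(eff$df_den[eff$effect == "CSr+ vs CSn+"],
            eff$df_den[eff$effect == "CS+ vs CS-"])
  g <- glance(m)
  expect_equal(g$n_participants, 16)
})

test_that("a simulated drug x CS effect is detected; unbalanced data are tolerated", {
  tbl <- make_trial_table(10, b_cs = 0.5, b_int = 0.5, seed = 5)
  # drop a scattering of trials (exclusions)
  tbl_miss <- withr::with_seed(1, dplyr::slice_sample(tbl, prop = 0.9))
  m <- fit_lme(tbl_miss, time = "none")
  eff <- tidy(m)
  expect_lt(eff$p[eff$effect == "Drug × (CS+ vs CS-)"], 0.01)
  expect_gt(eff$F[eff$effect == "CS+ vs CS-"], 10)
})

test_that("within-CS time coding counts trials inside each CS", {
  tbl <- make_trial_table(4, seed = 7, phase = "relearning")
  m <- suppressMessages(fit_lme(tbl, time = "within_cs"))
  eff <- tidy(m)
  # 30 trials per CS in relearning: 29 numerator df for the trial factor
  expect_equal(eff$df_num[eff$effect == "Trial"], 29)
})

test_that("covariates enter as main effect and CS interaction", {
  tbl <- make_trial_table(6, b_cs = 0.4, seed = 9)
  covs <- withr::with_seed(3, tibble::tibble(
    participant = unique(tbl$participant),
    acq_psr = stats::rnorm(12)
  ))
  tbl <- dplyr::left_join(tbl, covs, by = "participant")
  m <- fit_lme(tbl, time = "none", covariates = "acq_psr")
  expect_true(all(c("acq_psr", "acq_psr × (CS+ vs CS-)") %in% tidy(m)$effect))
})

test_that("rm-ANOVA: two-condition one-group F equals the squared paired t", {
  withr::with_seed(3, {
    d <- tibble::tibble(
      participant = rep(sprintf("p%d", 1:10), 2), group = "placebo",
      cs = rep(c("CS-", "CSr+"), each = 10),
      amplitude = stats::rnorm(20, rep(c(1, 1.5), each = 10))
    )
  })
  a <- fit_rm_anova(d)
  w <- tidyr::pivot_wider(d, names_from = cs, values_from = amplitude)
  tt <- stats::t.test(w$`CSr+`, w$`CS-`, paired = TRUE)
  expect_equal(tidy(a)$F[1], unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(tidy(a)$p[1], tt$p.value, tolerance = 1e-8)
})

test_that("three-condition rm-ANOVA has the conditionwise row structure", {
  withr::with_seed(8, {
    d <- tidyr::expand_grid(participant = sprintf("p%d", 1:12),
                            cs = c("CS-", "CSr+", "CSn+")) |>
      dplyr::mutate(group = rep(c("placebo", "drug"), each = 18),
                    amplitude = stats::rnorm(36) + 2 * (cs != "CS-"))
  })
  a <- fit_rm_anova(d)
  eff <- tidy(a)
  expect_setequal(eff$effect, c("Drug", "CS+ vs CS-", "CSr+ vs CSn+",
                                "Drug × (CS+ vs CS-)", "Drug × (CSr+ vs CSn+)"))
  expect_lt(eff$p[eff$effect == "CS+ vs CS-"], 0.01)
  # pooled within error: both CS contrasts share the denominator df
  expect_equal(eff$df_den[eff$effect == "CS+ vs CS-"],
               eff$df_den[eff$effect == "CSr+ vs CSn+"])
})

test_that("LME on balanced two-condition data agrees with the rm-ANOVA F", {
  # degenerate equivalence: balanced complete data, random intercept only
  withr::with_seed(12, {
    d <- tidyr::expand_grid(participant = sprintf("p%d", 1:14),
                            cs = c("CS-", "CSr+")) |>
      dplyr::mutate(group = rep(c("placebo", "drug"), each = 14),
                    trial = 1L,
                    amplitude = stats::rnorm(28) + 0.8 * (cs != "CS-") +
                      0.5 * (cs != "CS-") * (group == "drug") +
                      rep(stats::rnorm(14, 0, 0.4), each = 2))
  })
  m <- fit_lme(d, time = "none")
  a <- fit_rm_anova(d)
  eff_m <- tidy(m)
  eff_a <- tidy(a)
  f_lme <- eff_m$F[eff_m$effect == "Drug × (CS+ vs CS-)"]
  f_aov <- unname(eff_a$F[eff_a$effect == "Drug × (CSr+ vs CS-)"])
  expect_equal(unname(f_lme), f_aov, tolerance = 0.01)
})

test_that("group t test: identical groups, textbook case, paired variant", {
  same <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # hand-computed pooled t on 3+3 values
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  sp <- sqrt((2 * stats::var(x) + 2 * stats::var(y)) / 4)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(2 / 3))
  out <- compare_groups(c(x, y), rep(c("a", "b"), each = 3))
  expect_equal(out$t, t_hand)
  expect_equal(out$df, 4)
  pared <- compare_groups(c(1, 2, 3), c(2, 4, 6), paired = TRUE)
  expect_equal(pared$estimate, -2)
})

test_that("clearance arithmetic follows first-order elimination", {
  expect_equal(clearance_fraction(16, 0), 0)
  expect_equal(clearance_fraction(16, 16), 0.5)
  expect_equal(clearance_fraction(16, 32), 0.75)
  expect_gt(clearance_fraction(16, 168), 0.999)
  expect_error(clearance_fraction(-1, 10))
})
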