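# fearphys

Psychophysiological quantification and statistical inference for human
discriminative threat-conditioning (fear-conditioning) experiments, built
tidyverse-style: every stage takes a data frame (or a channel recording) and
returns a tibble, so full analyses chain with the pipe.

## The problem the package addresses

In a threat-conditioning study, participants learn that some visual cues
(CS+) predict an aversive electrical stimulus (US) on half of their
presentations while another cue (CS−) never does. Memory is then read out
physiologically: fear-potentiated startle (larger eye-blink EMG responses to
loud probes during a threat cue), anticipatory skin conductance and
pupil-size responses, and conditioned bradycardia (heart-period lengthening).
A drug/placebo group contrast — e.g. a reconsolidation-interference
manipulation administered before a memory reminder — is then tested on the
trialwise response amplitudes.

`fearphys` implements the full chain for such designs:

1. **Design** — constrained randomization of trial sequences
   (`generate_trial_sequence()`, `validate_sequence()`, `assign_timing()`):
   45-trial acquisition/retention phases (15 per CS), 90-trial relearning,
   50% reinforcement, ITIs of 7/9/11 s, a US coterminating with the 4 s CS,
   startle probes 3.5 s after CS onset in retention.
2. **Synthetic cohorts** — a forward simulator (`simulate_cohort()`) that
   generates raw EMG, skin conductance, pupil + gaze, and ECG with known
   ground-truth per-trial amplitudes, so every stage is verifiable by
   parameter recovery.
3. **Quantification** — each measure is modeled as amplitude × a canonical
   response kernel, so estimation is (latency-shifted) regression:
   * SEBR: band-pass 50–470 Hz, mains notches, rectify, smooth at 53.05 Hz,
     then variable-onset kernel regression per probe and CS− normalization.
   * SCR: artifact interpolation/exclusion, 0.0159–5 Hz band-pass, 10 Hz,
     and joint non-negative inversion of anticipatory (free latency 0–2 s)
     plus evoked (at the potential US time of *every* trial) responses.
   * PSR: blink/gaze cleaning, strict <50%-in-10-s trial exclusion, and a
     single-trial convolution GLM at 250 Hz.
   * HPR: Pan–Tompkins-type R-spike detection, 400–1200 ms IBI gating,
     10 Hz interpolation, 0.015–0.5 Hz filtering, conditionwise convolution
     GLM.
4. **Inference** — trial-level mixed models
   `response ~ drug * CS * time + (1 | participant)` with Satterthwaite df
   and orthogonal CS contrasts (`fit_lme()`), pooled-error repeated-measures
   ANOVA (`fit_rm_anova()`), group t tests, and the drug-clearance utility
   `clearance_fraction()` (first-order elimination, `1 − 2^(−t/t½)`).
5. **Cross-validated permutation test** (`cv_statistic()`,
   `permutation_test()`) — predicts each participant's CS+/CS− difference
   from the drug label in threefold cross-validation over 10 random
   partitionings; the statistic is the residual variance proportion
   `Σerror²/n/var`, and the p value is the rate at which 1000 label
   permutations beat the observed prediction.

Fitted objects have broom-style `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` ggplot2 graphics. Session data travel as text
"bundles" (`write_bundle()`/`read_bundle()`) with BIDS-style events files;
group labels stay blinded behind codes until the explicit unblinding join.

## Worked example

Simulate a small cohort (3 participants per group), quantify every channel,
fit the retention startle model and run the cross-validated permutation
test:

```r
library(fearphys)

cfg <- sim_config(n_per_group = 3, seed = 101)
res <- run_pipeline(cfg, phases = c("acquisition", "retention"))

tidy(res$effects$retention_sebr)[1:4, ]
#> # A tibble: 4 × 5
#>   effect                    F df_num df_den        p
#>   <chr>                 <dbl>  <dbl>  <dbl>    <dbl>
#> 1 Drug                 0.0582      1   4.04 8.21e- 1
#> 2 CS+ vs CS-          79.5         1 116.   8.06e-15
#> 3 Drug × (CS+ vs CS-)  1.57        1 117.   2.13e- 1
#> 4 Trial                4.86       44 116.   4.80e-12

res$cv
#> <cv_perm> residual variance proportion 1.417, p = 0.198 (1000 permutations)
```

Reading the output: the startle discrimination between threat and safe cues
is unmistakable (CS+ vs CS−), responses habituate across the 45 extinction
trials (Trial), and at this toy sample size the simulated drug modulation of
the CS+ effect (a 1.5× multiplier in the generator) is not detectable —
neither in the mixed model (drug × CS) nor in the cross-validated prediction
of each participant's CS+/CS− difference from the drug label (a residual
variance proportion below 1 would mean better-than-chance prediction). At a
study-scale sample size the same effect is detected reliably: the package's
acceptance run (below) finds drug × CS F ≈ 25, p < 10⁻⁶ and a permutation
p of 0.001 with 10 participants per group.

Ground truth is returned alongside (`res$truth`), so recovery can be checked
directly:

```r
library(dplyr)
inner_join(res$estimates$sebr,
           filter(res$truth, measure == "sebr"),
           by = c("participant", "phase", "trial")) |>
  summarise(r = cor(amplitude.x, amplitude.y))
#> # A tibble: 1 × 1
#>       r
#>   <dbl>
#> 1 1.000
```

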