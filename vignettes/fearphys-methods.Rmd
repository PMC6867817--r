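---
title: "Models and methods behind fearphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fearphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fearphys` implements the quantification and inference chain of a
discriminative threat-conditioning (fear-conditioning) experiment with a
pharmacological between-group manipulation: from raw multichannel
physiological recordings to trialwise response amplitudes, mixed-model
contrasts, and a cross-validated permutation test of the drug × CS effect.
This vignette explains the models the package fits, the choices made where
the design was genuinely open, and what the synthetic-data generator does and
does not emulate.

## The experimental design

Three visual conditioned stimuli are presented for 4 s each: a CS− that is
never reinforced, and two CS+ (CSr+, the cue later reminded, and CSn+, the
non-reminded cue), each reinforced on half of its trials by a 500 ms
electrical stimulation (US) that coterminates with the CS, so the US starts
3.5 s after CS onset. Intertrial intervals are drawn from {7, 9, 11} s.
Acquisition and retention sessions have 45 trials (15 per CS); relearning has
90 (30 per CS). During retention no US is delivered and a startle probe
sounds 3.5 s after every CS onset.

`generate_trial_sequence()` draws trial orders under the design's
randomization constraints: the first trial of a reinforced phase is a
reinforced CS+, the first six trials contain each CS exactly twice, at most
five identical CS in a row, and — counted over the CS+ subsequence — at most
four consecutive reinforcements or omissions. Sampling is by rejection with a
large attempt cap. We considered a constraint-guided repair stage and decided
against it: empirically, rejection accepts within a few dozen draws for
every phase, so a repair path would be dead code that complicates the
determinism contract. `validate_sequence()` re-derives every rule from the
sequence content and is used as the independent oracle in the test suite.

One wrinkle: with 15 trials per CS+ an exact 50% reinforcement rate is not
realizable. The generator reinforces `ceiling(n/2)` (8 of 15) trials of each
CS+ so that both CS+ keep identical global reinforcement rates, and exact
50% wherever the per-CS count is even (as in relearning, 15 of 30).

## Canonical response kernels

All four measures are quantified under the same principle: a response is
amplitude × a fixed-shape kernel, so estimation reduces to (possibly
latency-shifted) regression. The kernel families are:

* **SEBR** (startle eye-blink EMG envelope): gamma density, mode 40 ms,
  support ≈ 200 ms.
* **SCRF** (skin conductance): bi-exponential, rise 0.75 s, decay 3 s.
* **PSRF** (pupil): gamma density peaking at 2 s.
* **HPRF** (heart period): difference of gammas spanning ≈ 10 s, positive
  peak at 4 s with a late negative lobe.

All kernels are peak-normalized so fitted coefficients are amplitudes in
channel units. The exact functional forms in the literature are defined
inside a proprietary toolbox; we therefore claim *family-level* rather than
function-exact equivalence, and validate the pipelines by forward-simulation
recovery, not by kernel identity. Every kernel parameter is exposed, and the
simulator can deliberately mis-specify its kernels (shifted peak, different
dispersion) so that recovery tests do not merely confirm a tautology.

## Startle eye-blink quantification (SEBR)

The EMG chain is: fourth-order Butterworth band-pass 50–470 Hz (zero-phase,
bidirectional), biquad notch filters at the 50 Hz mains harmonics below the
upper band edge (Q = 35), rectification, and a fourth-order 53.05 Hz low-pass
(the 3 ms time-constant equivalent). `fit_sebr_trial()` then regresses the
envelope onto the startle kernel over a 1 ms onset grid spanning 0–150 ms
after the measured probe onset; the non-negative least-squares amplitude at
the residual-minimizing onset is the trial estimate, with ties broken by the
earliest onset. Amplitudes are constrained non-negative because a blink has
no sign in envelope units.

Because electrode impedance and muscle anatomy scale the measured EMG
multiplicatively, `normalize_sebr()` divides each participant's single-trial
estimates by that participant's CS− mean; the CS− mean of the output is 1 by
construction, and the whole chain is exactly equivariant to a channel gain.
Normalization is applied per participant × session; pooling across sessions
is possible via the `by` argument but not the default, since gain changes
with electrode placement between visits.

## Skin conductance model inversion (SCR)

Preprocessing follows the stated chain: artifact periods shorter than 2 s
are linearly interpolated for filtering and masked for inversion; longer
artifact periods exclude any trial they touch. The trace is filtered with a
first-order bidirectional Butterworth band-pass (0.0159–5 Hz) and decimated
to 10 Hz with the mask propagated (a decimated sample is valid only if its
entire source block is).

The response model per trial is (a) an anticipatory response: a Gaussian
input of fixed dispersion (SD 0.3 s) whose centre — the free latency — lies
0–2 s after CS onset, convolved with the SCRF; and (b) an evoked response of
fixed latency at the *potential* US onset of **every** trial, so the
inversion is blind to reinforcement. Overlapping responses of neighbouring
trials add in the forward model.

Two numerical points matter here. First, because amplitudes enter linearly
given the latencies, we solve the inversion by *profiling*: joint
non-negative least squares over all trial amplitudes (via the normal
equations and a Cholesky square root), alternated with per-trial latency
sweeps over a 0.05 s grid. This is strictly deterministic and needs no
multi-start heuristics; the test suite checks it against exhaustive
grid-search oracles. Second, the design columns must be *filter-matched*: a
zero-phase high-pass with a ~10 s time constant both distorts the kernel
(undershoot tails tens of seconds long) and makes it acausal (response mass
before the input). Basis waveforms are therefore built at the raw rate,
passed through the identical filter, decimated the same way, and kept from
10 s before to 70 s after the event. With this, noiseless simulate → invert
recovers single-trial parameters essentially exactly; in dense 45-trial
sessions small-amplitude trials can absorb a few percent of residual
cross-talk from the latency grid, which is well inside the tolerance of the
statistical layer. Only nonreinforced trials enter analysis, to avoid US
contamination of the anticipatory estimate.

The tonic level is removed before filtering (the band-pass would otherwise
turn the DC step at the recording edge into a long transient), and all
filtering uses odd-reflection padding at the edges.

## Pupil-size responses (PSR)

Blink and saccade annotation intervals, gaze samples outside a ±5° box
around screen centre (at 70 cm viewing distance), and zero-area samples are
masked; missing runs are linearly interpolated for filtering and ignored in
the fit. The eye with fewer missing samples is analyzed (ties go to the left
eye, a documented arbitrary rule). A trial is excluded if *strictly less*
than 50% of samples are available in the 10 s after CS onset — a trial at
exactly 50% is included. Sessions with more than 35% excluded trials trigger
a warning; in the source study this level was a property of the data, not an
exclusion rule, so we implement it as a diagnostic only.

Amplitudes come from a single-trial convolution GLM at 250 Hz: one impulse
regressor per included trial convolved with the pupil kernel, plus an
intercept and a linear drift term per session, fitted by ordinary least
squares on valid samples. Drift regressors are kept deliberately minimal and
configurable. When tracker annotations are absent the package falls back to
a 30°/s gaze-velocity rule, documented as an approximation of an online
parser. Pupil units are tracker-arbitrary throughout; no unit conversion is
attempted.

## Heart-period responses (HPR)

R spikes are detected with a Pan–Tompkins-type chain: 5–15 Hz band-pass,
differentiation, squaring, 150 ms moving-window integration, adaptive dual
thresholds, and a 200 ms refractory rule. Two deliberate variations: peak
candidates must dominate their ±150 ms neighbourhood (suppressing noise
bumps that would otherwise claim the refractory window ahead of the true
R wave), and the final spike time is refined on the raw signal, whose R peak
is sharp, rather than on the band-passed waveform, whose side lobes can
outgrow the main lobe under noise.

Each interbeat interval is mapped onto the time of its following R spike;
values outside 400–1200 ms are dropped (boundary values are kept as valid —
the natural reading of excluding values "outside" the range — with an
exclusive-bounds switch available). The series is linearly interpolated to
10 Hz and band-pass filtered (0.015–0.5 Hz, fourth order, bidirectional,
with the same demeaning and edge padding as the SCR chain). A conditionwise
convolution GLM with filter-matched regressors yields one amplitude per CS
type per session, in ms of heart-period lengthening (positive =
bradycardia). Because the three condition regressors overlap heavily and
their sum is nearly collinear with the intercept, the common level of the
three amplitudes is weakly identified while condition *differences* are well
identified; tests therefore assert differences, which is also what the
ANOVA consumes.

## Statistical layer

Trialwise estimates (SEBR, PSR, SCR) are analyzed in linear mixed-effects
models, `response ~ drug * CS * time + (1 | participant)`, with sum-to-zero
coding, Type III F tests and Satterthwaite denominator degrees of freedom
(`lmerTest`), falling back to residual df if the approximation fails. Time
is a categorical factor: trial number across CS in retention, and the
within-CS trial counter in relearning. The CS factor enters as two
orthogonal contrasts — mean(CS+) vs CS−, and CSr+ vs CSn+ — with the latter
estimated on CS+ trials only, which is why its denominator df are smaller.
Richer random-effects structures are out of contract (they were inestimable
in data of this shape). Unbalanced tables from trial exclusions are
unproblematic for this model. Covariates (e.g. an acquisition learning
index) can be added as main effects plus CS interactions.

Conditionwise heart period goes into a standard repeated-measures ANOVA with
a participant error stratum; the two CS contrasts are tested against the
pooled within-participant error. With two conditions and one group this
reduces exactly to the squared paired t statistic, which the tests exploit
as a closed-form oracle. Control measures use independent-samples pooled
t tests without multiplicity correction. The clearance utility implements
first-order elimination, 1 − 2^(−t/t½): with a 16 h half-life, more than
99.9% of a dose is gone a week later.

## Cross-validated permutation test

The drug × CS effect is probed predictively: each participant's CS+/CS−
difference is predicted from the drug label in threefold cross-validation
(the linear model on a binary label reduces to training-fold group means,
but is implemented as general least squares so covariates can be added).
The statistic is the *residual variance proportion* — summed squared
prediction error divided by the number of data points and by the variance of
the differences — averaged over the 3 folds and 10 random partitionings.
Labels are then permuted 1000 times with the partitionings held fixed
(controlling partitioning noise; recomputing partitionings per permutation
is available as an alternative), and the p value is the rate at which
permuted statistics fall *strictly below* the observed one, exactly the
literal counting rule; an add-one corrected variant is off by default. With
group sizes not divisible by three, folds differ by at most one and
partitionings are redrawn (bounded retries) until every training set
contains both labels.

## The synthetic cohort

`simulate_cohort()` forward-simulates raw channels with known per-trial
amplitudes so every downstream stage is testable by parameter recovery. The
generator encodes the structure the analysis assumes: CS+ amplitudes a
factor 2 above CS−; a drug-group multiplier of 1.5 on the retention CS+
surplus (and its inverse on relearning); exponential habituation (rate
0.02/trial) and extinction of the CS+ surplus (0.05/trial); lognormal
trial-to-trial variability (SD 0.35) and a lognormal participant gain
(SD 0.4) applied multiplicatively to the startle channel — the stated
rationale for CS− normalization. Blink gaps (4/min, 0.1–0.5 s), gaze
excursions beyond the box, step artifacts in skin conductance (durations
0.5–4 s, straddling the 2 s interpolation threshold), optional 50 Hz mains
on the EMG, and an integrate-and-fire ECG with a synthetic QRS-T template
complete the picture. Channel noise defaults put the startle channel near
single-trial SNR 5; the defaults are chosen so recovery is comfortable at
1× noise and visibly degrades at 10×, and recovery correlation is
monotonically non-increasing in noise by test.

What the generator does **not** emulate: biophysical sudomotor or pupil
muscle dynamics (responses are amplitudes on kernels by construction),
luminance effects, movement-locked artifacts correlated with stimuli,
non-stationary heart-rate variability beyond a fixed respiratory sinusoid,
or kernel shapes differing from the fitters' unless explicitly
mis-specified. Passing recovery tests therefore demonstrates correctness of
the estimation chain, not fidelity of any kernel to human physiology.

## Problem sizes and calibration used by the test suite

The suite validates sequence generation on 1000 sequences per phase;
forward–inverse identity on zero-noise parameter grids (amplitudes within
5%, SCR latency within 0.1 s, HPR condition difference within 10%);
recovery on a 20-participant cohort at default noise (r ≥ 0.9 for SEBR and
PSR, ≥ 0.8 for SCR anticipatory amplitude, HPR effect sign in ≥ 95% of
participants); uniformity of null mixed-model p values (200 replicates,
Kolmogorov–Smirnov); permutation-test type-I error at α = 0.05 within its
binomial 95% CI (200 replicates × 200 permutations); and a power curve at
n = 24 with 400 permutations that rises strictly in effect size, with the
top effect size tied to the two-sample effect that reaches 80% power at the
full design size of n = 74. These sizes were chosen as the smallest that
make the stochastic checks stable under their fixed seeds.

## Known limitations

* Kernel shapes are family-level stand-ins for the cited canonical
  functions; amplitudes are comparable within a kernel choice, not across
  toolboxes.
* The SCR inversion is windowed profiling, not a variational scheme; its
  contract is forward-model consistency, which is what the tests enforce.
* The conditionwise HPR level (as opposed to condition differences) is
  weakly identified by design.
* The printed denominator df of the source tables for the pooled-error
  ANOVA cannot all be reproduced by a single error layout; the package
  implements the standard pooled-error analysis and does not chase the
  printed values.
* No Bayesian re-analysis, equivalence testing, or multiplicity correction
  (deliberately, matching the analysis plan the package implements).
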