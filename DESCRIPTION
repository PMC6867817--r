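Package: fearphys
Title: Psychophysiological Quantification and Inference for Human Threat Conditioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discriminative threat-conditioning
    (fear conditioning) experiments with fear-potentiated startle. Generates and
    validates constrained conditioning trial sequences; forward-simulates
    multichannel physiological recordings (orbicularis oculi EMG, skin
    conductance, pupil area with gaze, ECG) with known ground-truth per-trial
    response amplitudes; quantifies trialwise startle eye-blink responses (SEBR)
    by variable-onset canonical-response regression, anticipatory and evoked
    skin conductance responses (SCR) by model inversion under a canonical
    response function, anticipatory pupil-size responses (PSR) by single-trial
    convolution GLM, and heart-period responses (HPR) by Pan-Tompkins R-spike
    detection and conditionwise convolution GLM; and fits the study-level
    statistics: trialwise linear mixed-effects models with orthogonal CS
    contrasts, conditionwise repeated-measures ANOVA, group t tests, and a
    threefold cross-validated permutation test of the drug-by-CS effect based
    on the residual variance proportion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
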