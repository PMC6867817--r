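#' Fit all measures of one session bundle
#'
#' Dispatches on the channels present: EMG is preprocessed and fitted
#' trialwise with CS- normalization applied later at the cohort level; skin
#' conductance is preprocessed with its artifact annotations and inverted;
#' the better eye's pupil trace is cleaned and fitted by convolution GLM
#' (reinforced trials flagged for removal from analysis); the ECG is turned
#' into a heart-period trace and fitted conditionwise.
#'
#' @param bundle A session bundle (see [read_bundle()]).
#' @param configs Optional list of pipeline configs (`emg`, `scr`, `pupil`,
#'   `hpr`).
#' @return Named list of per-measure estimate tibbles (subset of `sebr`,
#'   `scr`, `psr`, `hpr`), each tagged with participant and phase.
#' @export
fit_bundle <- function(bundle, configs = list()) {
  seq <- new_trial_sequence(bundle$events, bundle$manifest$phase, NA)
  attr(seq, "duration_s") <- bundle$manifest$duration_s %||%
    (max(seq$cs_onset_s) + seq$cs_duration_s[1] + max(seq$iti_s))
  ch <- bundle$channels
  ann <- bundle$annotations
  tag <- function(d) dplyr::mutate(d,
                                   participant = bundle$manifest$participant,
                                   phase = bundle$manifest$phase,
                                   group_code = bundle$manifest$group_code)
  out <- list()
  if ("emg" %in% names(ch)) {
    env <- preprocess_emg(ch$emg, configs$emg %||% emg_config())
    out$sebr <- tag(fit_sebr(env, seq, configs$emg %||% emg_config()))
  }
  if ("sc" %in% names(ch)) {
    art <- ann[ann$channel == "sc", c("start_s", "end_s", "label")]
    trace <- preprocess_scr(ch$sc, art, configs$scr %||% scr_config())
    out$scr <- tag(select_scr_trials(invert_scr(trace, seq,
                                                configs$scr %||% scr_config())))
  }
  if (all(c("pupil_left", "pupil_right") %in% names(ch))) {
    cfg <- configs$pupil %||% pupil_config()
    cl <- function(side) {
      iv <- ann[ann$channel == paste0("pupil_", side), c("start_s", "end_s")]
      clean_pupil(ch[[paste0("pupil_", side)]], iv, cfg)
    }
    eye <- select_eye(cl("left"), cl("right"))
    out$psr <- tag(fit_pupil_glm(eye, seq, cfg))
  }
  if ("ecg" %in% names(ch)) {
    cfg <- configs$hpr %||% hpr_config()
    spikes <- detect_r_spikes(ch$ecg, cfg)
    hp <- build_hp_trace(spikes, duration_s = attr(seq, "duration_s"),
                         config = cfg)
    out$hpr <- tag(fit_hpr_glm(hp, seq, cfg))
  }
  out
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the study's analysis order: simulate the cohort, quantify
#' every channel of every session bundle, unblind the group codes, and fit
#' the phase-appropriate statistics — the retention startle LME (trial number
#' across CS), acquisition/relearning LMEs for SCR and PSR (nonreinforced
#' trials only; within-CS trial counter in relearning), the conditionwise
#' heart-period repeated-measures ANOVA, and the cross-validated permutation
#' test of the drug x CS effect on the retention startle difference. Every
#' stochastic stage consumes a seed derived from the config, so a config
#' fully determines the outputs; the run log records the config hash.
#'
#' @param config A [sim_config()]; its seed drives the whole run.
#' @param phases Phases to simulate and analyze.
#' @param cv A [cv_config()]; defaults to the study scheme (3 folds, 10
#'   partitionings, 1000 permutations) seeded from `config`.
#' @param configs Optional pipeline config overrides as in [fit_bundle()].
#' @return A `fear_pipeline` list: `estimates` (per-measure trial tables with
#'   unblinded group), `effects` (named list of effect tables), `cv` (a
#'   `cv_perm`), `truth`, `log`.
#' @export
run_pipeline <- function(config, phases = c("acquisition", "retention"),
                         cv = NULL, configs = list()) {
  t0 <- Sys.time()
  sim <- simulate_cohort(config, phases = phases)
  fits <- purrr::map(sim$bundles, fit_bundle, configs = configs)
  measures <- unique(unlist(purrr::map(fits, names)))
  estimates <- purrr::map(
    stats::setNames(measures, measures),
    function(m) {
      dplyr::bind_rows(purrr::compact(purrr::map(fits, m))) |>
        dplyr::left_join(sim$code_map, by = c(group_code = "code"))
    }
  )
  effects <- list()
  if ("sebr" %in% measures) {
    seb <- estimates$sebr |>
      dplyr::filter(.data$phase == "retention") |>
      normalize_sebr(by = "participant")
    estimates$sebr <- seb
    effects$retention_sebr <- fit_lme(
      dplyr::mutate(seb, amplitude = .data$normalized_amplitude),
      time = "across_cs"
    )
  }
  for (ph in intersect(phases, c("acquisition", "relearning"))) {
    tm <- if (ph == "relearning") "within_cs" else "none"
    for (m in intersect(c("scr", "psr"), measures)) {
      d <- estimates[[m]] |>
        dplyr::filter(.data$phase == ph, !.data$reinforced,
                      is.finite(.data$amplitude))
      if (nrow(d)) effects[[paste(ph, m, sep = "_")]] <- fit_lme(d, time = tm)
    }
    if ("hpr" %in% measures) {
      d <- estimates$hpr |> dplyr::filter(.data$phase == ph)
      if (nrow(d)) effects[[paste(ph, "hpr", sep = "_")]] <- fit_rm_anova(d)
    }
  }
  cv_res <- NULL
  if ("sebr" %in% measures) {
    diffs <- estimates$sebr |>
      dplyr::group_by(.data$participant, .data$group) |>
      dplyr::summarise(
        diff = mean(.data$normalized_amplitude[.data$cs != "CS-"]) -
          mean(.data$normalized_amplitude[.data$cs == "CS-"]),
        .groups = "drop"
      )
    cv <- cv %||% cv_config(seed = config$seed + 7L)
    cv_res <- permutation_test(diffs, config = cv)
  }
  log <- list(config_hash = rlang::hash(config), seed = config$seed,
              started = format(t0), elapsed_s = as.numeric(Sys.time() - t0),
              r_version = R.version.string,
              package_version = as.character(utils::packageVersion("fearphys")))
  structure(list(estimates = estimates, effects = effects, cv = cv_res,
                 truth = sim$truth, log = log),
            class = "fear_pipeline")
}

#' @export
print.fear_pipeline <- function(x, ...) {
  cat(sprintf("<fear_pipeline> measures: %s; effect tables: %s\n",
              paste(names(x$estimates), collapse = ", "),
              paste(names(x$effects), collapse = ", ")))
  if (!is.null(x$cv)) print(x$cv)
  invisible(x)
}

#' Condition-mean plot of per-trial amplitude estimates
#'
#' @param estimates Tibble with `trial`, `cs` and an amplitude column.
#' @param amplitude Amplitude column name.
#' @return A ggplot of per-trial condition means.
#' @export
plot_trial_amplitudes <- function(estimates, amplitude = "amplitude") {
  est <- dplyr::filter(estimates, is.finite(.data[[amplitude]]))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$trial,
                                    y = .data[[amplitude]],
                                    colour = .data$cs)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 1) +
    ggplot2::labs(x = "trial", y = amplitude, colour = "CS") +
    ggplot2::theme_minimal()
}
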