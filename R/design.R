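#' @importFrom rlang .data
NULL

CS_LEVELS <- c("CS-", "CSr+", "CSn+")
CS_PLUS <- c("CSr+", "CSn+")

phase_layout <- function(phase) {
  switch(phase,
    acquisition = list(per_cs = 15, reinforced = TRUE, probes = FALSE),
    reminder    = list(per_cs = NA, reinforced = FALSE, probes = FALSE),
    retention   = list(per_cs = 15, reinforced = FALSE, probes = TRUE),
    relearning  = list(per_cs = 30, reinforced = TRUE, probes = FALSE),
    stop(sprintf("invalid phase '%s'", phase), call. = FALSE)
  )
}

#' Generate a conditioning trial sequence
#'
#' Draws a randomly balanced trial order for one session phase under the
#' design's randomization constraints: for reinforced phases the first trial
#' is a reinforced CS+, the first six trials contain each CS exactly twice,
#' no more than `max_run_cs` identical CS in a row, and — counted over the
#' CS+ subsequence — no more than `max_run_us` reinforced trials or US
#' omissions in a row. Each CS+ type is reinforced on exactly 50% of its
#' trials; the CS- is never reinforced. The retention phase has no
#' reinforcement and carries a startle probe 3.5 s after every CS onset.
#'
#' Sequences are drawn by rejection sampling; after `max_attempts` draws
#' without a constraint-satisfying sequence an error is raised.
#'
#' @param phase One of `"acquisition"` (45 trials, 15 per CS, 50%
#'   reinforcement), `"retention"` (45 trials, unreinforced, probed),
#'   `"relearning"` (90 trials, 30 per CS, 50% reinforcement) or
#'   `"reminder"` (a single unreinforced CSr+ trial, not randomized).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param timing If `TRUE` (default) also draw intertrial intervals and derive
#'   onset times via [assign_timing()].
#' @param first_six_rule Apply the first-six-balance rule (all multi-trial
#'   phases by default).
#' @param max_run_cs,max_run_us Run-length caps (defaults 5 and 4).
#' @param max_attempts Rejection-sampling cap.
#'
#' @return A `trial_sequence`: tibble with one row per trial and columns
#'   `trial`, `cs`, `reinforced` (plus timing columns when `timing = TRUE`),
#'   with the phase and seed stored as attributes.
#' @examples
#' seq <- generate_trial_sequence("acquisition", seed = 1)
#' table(seq$cs)
#' validate_sequence(seq)
#' @export
generate_trial_sequence <- function(phase = c("acquisition", "retention",
                                              "relearning", "reminder"),
                                    seed,
                                    timing = TRUE,
                                    first_six_rule = TRUE,
                                    max_run_cs = 5,
                                    max_run_us = 4,
                                    max_attempts = 1e5) {
  phase <- match.arg(phase)
  stopifnot(is.numeric(seed), length(seed) == 1)
  lay <- phase_layout(phase)

  if (phase == "reminder") {
    seq <- tibble::tibble(trial = 1L, cs = "CSr+", reinforced = FALSE)
    seq <- new_trial_sequence(seq, phase, seed)
    if (timing) seq <- assign_timing(seq, seed = seed)
    return(seq)
  }

  seq <- withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    draw_sequence(lay, phase, first_six_rule, max_run_cs, max_run_us,
                  max_attempts)
  })
  seq <- new_trial_sequence(seq, phase, seed)
  if (timing) seq <- assign_timing(seq, seed = seed)
  seq
}

new_trial_sequence <- function(df, phase, seed) {
  attr(df, "phase") <- phase
  attr(df, "seed") <- seed
  class(df) <- c("trial_sequence", class(tibble::tibble()))
  df
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> phase %s, %d trials, %d reinforced (seed %s)\n",
              seq_phase(x), nrow(x), sum(x$reinforced),
              format(attr(x, "seed"))))
  NextMethod()
}

#' @rdname generate_trial_sequence
#' @param seq A `trial_sequence`.
#' @export
seq_phase <- function(seq) attr(seq, "phase")

draw_sequence <- function(lay, phase, first_six_rule, max_run_cs, max_run_us,
                          max_attempts) {
  counts <- stats::setNames(rep(lay$per_cs, 3), CS_LEVELS)
  n <- sum(counts)
  for (attempt in seq_len(max_attempts)) {
    cs <- draw_cs_order(counts, lay$reinforced, first_six_rule)
    if (max_run(cs) > max_run_cs) next
    if (first_six_rule && !first_six_balanced(cs)) next
    if (lay$reinforced) {
      reinforced <- draw_reinforcement(cs)
      if (is.null(reinforced)) next
      runs <- max_run(reinforced[cs %in% CS_PLUS])
      if (runs > max_run_us) next
    } else {
      reinforced <- rep(FALSE, n)
    }
    return(tibble::tibble(trial = seq_len(n), cs = cs, reinforced = reinforced))
  }
  stop("unsatisfiable constraints: no valid sequence after ",
       max_attempts, " attempts", call. = FALSE)
}

draw_cs_order <- function(counts, reinforced_phase, first_six_rule) {
  labels <- rep(names(counts), counts)
  if (!first_six_rule) {
    cs <- sample(labels)
    if (reinforced_phase && !(cs[1] %in% CS_PLUS)) {
      # swap a CS+ into position 1
      j <- which(cs %in% CS_PLUS)[1]
      cs[c(1, j)] <- cs[c(j, 1)]
    }
    return(cs)
  }
  first_six <- sample(rep(names(counts), 2))
  if (reinforced_phase && !(first_six[1] %in% CS_PLUS)) {
    j <- which(first_six %in% CS_PLUS)[1]
    first_six[c(1, j)] <- first_six[c(j, 1)]
  }
  rest_counts <- counts - 2
  rest <- sample(rep(names(rest_counts), rest_counts))
  c(first_six, rest)
}

draw_reinforcement <- function(cs) {
  reinforced <- rep(FALSE, length(cs))
  for (type in CS_PLUS) {
    idx <- which(cs == type)
    # nearest to a 50% schedule; with an odd count both CS+ get ceiling(n/2)
    # so their global reinforcement rates stay equal
    k <- ceiling(length(idx) / 2)
    pick <- sample(idx, k)
    if (cs[1] == type && !(1 %in% pick)) {
      # first trial must be reinforced: force it in, drop one other
      pick <- c(1, sample(setdiff(pick, 1), k - 1))
    }
    reinforced[pick] <- TRUE
  }
  if (!reinforced[1]) return(NULL)
  reinforced
}

max_run <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(as.vector(x))$lengths)
}

first_six_balanced <- function(cs) {
  length(cs) >= 6 && all(table(factor(cs[1:6], levels = CS_LEVELS)) == 2)
}

#' Validate a trial sequence against the design constraints
#'
#' Independent constraint checker: re-derives every rule from the sequence
#' content and returns a character vector of named violations (empty when the
#' sequence is valid). Never raises on content.
#'
#' @param seq A `trial_sequence` (or any tibble with `trial`, `cs`,
#'   `reinforced` and optionally timing columns).
#' @param first_six_rule,max_run_cs,max_run_us As in
#'   [generate_trial_sequence()].
#' @return Character vector of violation names; `character(0)` if valid.
#' @export
validate_sequence <- function(seq, first_six_rule = TRUE,
                              max_run_cs = 5, max_run_us = 4) {
  phase <- seq_phase(seq) %||% "acquisition"
  lay <- phase_layout(phase)
  v <- character(0)
  add <- function(v, name, bad) if (bad) c(v, name) else v

  if (phase == "reminder") {
    v <- add(v, "reminder-shape",
             nrow(seq) != 1 || seq$cs[1] != "CSr+" || seq$reinforced[1])
    return(v)
  }

  counts <- table(factor(seq$cs, levels = CS_LEVELS))
  v <- add(v, "n-trials", nrow(seq) != 3 * lay$per_cs)
  v <- add(v, "cs-counts", !all(counts == lay$per_cs))
  v <- add(v, "csminus-reinforced", any(seq$reinforced[seq$cs == "CS-"]))
  v <- add(v, "max-run-cs", max_run(seq$cs) > max_run_cs)
  if (first_six_rule) {
    v <- add(v, "first-six-balance", !first_six_balanced(seq$cs))
  }
  if (lay$reinforced) {
    v <- add(v, "first-trial-reinforced-csplus",
             !(seq$cs[1] %in% CS_PLUS && seq$reinforced[1]))
    for (type in CS_PLUS) {
      idx <- seq$cs == type
      v <- add(v, paste0("reinforcement-rate-", type),
               sum(seq$reinforced[idx]) != ceiling(sum(idx) / 2))
    }
    # run caps are counted over the CS+ subsequence only
    r <- rle(seq$reinforced[seq$cs %in% CS_PLUS])
    v <- add(v, "max-run-us", any(r$lengths[r$values] > max_run_us))
    v <- add(v, "max-run-us-omission", any(r$lengths[!r$values] > max_run_us))
  } else {
    v <- add(v, "reinforced-in-unreinforced-phase", any(seq$reinforced))
  }

  if ("cs_onset_s" %in% names(seq)) {
    v <- add(v, "onsets-not-increasing", is.unsorted(seq$cs_onset_s, strictly = TRUE))
    v <- add(v, "iti-values", !all(seq$iti_s %in% c(7, 9, 11)))
    if (lay$reinforced) {
      us_ok <- ifelse(seq$reinforced,
                      abs(seq$us_onset_s - (seq$cs_onset_s + seq$cs_duration_s - 0.5)) < 1e-9,
                      is.na(seq$us_onset_s))
      v <- add(v, "us-timing", !all(us_ok, na.rm = FALSE))
    }
    if (lay$probes) {
      v <- add(v, "probe-timing",
               !all(abs(seq$probe_onset_s - (seq$cs_onset_s + 3.5)) < 1e-9))
    }
  }
  v
}

#' Draw trial timings for a fixed CS order
#'
#' Draws intertrial intervals uniformly from `iti_choices` and derives CS, US
#' and probe onset times. The US is a 500 ms train coterminating with the 4 s
#' CS, so `us_onset_s = cs_onset_s + 3.5` on reinforced trials; startle probes
#' (retention phase) sound 3.5 s after every CS onset.
#'
#' @param seq A `trial_sequence` with CS order fixed.
#' @param seed Integer seed for the ITI draw.
#' @param lead_in_s Quiet recording before the first CS onset (seconds).
#' @param cs_duration_s CS duration (default 4 s).
#' @param us_duration_s US duration (default 0.5 s).
#' @param probe_delay_s Probe latency after CS onset (default 3.5 s).
#' @param iti_choices ITI support in seconds (default 7, 9, 11).
#' @return The sequence with columns `iti_s`, `cs_onset_s`, `cs_duration_s`,
#'   `us_onset_s`, `probe_onset_s` added; the attribute `duration_s` holds the
#'   total session length (last CS offset plus its ITI).
#' @export
assign_timing <- function(seq, seed, lead_in_s = 10,
                          cs_duration_s = 4, us_duration_s = 0.5,
                          probe_delay_s = 3.5, iti_choices = c(7, 9, 11)) {
  n <- nrow(seq)
  lay <- phase_layout(seq_phase(seq) %||% "acquisition")
  iti <- withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                          sample(iti_choices, n, replace = TRUE))
  onset <- lead_in_s + c(0, cumsum(cs_duration_s + iti[-n]))
  seq$iti_s <- iti
  seq$cs_onset_s <- onset
  seq$cs_duration_s <- cs_duration_s
  seq$us_onset_s <- ifelse(seq$reinforced,
                           onset + cs_duration_s - us_duration_s, NA_real_)
  seq$probe_onset_s <- if (isTRUE(lay$probes)) onset + probe_delay_s else NA_real_
  attr(seq, "duration_s") <- onset[n] + cs_duration_s + iti[n]
  seq
}

#' Timeline plot of a trial sequence
#'
#' @param object A `trial_sequence` with timing columns.
#' @param ... Ignored.
#' @return A ggplot showing CS onsets by type, with US and probe markers.
#' @export
autoplot.trial_sequence <- function(object, ...) {
  stopifnot("cs_onset_s" %in% names(object))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cs_onset_s, y = .data$cs)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$reinforced), size = 2) +
    ggplot2::geom_point(
      data = dplyr::filter(object, !is.na(.data$us_onset_s)),
      ggplot2::aes(x = .data$us_onset_s), colour = "red", shape = 4
    ) +
    ggplot2::labs(x = "time (s)", y = NULL, shape = "reinforced",
                  title = sprintf("Trial sequence (%s)", seq_phase(object))) +
    ggplot2::theme_minimal()
}
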