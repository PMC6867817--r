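#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

REQUIRED_MANIFEST_FIELDS <- c("version", "participant", "phase", "rates", "units")

# write doubles at 17 significant digits so the text round trip is exact
write_tsv_full <- function(df, path) {
  df <- dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  readr::write_tsv(df, path, progress = FALSE)
}

#' Write / read a session bundle
#'
#' A session bundle is a directory holding one session's recordings in a
#' neutral text interchange format: `manifest.yaml` (participant id, blinded
#' group code, phase, channel inventory with rates and units), one
#' tab-delimited file per channel under `channels/`, the trial event table
#' (`events.tsv`), and artifact/blink annotations (`annotations.tsv`). The
#' round trip `write_bundle()` then `read_bundle()` is the identity on
#' content. The manifest stores only the blinded group code; the code-group
#' mapping lives outside the bundle so all fitting stages run blind.
#'
#' @param bundle A bundle list: `manifest`, `channels` (named list of
#'   [channel_recording()]s), `events` (tibble), `annotations` (tibble).
#' @param path Bundle directory.
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()` returns
#'   the bundle list.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(file.path(path, "channels"), recursive = TRUE, showWarnings = FALSE)
  man <- bundle$manifest
  man$version <- man$version %||% 1L
  man$channels <- names(bundle$channels)
  yaml::write_yaml(man, file.path(path, "manifest.yaml"))
  for (nm in names(bundle$channels)) {
    ch <- bundle$channels[[nm]]
    df <- tibble::as_tibble(ch)[, setdiff(names(ch), "time")]
    write_tsv_full(df, file.path(path, "channels", paste0(nm, ".tsv")))
  }
  write_tsv_full(tibble::as_tibble(bundle$events),
                 file.path(path, "events.tsv"))
  ann <- bundle$annotations %||%
    tibble::tibble(channel = character(0), start_s = numeric(0),
                   end_s = numeric(0), label = character(0))
  readr::write_tsv(ann, file.path(path, "annotations.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  man_path <- file.path(path, "manifest.yaml")
  if (!file.exists(man_path)) stop("not a bundle: missing manifest.yaml",
                                   call. = FALSE)
  man <- yaml::read_yaml(man_path)
  missing_fields <- setdiff(REQUIRED_MANIFEST_FIELDS, names(man))
  if (length(missing_fields)) {
    stop("bundle manifest schema mismatch: missing field(s) ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  channels <- list()
  for (nm in man$channels %||% character(0)) {
    # base read.delim: strtod parsing is correctly rounded, so the 17-digit
    # text representation round-trips bit-exactly
    df <- utils::read.delim(file.path(path, "channels", paste0(nm, ".tsv")))
    extras <- setdiff(names(df), c("value", "valid"))
    channels[[nm]] <- channel_recording(
      df$value, rate = man$rates[[nm]], units = man$units[[nm]], channel = nm,
      valid = df$valid,
      extra = if (length(extras)) as.list(df[extras]) else NULL
    )
  }
  events <- readr::read_tsv(file.path(path, "events.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  # all-NA timing columns (e.g. US onsets in unreinforced phases) come back
  # logical; restore their numeric type
  for (cc in intersect(c("us_onset_s", "probe_onset_s"), names(events))) {
    events[[cc]] <- as.numeric(events[[cc]])
  }
  if ("trial" %in% names(events)) events$trial <- as.integer(events$trial)
  annotations <- readr::read_tsv(file.path(path, "annotations.tsv"),
                                 show_col_types = FALSE, progress = FALSE)
  list(manifest = man, channels = channels, events = events,
       annotations = annotations)
}

#' Export / import a trial sequence as a BIDS-style events file
#'
#' Columns `onset`, `duration`, `trial_type` plus the design columns needed
#' for lossless re-import (`trial`, `reinforced`, `iti_s`, `us_onset_s`,
#' `probe_onset_s`).
#'
#' @param seq A timed `trial_sequence`.
#' @param path Output `.tsv` path.
#' @return `write_events_bids()` returns `path` invisibly;
#'   `read_events_bids()` returns the sequence tibble.
#' @export
write_events_bids <- function(seq, path) {
  df <- tibble::tibble(
    onset = seq$cs_onset_s, duration = seq$cs_duration_s,
    trial_type = seq$cs, trial = seq$trial, reinforced = seq$reinforced,
    iti_s = seq$iti_s, us_onset_s = seq$us_onset_s,
    probe_onset_s = seq$probe_onset_s
  )
  readr::write_tsv(df, path, na = "n/a", progress = FALSE)
  invisible(path)
}

#' @rdname write_events_bids
#' @export
read_events_bids <- function(path) {
  df <- readr::read_tsv(path, na = "n/a", show_col_types = FALSE,
                        progress = FALSE)
  tibble::tibble(
    trial = as.integer(df$trial), cs = df$trial_type,
    reinforced = as.logical(df$reinforced), iti_s = df$iti_s,
    cs_onset_s = df$onset, cs_duration_s = df$duration,
    us_onset_s = as.numeric(df$us_onset_s),
    probe_onset_s = as.numeric(df$probe_onset_s)
  )
}
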