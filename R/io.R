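## On-disk session layout: events.csv (one row per trial, times in seconds,
## positions in cm), signals.rds (hfa_matrix and/or raw_recording, plus the
## ground-truth bank when simulated), meta.json (rates, config hash).

required_event_columns <- c(
  "trial", "block", "arm", "target", "target_x", "target_y", "target_z",
  "central", "cue_onset_s", "imperative_s", "movement_onset_s", "touch_s",
  "touch_x", "touch_y", "return_press_s", "success", "catch"
)

#' Write a session to a directory
#'
#' @param session List with `events` (a `session_events` tibble) and any of
#'   `hfa` (an `hfa_matrix`), `raw` (a `raw_recording`), `bank`
#'   (a `ground_truth_bank`), `config` (a `task_config`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(is.list(session), !is.null(session$events))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ev <- as.data.frame(session$events)
  utils::write.csv(ev[required_event_columns], file.path(dir, "events.csv"),
                   row.names = FALSE)
  signals <- session[intersect(names(session), c("hfa", "raw", "bank", "config"))]
  saveRDS(signals, file.path(dir, "signals.rds"))
  meta <- list(
    n_trials = nrow(ev),
    arms = sort(unique(ev$arm)),
    hfa_fs = if (!is.null(session$hfa)) session$hfa$fs else NULL,
    raw_fs = if (!is.null(session$raw)) session$raw$fs else NULL,
    config_hash = if (!is.null(session$config)) rlang::hash(session$config) else NULL
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Load and validate a session directory
#'
#' Reads the `events.csv` + `signals.rds` layout written by
#' [write_session()]. Schema violations are reported explicitly: missing
#' event columns raise an error enumerating them; trials with non-monotone
#' event times are dropped with a message and recorded in the
#' `rejected_trials` attribute; a stored signal without a sampling rate
#' raises an error naming the missing field.
#'
#' @param path Session directory.
#' @return A list with `events` and whichever of `hfa`, `raw`, `bank`,
#'   `config` were stored.
#' @export
load_session <- function(path) {
  ev_file <- file.path(path, "events.csv")
  sig_file <- file.path(path, "signals.rds")
  if (!file.exists(ev_file)) stop("missing events.csv in ", path, call. = FALSE)
  ev <- utils::read.csv(ev_file, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required_event_columns, names(ev))
  if (length(missing_cols) > 0) {
    stop("events.csv is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ev <- tibble::as_tibble(ev)

  ## enforce event-order invariant on non-catch trials
  with_events <- !ev$catch & !is.na(ev$movement_onset_s)
  ordered_ok <- rep(TRUE, nrow(ev))
  ordered_ok[with_events] <-
    ev$cue_onset_s[with_events] < ev$imperative_s[with_events] &
    ev$imperative_s[with_events] < ev$movement_onset_s[with_events] &
    ev$movement_onset_s[with_events] < ev$touch_s[with_events] &
    ev$touch_s[with_events] < ev$return_press_s[with_events]
  rejected <- ev$trial[!ordered_ok]
  if (length(rejected) > 0) {
    message("rejected ", length(rejected),
            " trial(s) with non-monotone event times: ",
            paste(rejected, collapse = ", "))
    ev <- ev[ordered_ok, ]
  }

  out <- list(events = ev)
  if (file.exists(sig_file)) {
    signals <- readRDS(sig_file)
    for (nm in names(signals)) {
      obj <- signals[[nm]]
      if (nm %in% c("hfa", "raw")) {
        fld <- if (nm == "hfa") "fs" else "fs"
        if (is.null(obj[[fld]])) {
          stop(sprintf("stored %s signal is missing its sampling-rate field '%s'",
                       nm, fld), call. = FALSE)
        }
      }
      out[[nm]] <- obj
    }
  }
  attr(out$events, "rejected_trials") <- rejected
  out
}
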