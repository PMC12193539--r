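#' Trials: ordered behavioral sequences with durations
#'
#' A trial is one individual's record within one couple's bioassay: an
#' ordered list of behavioral acts, each with a duration in seconds.
#'
#' @param trial_id trial identifier.
#' @param codes character vector of act codes, in temporal order.
#' @param durations numeric vector of per-act durations (seconds); recycled
#'   zeros if omitted.
#' @param subject subject identifier (defaults to `trial_id`).
#' @param sex `"male"`, `"female"` or `NA`.
#' @param group group label, e.g. `"virgin"` or `"once_mated"`.
#' @return An object of class `ethochain_trial`.
#' @examples
#' tr <- trial("t1", c("MW", "MTDF", "MWDF"), c(5, 1, 2), sex = "male")
#' tr$acts
#' @export
trial <- function(trial_id, codes, durations = NULL, subject = trial_id,
                  sex = NA_character_, group = NA_character_) {
  codes <- as.character(codes)
  if (length(codes) == 0L) abort("a trial needs at least one act", "validation_error")
  if (any(!nzchar(codes))) abort("empty act code in trial", "validation_error")
  durations <- if (is.null(durations)) rep(0, length(codes)) else as.numeric(durations)
  if (length(durations) != length(codes)) {
    abort("`durations` must match `codes` in length", "validation_error")
  }
  if (any(durations < 0)) abort("durations must be nonnegative", "validation_error")
  structure(
    list(trial_id = as.character(trial_id), subject = as.character(subject),
         sex = sex, group = group,
         acts = data.frame(code = codes, duration = durations)),
    class = "ethochain_trial"
  )
}

#' @export
print.ethochain_trial <- function(x, ...) {
  cat(sprintf("<trial %s [%s/%s]: %s>\n", x$trial_id,
              x$sex %||% NA, x$group %||% NA,
              paste(x$acts$code, collapse = " > ")))
  invisible(x)
}

#' Merge consecutive repeats of the same act
#'
#' Consecutive identical codes are merged into a single act whose duration is
#' the sum of the merged durations. After collapsing, no two consecutive acts
#' share a code, so transition matrices built from collapsed trials have an
#' empty diagonal (no self-transitions).
#'
#' @param x an `ethochain_trial`.
#' @return The collapsed trial.
#' @export
collapse_repeats <- function(x) {
  stopifnot(is_trial(x))
  runs <- rle(x$acts$code)
  if (all(runs$lengths == 1L)) return(x)
  idx <- rep(seq_along(runs$lengths), runs$lengths)
  x$acts <- data.frame(
    code = runs$values,
    duration = as.numeric(tapply(x$acts$duration, idx, sum))
  )
  x
}

#' Default BORIS aggregated-events column mapping
#'
#' Maps the canonical event fields to the column names of a BORIS
#' aggregated-events export. Override entries to read other dialects.
#'
#' @param trial_id,subject,code,start,stop column names in the export.
#' @return Named list usable as the `dialect` argument of [read_boris_events()].
#' @export
boris_dialect <- function(trial_id = "Observation id", subject = "Subject",
                          code = "Behavior", start = "Start (s)", stop = "Stop (s)") {
  list(trial_id = trial_id, subject = subject, code = code, start = start, stop = stop)
}

#' Read behavioral events from a BORIS-style export
#'
#' Reads a delimited export of timed behavioral events (one row per event)
#' and returns one event record per row. Point events (empty or missing stop
#' time) get `stop = start`, i.e. duration zero.
#'
#' @param path path to the delimited export.
#' @param dialect column-name mapping, see [boris_dialect()].
#' @param sep field separator; `"\t"` for TSV exports, `","` for CSV.
#' @return A data.frame with columns `trial_id`, `subject`, `code`, `start`,
#'   `stop` (times in seconds).
#' @export
read_boris_events <- function(path, dialect = boris_dialect(), sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", colClasses = "character")
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("event file '%s' is missing column(s): %s (expected: %s)",
                  path, paste(missing_cols, collapse = ", "),
                  paste(unlist(dialect), collapse = ", ")), "format_error")
  }
  parse_time <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad) > 0L) {
      abort(sprintf("unparseable %s time at data row %d of '%s': '%s'",
                    col, bad[1], path, x[bad[1]]), "format_error")
    }
    out
  }
  start <- parse_time(raw[[dialect$start]], "start")
  stop_ <- parse_time(raw[[dialect$stop]], "stop")
  if (anyNA(start)) {
    abort(sprintf("missing start time at data row %d of '%s'", which(is.na(start))[1], path),
          "format_error")
  }
  stop_[is.na(stop_)] <- start[is.na(stop_)]  # point events
  if (any(stop_ < start)) {
    abort(sprintf("stop before start at data row %d of '%s'", which(stop_ < start)[1], path),
          "format_error")
  }
  data.frame(
    trial_id = trimws(raw[[dialect$trial_id]]),
    subject = trimws(raw[[dialect$subject]]),
    code = trimws(raw[[dialect$code]]),
    start = start, stop = stop_
  )
}

#' Convert event records to per-trial ordered sequences
#'
#' Groups events by `(trial_id, subject)`, orders each group by start time
#' (ties broken by input row order, then code), converts start/stop to
#' durations, and (by default) merges consecutive repeats of the same code.
#' Repeat-collapsing defaults on because first-order transition analysis of
#' these data has no self-transitions.
#'
#' @param events data.frame as returned by [read_boris_events()].
#' @param collapse_repeats merge consecutive identical codes? Default `TRUE`.
#' @param sex,group labels attached to every resulting trial.
#' @return List of `ethochain_trial` objects, ordered by `(trial_id, subject)`.
#' @export
sequences_from_events <- function(events, collapse_repeats = TRUE,
                                  sex = NA_character_, group = NA_character_) {
  if (nrow(events) == 0L) abort("no events to convert", "usage_error")
  key <- interaction(events$trial_id, events$subject, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    ev <- events[idx, ]
    ord <- order(ev$start, seq_len(nrow(ev)), ev$code)
    ev <- ev[ord, ]
    overlaps <- which(ev$start[-1] < ev$stop[-nrow(ev)])
    if (length(overlaps) > 0L) {
      warning(sprintf("overlapping events in trial %s/%s; resolved by start-time order",
                      ev$trial_id[1], ev$subject[1]), call. = FALSE)
    }
    tr <- trial(ev$trial_id[1], ev$code, ev$stop - ev$start,
                subject = ev$subject[1], sex = sex, group = group)
    if (collapse_repeats) collapse_repeats(tr) else tr
  })
  unname(out)
}

#' Read and write the native sequence format
#'
#' One trial per line: `trial_id TAB subject TAB sex TAB group TAB acts`,
#' where `acts` is a comma-separated list of `code:duration` items. A flat
#' line format keeps simulated and fixture sequences diffable.
#'
#' @param path file path.
#' @return For `read_sequences`, a list of `ethochain_trial`; for
#'   `write_sequences`, `path` invisibly.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort(sprintf("no sequences in '%s'", path), "format_error")
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5L) {
      abort(sprintf("line %d of '%s': expected 5 tab-separated fields, got %d",
                    i, path, length(fields)), "format_error")
    }
    items <- strsplit(strsplit(fields[5], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    codes <- vapply(items, `[`, character(1), 1L)
    durs <- as.numeric(vapply(items, `[`, character(1), 2L))
    if (anyNA(durs)) abort(sprintf("line %d of '%s': unparseable duration", i, path), "format_error")
    sex <- if (fields[3] == "NA") NA_character_ else fields[3]
    trial(fields[1], codes, durs, subject = fields[2], sex = sex, group = fields[4])
  })
}

#' @rdname read_sequences
#' @param trials list of `ethochain_trial` objects.
#' @export
write_sequences <- function(trials, path) {
  trials <- check_trials(trials)
  lines <- vapply(trials, function(tr) {
    acts <- paste(sprintf("%s:%g", tr$acts$code, tr$acts$duration), collapse = ",")
    paste(tr$trial_id, tr$subject, tr$sex %||% "NA", tr$group %||% "NA", acts, sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
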