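#' Phase marker transitions
#'
#' Phases of the mating process (premating, mating, postmating) are assigned
#' to positions of a sequence by sex-specific marker transitions: the first
#' occurrence of the mating-start marker switches to the mating phase, and
#' the first later occurrence of the postmating-start marker switches to
#' postmating. The act at a phase-start marker belongs to the *new* phase.
#' A `"*"` subsequent matches any act, used for phases that begin simply
#' after a given act ends.
#'
#' @param sex `"male"` or `"female"`.
#' @param mating_start,postmating_start length-2 character vectors
#'   `c(antecedent, subsequent)`.
#' @return An object of class `ethochain_markers`.
#' @export
phase_markers <- function(sex, mating_start, postmating_start) {
  stopifnot(length(mating_start) == 2L, length(postmating_start) == 2L)
  if (identical(mating_start, postmating_start)) {
    abort("mating and postmating markers must be distinct", "usage_error")
  }
  structure(list(sex = sex, mating_start = mating_start,
                 postmating_start = postmating_start),
            class = "ethochain_markers")
}

#' Default phase markers for the beetle mating ethogram
#'
#' Males: mating begins at the first MEE to MIE transition (MIE is the first
#' mating act), postmating at the first MM to MG transition (MG, guarding,
#' is the first postmating act). Females: mating begins at the first FWK to
#' FM transition (aedeagus insertion), and postmating begins with whatever
#' act follows the end of FQHM (wildcard subsequent).
#'
#' @param sex `"male"` or `"female"`.
#' @return An `ethochain_markers` object.
#' @export
default_markers <- function(sex) {
  if (length(sex) != 1L || !sex %in% SEXES) {
    abort(sprintf("unknown sex label '%s' (expected male or female)",
                  paste(sex, collapse = ",")), "usage_error")
  }
  if (sex == "male") {
    phase_markers("male", c("MEE", "MIE"), c("MM", "MG"))
  } else {
    phase_markers("female", c("FWK", "FM"), c("FQHM", "*"))
  }
}

#' Read phase markers from a JSON file
#'
#' Expects fields `sex`, `mating_start`, `postmating_start` (each marker a
#' two-element array), so other species' ethograms can reuse the machinery.
#'
#' @param path path to the JSON file.
#' @return An `ethochain_markers` object.
#' @export
read_markers <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phase_markers(x$sex, x$mating_start, x$postmating_start)
}

#' Assign phases to the positions of a trial
#'
#' Walks the sequence once: positions before the mating-start marker are
#' premating; from the marker's subsequent act up to (but excluding) the
#' postmating marker's subsequent act, mating; after that, postmating. Only
#' the *first* occurrence of each marker transition switches phase, so e.g.
#' repeated courtship attempts before the first successful insertion all
#' remain premating. If a marker never occurs the later phases are absent.
#'
#' @param trial a repeat-collapsed `ethochain_trial`.
#' @param markers an `ethochain_markers` object (see [default_markers()]).
#' @return An object of class `ethochain_phases`: list with `trial_id`,
#'   `annotation` (data.frame position/code/duration/phase) and
#'   `phase_durations` (named numeric, seconds per phase present).
#' @examples
#' tr <- trial("t1", c("MW", "MEE", "MIE", "MM", "MG"), c(5, 2, 60, 200, 100))
#' segment_phases(tr, default_markers("male"))$phase_durations
#' @export
segment_phases <- function(trial, markers) {
  stopifnot(is_trial(trial))
  codes <- trial$acts$code
  n <- length(codes)
  phase <- rep("premating", n)
  match_marker <- function(marker, from = 1L) {
    if (n < 2L || from > n - 1L) return(NA_integer_)
    idx <- seq.int(from, n - 1L)
    hit <- codes[idx] == marker[1] & (marker[2] == "*" | codes[idx + 1L] == marker[2])
    if (any(hit)) idx[which(hit)[1]] + 1L else NA_integer_
  }
  mating_at <- match_marker(markers$mating_start)
  if (!is.na(mating_at)) {
    phase[mating_at:n] <- "mating"
    post_at <- match_marker(markers$postmating_start, from = mating_at)
    if (!is.na(post_at)) phase[post_at:n] <- "postmating"
  }
  durations <- tapply(trial$acts$duration, factor(phase, levels = PHASES), sum)
  durations <- durations[!is.na(durations)]
  structure(list(
    trial_id = trial$trial_id,
    annotation = data.frame(position = seq_len(n), code = codes,
                            duration = trial$acts$duration, phase = phase),
    phase_durations = durations
  ), class = "ethochain_phases")
}

#' Per-phase duration summaries across trials
#'
#' Segments every trial and summarizes the total time spent in each phase:
#' mean, standard error of the mean (SEM), and the number of trials in which
#' the phase occurred. Phases absent from a trial contribute nothing to that
#' phase's summary; a phase absent from all trials is reported with n = 0
#' and NA mean, and a single-trial phase has NA (undefined) SEM.
#'
#' @param trials list of trials (one group).
#' @param markers an `ethochain_markers` object.
#' @param group optional group label echoed in the output.
#' @return Data.frame with columns `group`, `phase`, `n`, `mean`, `sem`.
#' @export
phase_durations <- function(trials, markers, group = NA_character_) {
  trials <- check_trials(trials)
  per_trial <- lapply(trials, function(tr) segment_phases(tr, markers)$phase_durations)
  out <- lapply(PHASES, function(ph) {
    vals <- unlist(lapply(per_trial, function(d) d[ph]))
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    data.frame(group = group, phase = ph, n = n,
               mean = if (n > 0) mean(vals) else NA_real_,
               sem = if (n > 1) stats::sd(vals) / sqrt(n) else NA_real_)
  })
  do.call(rbind, out)
}

#' Write a phase annotation as TSV
#'
#' One row per act position: trial_id, position, code, phase, duration.
#'
#' @param annotations list of `ethochain_phases` (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotations, path) {
  if (inherits(annotations, "ethochain_phases")) annotations <- list(annotations)
  rows <- do.call(rbind, lapply(annotations, function(a) {
    cbind(trial_id = a$trial_id, a$annotation[c("position", "code", "phase", "duration")])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
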