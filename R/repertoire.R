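#' Behavior repertoires
#'
#' A repertoire is the catalog of discrete behavioral acts an animal can
#' perform: a short uppercase code (e.g. `"MW"`, male walks), a name, a
#' free-text description, the mating phase the act belongs to by default
#' (premating, mating or postmating), and whether the act can terminate a
#' sequence. All other modules reference acts by code.
#'
#' The phase recorded here is a default only: the authoritative phase of an
#' *occurrence* of an act comes from marker-based segmentation (see
#' [segment_phases()]), since the same motor pattern can occur in different
#' phases under different codes (e.g. FW vs FWP).
#'
#' @name repertoire
NULL

#' Load a behavior repertoire from a delimited text file
#'
#' Reads a CSV (or TSV) file with header columns `code`, `name`,
#' `description`, `phase`, and optionally `terminal` and `notes`. Codes are
#' whitespace-stripped and treated case-sensitively. Packaged transcriptions
#' of the male (13 acts) and female (11 acts) beetle mating repertoires are
#' available through [reference_repertoire()].
#'
#' @param path path to the repertoire file.
#' @param sex `"male"` or `"female"`; recorded on the returned object.
#' @param sep field separator, `","` by default.
#' @return An object of class `ethochain_repertoire`: a list with elements
#'   `acts` (a data.frame with one row per act, in file order) and `sex`.
#' @examples
#' rep_m <- reference_repertoire("male")
#' nrow(rep_m$acts)  # 13
#' @seealso [reference_repertoire()], [validate_codes()]
#' @export
load_repertoire <- function(path, sex = c("male", "female", "mixed"), sep = ",") {
  sex <- match.arg(sex)
  acts <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, comment.char = "")
  if (nrow(acts) == 0L) abort(sprintf("repertoire file '%s' has no rows", path), "format_error")
  required <- c("code", "name", "description", "phase")
  missing_cols <- setdiff(required, names(acts))
  if (length(missing_cols) > 0L) {
    abort(sprintf("repertoire file '%s' is missing column(s): %s",
                  path, paste(missing_cols, collapse = ", ")), "format_error")
  }
  acts$code <- trimws(acts$code)
  if (is.null(acts$terminal)) acts$terminal <- FALSE
  acts$terminal <- as.logical(acts$terminal)
  if (is.null(acts$notes)) acts$notes <- ""
  new_repertoire(acts, sex)
}

new_repertoire <- function(acts, sex) {
  dup <- unique(acts$code[duplicated(acts$code)])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate act code(s) in repertoire: %s", paste(dup, collapse = ", ")),
          "validation_error")
  }
  if (any(!nzchar(acts$code))) abort("empty act code in repertoire", "validation_error")
  bad_phase <- setdiff(unique(acts$phase), PHASES)
  if (length(bad_phase) > 0L) {
    abort(sprintf("unknown phase label(s): %s (expected %s)",
                  paste(bad_phase, collapse = ", "), paste(PHASES, collapse = "/")),
          "validation_error")
  }
  rownames(acts) <- NULL
  structure(list(acts = acts, sex = sex), class = "ethochain_repertoire")
}

#' Write a repertoire back to a delimited text file
#'
#' Inverse of [load_repertoire()]; loading the written file yields an
#' identical act table (round-trip identity).
#'
#' @param repertoire an `ethochain_repertoire`.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(repertoire, path, sep = ",") {
  utils::write.table(repertoire$acts, path, sep = sep, quote = TRUE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Packaged reference repertoires
#'
#' Returns the packaged transcription of the published male (13 acts:
#' 8 premating, 2 mating, 3 postmating -- MG, MWP, and the remating-only
#' MQP) or female (11 acts: 8 premating, 2 mating, 1 postmating) beetle
#' mating-behavior repertoire.
#'
#' @param sex `"male"` or `"female"`.
#' @return An `ethochain_repertoire`.
#' @export
reference_repertoire <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  path <- system.file("extdata", paste0("repertoire_", sex, ".csv"),
                      package = "ethochain", mustWork = TRUE)
  load_repertoire(path, sex = sex)
}

#' Check trial codes against a repertoire
#'
#' Reports the full set of codes used by `trials` that are absent from the
#' repertoire (not just the first offender).
#'
#' @param repertoire an `ethochain_repertoire`.
#' @param trials a list of trials (see [trial()]) or a character vector of codes.
#' @return Character vector of unknown codes (empty when all codes are known).
#' @export
validate_codes <- function(repertoire, trials) {
  codes <- if (is.character(trials)) trials else {
    unique(unlist(lapply(check_trials(trials), function(tr) tr$acts$code)))
  }
  sort(setdiff(unique(codes), repertoire$acts$code))
}

#' @export
print.ethochain_repertoire <- function(x, ...) {
  cat(sprintf("<%s repertoire: %d acts (%s)>\n", x$sex, nrow(x$acts),
              paste(sprintf("%s %d", names(table(x$acts$phase)[PHASES[PHASES %in% x$acts$phase]]),
                            table(x$acts$phase)[PHASES[PHASES %in% x$acts$phase]]),
                    collapse = ", ")))
  print(x$acts[, c("code", "name", "phase", "terminal")], ...)
  invisible(x)
}
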