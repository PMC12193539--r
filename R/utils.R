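# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

PHASES <- c("premating", "mating", "postmating")
SEXES <- c("male", "female")

#' Truncate towards zero at a number of decimal places
#'
#' The published transition tables print values truncated (not rounded) to
#' the shown decimals; this reproduces that convention for regression
#' comparisons against printed values.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector truncated to `digits` decimals.
#' @keywords internal
#' @noRd
trunc_digits <- function(x, digits) {
  f <- 10^digits
  trunc(x * f) / f
}

# Number of decimal places in a printed numeric string ("3.14" -> 2, "64" -> 0).
printed_decimals <- function(x) {
  x <- as.character(x)
  has_dot <- grepl(".", x, fixed = TRUE)
  out <- integer(length(x))
  out[has_dot] <- nchar(sub("^[^.]*\\.", "", x[has_dot]))
  out
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
abort <- function(message, class) {
  stop(structure(
    class = c(class, "ethochain_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_trial <- function(x) inherits(x, "ethochain_trial")

check_trials <- function(trials, what = "trials") {
  if (is_trial(trials)) trials <- list(trials)
  if (!is.list(trials) || length(trials) == 0L || !all(vapply(trials, is_trial, logical(1)))) {
    abort(sprintf("`%s` must be a nonempty list of trial objects", what), "usage_error")
  }
  trials
}
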