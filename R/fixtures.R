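#' Packaged reference transition tables
#'
#' The package ships verbatim transcriptions of the four published
#' significant-transition tables of beetle mating behavior (virgin and
#' once-mated males and females): observed counts, printed expected values,
#' per-cell chi-square, transition percentages, significance stars, the
#' printed row/column margins, grand totals, and the printed omnibus
#' statistics. These serve as regression fixtures for the transition
#' analysis and as parameter sources for the sequence simulator.
#'
#' @return `reference_groups()` returns the valid group names.
#' @export
reference_groups <- function() {
  c("virgin_male", "mated_male", "virgin_female", "mated_female")
}

#' @rdname reference_groups
#'
#' @details
#' Printed `exp`, `chi_sq` and `t_pct` values are retained as character
#' strings (alongside numeric versions) because the source truncates values
#' to the printed decimals; regression comparisons need the printed
#' precision. One `virgin_female` cell (FW to FMM, observed 13) is not
#' printed in the source table but is implied exactly by its margins; it is
#' included with `significant = FALSE`, `inferred = TRUE` so that margin
#' conservation holds.
#'
#' @param group one of `"virgin_male"`, `"mated_male"`, `"virgin_female"`,
#'   `"mated_female"`.
#' @return `load_reference_table()` returns an object of class
#'   `ethochain_fixture`: a list with elements `group`, `sex`, `n_trials`,
#'   `cells` (data.frame), `antecedents`, `subsequents`, `row_totals`,
#'   `col_totals`, `grand_total`, `sum_chi_sq`, `df`.
#' @examples
#' fx <- load_reference_table("virgin_male")
#' fx$grand_total  # 258
#' fx$df           # 90
#' @export
load_reference_table <- function(group) {
  if (length(group) != 1L || !group %in% reference_groups()) {
    abort(sprintf("unknown reference table '%s'; valid names: %s",
                  paste(group, collapse = ","), paste(reference_groups(), collapse = ", ")),
          "lookup_error")
  }
  extdata <- function(f) system.file("extdata", f, package = "ethochain", mustWork = TRUE)
  cells <- utils::read.table(extdata("reference_cells.tsv"), header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, colClasses = "character",
                             comment.char = "#")
  cells <- cells[cells$group == group, ]
  cells$obs <- as.integer(cells$obs)
  cells$significant <- as.logical(cells$significant)
  cells$inferred <- as.logical(cells$inferred)
  for (col in c("exp", "chi_sq", "t_pct")) {
    cells[[paste0(col, "_printed")]] <- cells[[col]]
    cells[[col]] <- suppressWarnings(as.numeric(cells[[col]]))
  }
  rownames(cells) <- NULL

  marg <- jsonlite::read_json(extdata("reference_margins.json"), simplifyVector = TRUE)[[group]]
  fx <- structure(
    list(group = group, sex = marg$sex, n_trials = marg$n_trials,
         cells = cells,
         antecedents = marg$antecedents, subsequents = marg$subsequents,
         row_totals = unlist(marg$row_totals), col_totals = unlist(marg$col_totals),
         grand_total = marg$grand_total,
         sum_chi_sq = marg$sum_chi_sq, df = marg$df),
    class = "ethochain_fixture"
  )
  validate_fixture(fx)
  fx
}

# Conservation: cell sums must reproduce the printed margins and grand total.
validate_fixture <- function(fx) {
  cells <- fx$cells
  if (sum(cells$obs) != fx$grand_total) {
    abort(sprintf("fixture %s: cell sum %d != grand total %d",
                  fx$group, sum(cells$obs), fx$grand_total), "validation_error")
  }
  row_sums <- tapply(cells$obs, factor(cells$antecedent, levels = fx$antecedents), sum,
                     default = 0L)
  col_sums <- tapply(cells$obs, factor(cells$subsequent, levels = fx$subsequents), sum,
                     default = 0L)
  if (any(row_sums != fx$row_totals[fx$antecedents])) {
    abort(sprintf("fixture %s: row totals do not match cell sums", fx$group), "validation_error")
  }
  if (any(col_sums != fx$col_totals[fx$subsequents])) {
    abort(sprintf("fixture %s: column totals do not match cell sums", fx$group), "validation_error")
  }
  invisible(fx)
}

#' @export
print.ethochain_fixture <- function(x, ...) {
  cat(sprintf("<reference transition table '%s' (%s): %d cells, N = %d, Sum chi2 = %s, df = %d>\n",
              x$group, x$sex, nrow(x$cells), x$grand_total,
              format(x$sum_chi_sq), x$df))
  invisible(x)
}

#' Build a transition count matrix from a reference table
#'
#' Assembles the fixture's observed counts into the same
#' `ethochain_matrix` container produced by [count_transitions()], with the
#' printed antecedent/subsequent ordering and margins.
#'
#' @param fixture an `ethochain_fixture` from [load_reference_table()].
#' @return An `ethochain_matrix`.
#' @export
fixture_matrix <- function(fixture) {
  obs <- matrix(0L, length(fixture$antecedents), length(fixture$subsequents),
                dimnames = list(fixture$antecedents, fixture$subsequents))
  obs[cbind(fixture$cells$antecedent, fixture$cells$subsequent)] <- fixture$cells$obs
  new_transition_matrix(obs)
}

#' Printed group-comparison statistics
#'
#' Loads the packaged transcription of the study's printed group statistics:
#' percentages of males walking at the start / showing the MHAM act with
#' printed z and p, and the guarding-duration summaries (mean, SEM, n) with
#' the printed t-test results.
#'
#' @return Nested list mirroring the packaged JSON.
#' @export
load_group_stats <- function() {
  path <- system.file("extdata", "group_stats.json", package = "ethochain", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
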