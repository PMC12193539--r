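#' Analysis configuration
#'
#' Bundles the tunable conventions of the transition analysis.
#'
#' @param min_occurrence_fraction acts must occur in at least this fraction
#'   of trials to enter the matrix (inclusive comparison). Default 0.10, the
#'   study's "at least 10% of the repetitions" rule, where a repetition is
#'   one couple's bioassay trial.
#' @param significance_rule `"obs_gt_exp"` (default): a transition is
#'   significant when its observed count strictly exceeds its expected
#'   count, the published criterion (every starred cell in the reference
#'   tables has O > E). `"obs_gt_exp_and_cell_chi2"` additionally requires
#'   the per-cell chi-square to reach `cell_chi2_threshold`.
#' @param cell_chi2_threshold per-cell chi-square cutoff for the stricter
#'   rule; 3.84 is the 0.95 quantile of chi-square with 1 df.
#' @param percentage_denominator denominator of the transition percentage T:
#'   `"all_transitions"` (default) uses the matrix grand total N, which
#'   reproduces every printed T in the reference tables;
#'   `"significant_only"` uses the sum of observed counts over significant
#'   cells.
#' @param expected_rounding `"unrounded"` (default) computes chi-square from
#'   exact expected values; `"two_decimals"` truncates E to 2 decimals
#'   first, the convention under which several printed chi-square values
#'   (e.g. 267.8 for an E of 0.09) are reproduced.
#' @param alpha two-sided rejection probability for the omnibus test.
#' @return A list of class `ethochain_config`.
#' @export
analysis_config <- function(min_occurrence_fraction = 0.10,
                            significance_rule = c("obs_gt_exp", "obs_gt_exp_and_cell_chi2"),
                            cell_chi2_threshold = 3.84,
                            percentage_denominator = c("all_transitions", "significant_only"),
                            expected_rounding = c("unrounded", "two_decimals"),
                            alpha = 0.05) {
  if (!(min_occurrence_fraction > 0 && min_occurrence_fraction < 1)) {
    abort("`min_occurrence_fraction` must be in (0, 1)", "usage_error")
  }
  if (!(alpha > 0 && alpha < 1)) abort("`alpha` must be in (0, 1)", "usage_error")
  structure(list(
    min_occurrence_fraction = min_occurrence_fraction,
    significance_rule = match.arg(significance_rule),
    cell_chi2_threshold = cell_chi2_threshold,
    percentage_denominator = match.arg(percentage_denominator),
    expected_rounding = match.arg(expected_rounding),
    alpha = alpha
  ), class = "ethochain_config")
}

#' Acts passing the occurrence inclusion rule
#'
#' An act is included when the fraction of trials containing it is at least
#' `min_fraction` (number of trials containing the act / number of trials;
#' the comparison is inclusive, so 3 of 26 trials passes a 0.10 threshold).
#'
#' @param trials list of trials.
#' @param min_fraction inclusion threshold in (0, 1).
#' @return Character vector of included codes, in order of first appearance.
#' @export
include_acts <- function(trials, min_fraction = 0.10) {
  trials <- check_trials(trials)
  all_codes <- unlist(lapply(trials, function(tr) unique(tr$acts$code)))
  counts <- table(factor(all_codes, levels = unique(all_codes)))
  names(counts)[counts / length(trials) >= min_fraction]
}

new_transition_matrix <- function(observed) {
  storage.mode(observed) <- "integer"
  structure(list(
    observed = observed,
    antecedents = rownames(observed),
    subsequents = colnames(observed),
    row_totals = rowSums(observed),
    col_totals = colSums(observed),
    N = sum(observed)
  ), class = "ethochain_matrix")
}

#' @export
print.ethochain_matrix <- function(x, ...) {
  cat(sprintf("<transition count matrix: %d antecedents x %d subsequents, N = %d>\n",
              length(x$antecedents), length(x$subsequents), x$N))
  print(x$observed, ...)
  invisible(x)
}

#' Count first-order transitions
#'
#' Tallies how often act `a` is immediately followed by act `b` across all
#' trials, over the supplied act set. Only consecutive pairs whose two codes
#' are both in `acts` are counted; other pairs are skipped (the number of
#' skipped pairs is attached as attribute `skipped`). Acts with no outgoing
#' transitions contribute no row and acts with no incoming transitions no
#' column, so the matrix need not be square.
#'
#' @param trials list of repeat-collapsed trials.
#' @param acts character vector of codes to count over.
#' @return An `ethochain_matrix` with observed counts, margins and grand
#'   total N.
#' @export
count_transitions <- function(trials, acts) {
  trials <- check_trials(trials)
  if (length(acts) == 0L) abort("`acts` must be nonempty", "usage_error")
  obs <- matrix(0L, length(acts), length(acts), dimnames = list(acts, acts))
  skipped <- 0L
  for (tr in trials) {
    codes <- tr$acts$code
    if (length(codes) < 2L) next
    a <- codes[-length(codes)]
    b <- codes[-1L]
    keep <- a %in% acts & b %in% acts
    skipped <- skipped + sum(!keep)
    if (any(keep)) {
      tab <- table(factor(a[keep], levels = acts), factor(b[keep], levels = acts))
      obs <- obs + unclass(tab)
    }
  }
  obs <- obs[rowSums(obs) > 0L, colSums(obs) > 0L, drop = FALSE]
  out <- new_transition_matrix(obs)
  attr(out, "skipped") <- skipped
  out
}

#' Expected transition frequencies under independence
#'
#' E(a, b) = row total(a) x column total(b) / N, the contingency-table
#' expectation for every structural cell.
#'
#' @param matrix an `ethochain_matrix`.
#' @return Numeric matrix of expected values with the same dimensions.
#' @export
expected_counts <- function(matrix) {
  if (matrix$N <= 0) abort("cannot compute expected counts with N = 0", "usage_error")
  outer(matrix$row_totals, matrix$col_totals) / matrix$N
}

#' Per-cell chi-square contribution
#'
#' (O - E)^2 / E, vectorized over cells.
#'
#' @param observed observed count(s).
#' @param expected expected value(s), strictly positive.
#' @return Numeric chi-square contribution(s).
#' @export
cell_chi_square <- function(observed, expected) {
  if (any(expected <= 0)) abort("expected values must be > 0", "usage_error")
  (observed - expected)^2 / expected
}

#' Transition percentages
#'
#' T(a, b) = 100 x O(a, b) / D. Under the default `"all_transitions"`
#' convention D is the grand total N; under `"significant_only"` it is the
#' observed total over significant cells (which requires `significant`).
#'
#' @param matrix an `ethochain_matrix`.
#' @param denominator percentage convention, see [analysis_config()].
#' @param significant logical matrix of significance flags, needed for the
#'   `"significant_only"` convention.
#' @return Numeric matrix of percentages in `[0, 100]`.
#' @export
transition_percentages <- function(matrix,
                                   denominator = c("all_transitions", "significant_only"),
                                   significant = NULL) {
  denominator <- match.arg(denominator)
  D <- if (denominator == "all_transitions") matrix$N else {
    if (is.null(significant)) {
      abort("`significant` flags are required for the significant_only convention", "usage_error")
    }
    sum(matrix$observed[significant])
  }
  if (D <= 0) abort("zero percentage denominator", "usage_error")
  100 * matrix$observed / D
}

#' Flag significant transitions
#'
#' Under the published criterion (`"obs_gt_exp"`) a cell is significant when
#' its observed count strictly exceeds its expected count. The stricter rule
#' additionally requires the per-cell chi-square to reach `threshold`.
#'
#' @param observed,expected matrices (or vectors) of observed counts and
#'   expected values.
#' @param rule significance rule, see [analysis_config()].
#' @param threshold per-cell chi-square cutoff for the stricter rule.
#' @return Logical matrix (or vector) of flags.
#' @export
flag_significant <- function(observed, expected,
                             rule = c("obs_gt_exp", "obs_gt_exp_and_cell_chi2"),
                             threshold = 3.84) {
  rule <- match.arg(rule)
  sig <- observed > expected
  if (rule == "obs_gt_exp_and_cell_chi2") {
    sig <- sig & (observed - expected)^2 / expected >= threshold
  }
  sig
}

#' Omnibus test over significant transitions
#'
#' The global statistic is the sum of per-cell chi-square values over the
#' cells flagged significant (this reproduces the published sum 1646.44 ~
#' 1646.4 for the virgin-male table from its printed cells). Degrees of
#' freedom are (r - 1)(c - 1) over the full matrix, with r antecedent rows
#' and c subsequent columns counted separately; the p-value is the upper
#' tail of the chi-square distribution.
#'
#' @param matrix an `ethochain_matrix`.
#' @param chi_sq matrix of per-cell chi-square values.
#' @param significant logical matrix of significance flags.
#' @return List with `sum_chi_sq`, `df`, `p_value`.
#' @export
global_test <- function(matrix, chi_sq, significant) {
  r <- length(matrix$antecedents)
  c <- length(matrix$subsequents)
  if (r < 2L || c < 2L) abort("omnibus test needs at least a 2x2 matrix", "usage_error")
  stat <- sum(chi_sq[significant])
  df <- (r - 1L) * (c - 1L)
  list(sum_chi_sq = stat, df = df, p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' First-order Markov transition analysis of behavioral sequences
#'
#' The full pipeline: apply the occurrence inclusion rule, count first-order
#' transitions, compute expected frequencies under independence, flag
#' significant transitions, compute per-cell chi-square and transition
#' percentages, and run the omnibus test.
#'
#' @param trials list of repeat-collapsed trials (see [trial()],
#'   [sequences_from_events()]).
#' @param config an [analysis_config()].
#' @return An object of class `ethochain_analysis`: a list with the count
#'   `matrix`, matrices `expected`, `chi_sq`, `t_pct`, `significant`, the
#'   `included_acts`, a long-format `cells` data.frame (one row per nonzero
#'   cell), `sum_chi_square_significant`, `df`, `p_global`, `n_trials`, and
#'   the `config` echo.
#' @examples
#' trs <- list(
#'   trial("t1", c("MW", "MTDF", "MWDF", "MATFB")),
#'   trial("t2", c("MW", "MTDF", "MWDF", "MATFB"))
#' )
#' an <- analyze(trs)
#' an$df
#' @export
analyze <- function(trials, config = analysis_config()) {
  trials <- check_trials(trials)
  included <- include_acts(trials, config$min_occurrence_fraction)
  if (length(included) == 0L) abort("no acts pass the inclusion rule", "usage_error")
  m <- count_transitions(trials, included)
  if (m$N == 0L) abort("no transitions among included acts", "usage_error")
  expected <- expected_counts(m)
  e_used <- if (config$expected_rounding == "two_decimals") trunc_digits(expected, 2) else expected
  significant <- flag_significant(m$observed, e_used, config$significance_rule,
                                  config$cell_chi2_threshold)
  chi_sq <- matrix(NA_real_, nrow(e_used), ncol(e_used), dimnames = dimnames(e_used))
  pos <- e_used > 0
  chi_sq[pos] <- cell_chi_square(m$observed[pos], e_used[pos])
  t_pct <- transition_percentages(m, config$percentage_denominator, significant)
  glob <- global_test(m, chi_sq, significant)

  nz <- which(m$observed > 0L, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  cells <- data.frame(
    antecedent = m$antecedents[nz[, 1L]],
    subsequent = m$subsequents[nz[, 2L]],
    obs = m$observed[nz],
    exp = expected[nz],
    chi_sq = chi_sq[nz],
    t_pct = t_pct[nz],
    significant = significant[nz]
  )

  structure(list(
    matrix = m, expected = expected, chi_sq = chi_sq, t_pct = t_pct,
    significant = significant, included_acts = included, cells = cells,
    sum_chi_square_significant = glob$sum_chi_sq, df = glob$df,
    p_global = glob$p_value, n_trials = length(trials), config = config
  ), class = "ethochain_analysis")
}

#' @export
print.ethochain_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "<transition analysis: %d trials, %d included acts, N = %d transitions>\n",
    "  significant cells: %d; Sum chi2 = %.2f, df = %d, p %s\n"),
    x$n_trials, length(x$included_acts), x$matrix$N,
    sum(x$significant), x$sum_chi_square_significant, x$df,
    if (x$p_global < 1e-4) "< 1e-4" else sprintf("= %.4g", x$p_global)))
  invisible(x)
}

#' Write a transition table and JSON summary
#'
#' `write_transition_table()` writes the long-format cell table (antecedent,
#' subsequent, Obs, Exp, chi2, T, significant) as TSV, mirroring the
#' published table layout; `analysis_summary()` returns (and optionally
#' writes as JSON) the headline quantities.
#'
#' @param analysis an `ethochain_analysis`.
#' @param path output path (TSV or JSON).
#' @param digits decimals for reported Exp, chi-square and T values.
#' @return `path` (or the summary list), invisibly.
#' @export
write_transition_table <- function(analysis, path, digits = 2) {
  cells <- analysis$cells
  for (col in c("exp", "chi_sq", "t_pct")) cells[[col]] <- round(cells[[col]], digits)
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_table
#' @export
analysis_summary <- function(analysis, path = NULL) {
  out <- list(
    n_trials = analysis$n_trials,
    included_acts = analysis$included_acts,
    n_transitions = analysis$matrix$N,
    n_significant = sum(analysis$significant),
    sum_chi_square_significant = analysis$sum_chi_square_significant,
    df = analysis$df,
    p_global = analysis$p_global,
    config = unclass(analysis$config)
  )
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Regression of expected values against a printed reference table
#'
#' Recomputes E = row total x column total / N from the printed margins of a
#' reference table and compares with the printed expected values. The
#' printed values are truncated to the shown decimals (occasionally
#' rounded), so the per-cell tolerance is one unit in the last printed digit
#' plus 0.02. Known print inconsistencies can be excluded via `skip` (cell
#' keys `"A->B"`).
#'
#' @param fixture an `ethochain_fixture`.
#' @param skip character vector of `"antecedent->subsequent"` keys excluded
#'   from the pass/fail flag (still reported).
#' @return Data.frame with one row per printed cell: printed and recomputed
#'   E, absolute deviation, tolerance, and flags `ok` and `skipped`.
#' @export
expected_regression <- function(fixture, skip = character()) {
  cells <- fixture$cells[!is.na(fixture$cells$exp), ]
  computed <- fixture$row_totals[cells$antecedent] * fixture$col_totals[cells$subsequent] /
    fixture$grand_total
  dp <- printed_decimals(cells$exp_printed)
  tol <- 10^(-dp) + 0.02
  key <- paste0(cells$antecedent, "->", cells$subsequent)
  data.frame(
    antecedent = cells$antecedent, subsequent = cells$subsequent,
    obs = cells$obs, exp_printed = cells$exp, exp_computed = unname(computed),
    delta = unname(abs(computed - cells$exp)), tol = tol,
    skipped = key %in% skip,
    ok = key %in% skip | abs(computed - cells$exp) <= tol
  )
}

#' @rdname expected_regression
#'
#' @details
#' `chi_square_regression()` does the analogous check for the printed
#' per-cell chi-square values. The source is inconsistent about whether
#' chi-square was computed from the printed (2-decimal) or the unrounded
#' expected value, so the recomputation accepts agreement with either
#' convention.
#' @export
chi_square_regression <- function(fixture, skip = character()) {
  cells <- fixture$cells[!is.na(fixture$cells$chi_sq), ]
  e_margin <- fixture$row_totals[cells$antecedent] * fixture$col_totals[cells$subsequent] /
    fixture$grand_total
  chi_unrounded <- cell_chi_square(cells$obs, e_margin)
  chi_printed_e <- cell_chi_square(cells$obs, cells$exp)
  dp <- printed_decimals(cells$chi_sq_printed)
  tol <- 10^(-dp) + 0.02
  d1 <- abs(chi_unrounded - cells$chi_sq)
  d2 <- abs(chi_printed_e - cells$chi_sq)
  key <- paste0(cells$antecedent, "->", cells$subsequent)
  data.frame(
    antecedent = cells$antecedent, subsequent = cells$subsequent,
    chi_printed = cells$chi_sq,
    chi_from_margins = unname(chi_unrounded), chi_from_printed_e = unname(chi_printed_e),
    delta = unname(pmin(d1, d2)), tol = tol,
    skipped = key %in% skip,
    ok = key %in% skip | pmin(d1, d2) <= tol
  )
}
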