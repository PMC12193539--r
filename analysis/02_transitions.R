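#!/usr/bin/env Rscript
# Step 2: first-order transition analysis.
#
# (a) Regression against the published tables: recompute expected values
#     E = row x col / N and per-cell chi-square from the printed margins and
#     compare with the printed cells (print errors are skip-listed).
# (b) Full pipeline on the simulated sequence sets from step 1: inclusion
#     rule, counts, expected values, significance flags, omnibus test.

suppressPackageStartupMessages(library(ethochain))
`%||%` <- function(a, b) if (is.null(a)) b else a
dir.create("results", showWarnings = FALSE)

exp_skip <- list(virgin_male = c("MEE->MIE", "MIE->MM", "MM->MG", "MWDF->MATFB"))
chi_skip <- list(virgin_male = c("MHAM->MW", "MHFAR->MW"))

cat("== Regression of printed expected values and chi-square ==\n")
regs <- lapply(reference_groups(), function(grp) {
  fx <- load_reference_table(grp)
  reg <- expected_regression(fx, skip = exp_skip[[grp]] %||% character())
  chi <- chi_square_regression(fx, skip = chi_skip[[grp]] %||% character())
  cat(sprintf("%-14s E: %2d/%2d cells ok (max |delta| %.3f, %d skip-listed); chi2: %2d/%2d ok\n",
              grp, sum(reg$ok), nrow(reg), max(reg$delta[!reg$skipped]),
              sum(reg$skipped), sum(chi$ok), nrow(chi)))
  cbind(group = grp, reg)
})
write.table(do.call(rbind, regs), "results/expected_regression.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("\n== Transition analysis of the simulated sequence sets ==\n")
for (grp in reference_groups()) {
  trials <- read_sequences(file.path("results", sprintf("sequences_%s.tsv", grp)))
  an <- analyze(trials)  # defaults: 10% inclusion, O > E criterion, T over N
  write_transition_table(an, file.path("results", sprintf("transitions_%s.tsv", grp)))
  analysis_summary(an, file.path("results", sprintf("transitions_%s.json", grp)))
  rec <- significant_edge_recovery(spec_from_analysis(load_reference_table(grp)), an)
  cat(sprintf("%-14s N = %3d, %2d significant cells, Sum chi2 = %7.1f, df = %3d; strong-edge recovery %d/%d\n",
              grp, an$matrix$N, sum(an$significant),
              an$sum_chi_square_significant, an$df, rec$recovered, rec$total))
}
cat("\nAt the study's own sample sizes most, but not necessarily all, strong\nreference edges reach significance; tables written under results/.\n")
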