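#!/usr/bin/env Rscript
# Step 1: simulate trial collections for the four study groups.
#
# The raw observation videos behind the published transition tables were
# never deposited, so the workflow starts by deriving a semi-Markov
# generator from each published table (conditional transition probabilities
# from row-normalized counts; initial distribution and per-act stopping
# probabilities from the margins' net flow) and simulating sequence sets at
# the study's sample sizes: 26 virgin couples and 15 once-mated couples.
# Per-act durations are placeholder lognormals (the source prints no
# per-act duration data).

suppressPackageStartupMessages(library(ethochain))
dir.create("results", showWarnings = FALSE)
seed0 <- 20260901L

for (grp in reference_groups()) {
  gen <- reference_generator(grp, seed = seed0 + match(grp, reference_groups()))
  trials <- simulate_trials(gen)  # n_trials = the group's study sample size
  out <- file.path("results", sprintf("sequences_%s.tsv", grp))
  write_sequences(trials, out)
  lens <- vapply(trials, function(tr) nrow(tr$acts), integer(1))
  cat(sprintf("%s: %d trials (median length %d acts) -> %s\n",
              grp, length(trials), as.integer(median(lens)), out))
}
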