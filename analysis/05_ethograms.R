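#!/usr/bin/env Rscript
# Step 5: phase-colored kinematic diagrams (DOT).
#
# One directed graph per group: nodes are the acts involved in significant
# transitions (premating blue, mating red, postmating gray; border width
# scaled from act prevalence in the simulated sequence sets), edges are the
# significant transitions with pen width proportional to the transition
# percentage. Render with e.g. `dot -Tsvg results/ethogram_virgin_male.dot`.

suppressPackageStartupMessages(library(ethochain))
dir.create("results", showWarnings = FALSE)

for (grp in reference_groups()) {
  fx <- load_reference_table(grp)
  trials <- read_sequences(file.path("results", sprintf("sequences_%s.tsv", grp)))
  g <- build_graph(fx, prevalence = act_prevalence(trials),
                   repertoire = reference_repertoire(fx$sex))
  out <- file.path("results", sprintf("ethogram_%s.dot", grp))
  to_dot(g, path = out)
  cat(sprintf("%-14s %2d nodes, %2d edges -> %s\n", grp, nrow(g$nodes), nrow(g$edges), out))
}
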