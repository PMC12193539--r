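---
title: "First-order Markov transition analysis of mating-behavior sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-order Markov transition analysis of mating-behavior sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethochain)
```

## The model

Quantitative ethology describes a mating bout as an ordered sequence of
discrete behavioral acts drawn from a fixed repertoire. `ethochain`
analyzes such sequences under a first-order Markov assumption: the
probability of the next act depends only on the current act. The data
summary is the transition count matrix, where cell $O_{ab}$ counts how
often act $a$ is immediately followed by act $b$ across all trials of a
group (a trial being one couple's bioassay). Because consecutive repeats
of the same act are merged before counting (an act "followed by itself" is
just a longer occurrence), the diagonal is structurally zero.

Against the null hypothesis that antecedent and subsequent acts are
independent, each cell has expectation

$$E_{ab} = \frac{R_a \, C_b}{N},$$

with $R_a$ the row total, $C_b$ the column total, and $N$ the grand total
of transitions. The per-cell statistic is $\chi^2_{ab} = (O_{ab} -
E_{ab})^2 / E_{ab}$, and a transition is *significant* when $O_{ab} >
E_{ab}$ — the criterion used in the reference study, which every starred
cell of its four tables satisfies. The omnibus statistic is the sum of
$\chi^2_{ab}$ over significant cells, referred to a chi-square
distribution with $(r-1)(c-1)$ degrees of freedom, where $r$ counts
antecedent rows (acts with at least one outgoing transition) and $c$
subsequent columns; terminal acts occupy columns but need no row, so the
matrix need not be square. The transition percentage $T_{ab} = 100\,
O_{ab} / N$ drives the edge thickness of the kinematic diagrams.

Acts enter the matrix only if they occur in at least a fraction (default
10%) of the trials, comparing inclusively: 3 of 26 trials (11.5%) passes,
2 of 26 (7.7%) does not. "Occurrence" is per trial, not per event.

## Tunable conventions and their defaults

* `min_occurrence_fraction = 0.10` — the study's inclusion rule.
* `significance_rule = "obs_gt_exp"` — the study's criterion. A stricter
  variant, `"obs_gt_exp_and_cell_chi2"` (default threshold 3.84, the 0.95
  quantile of $\chi^2_1$), is provided because the bare criterion is
  anti-conservative for these matrices: the independence expectation
  spreads mass onto the structurally empty diagonal, so off-diagonal
  cells exceed expectation more than half the time even under a uniform
  chain. In a 500-replicate null simulation (5 acts, uniform transitions,
  20 trials of length 12) the bare rule flagged ~80% of off-diagonal
  cells while the chi-square-threshold rule stayed near 7%. The default
  nevertheless follows the published criterion; the stricter rule is an
  option, not a silent correction.
* `percentage_denominator = "all_transitions"` — $T$ is a share of the
  grand total $N$. This is the convention that reproduces every printed
  percentage in the reference tables (including the virgin-female table,
  whose margins count transitions that its starred cells do not).
* `expected_rounding = "unrounded"` — chi-square from exact $E$. The
  `"two_decimals"` compatibility mode truncates $E$ to 2 decimals first;
  some printed chi-square values (e.g. 267.8 from $E = 0.09$) are only
  reproducible that way.
* `alpha = 0.05`, two-sided everywhere.

## Phase segmentation

Each sequence is split into premating, mating and postmating phases by
sex-specific *marker transitions*, with the act at a phase-start marker
belonging to the new phase: for males, mating begins at the first
MEE→MIE (aedeagus insertion) and postmating at the first MM→MG
(guarding); for females, mating begins at the first FWK→FM and postmating
with whatever act follows the end of FQHM (a wildcard subsequent — the
source defines the female postmating boundary only as following FQHM,
and FQHM→FWP is the successor its tables show). Only the first occurrence
of a marker switches phase, so a female who throws the male off and is
re-courted stays in premating until the first successful insertion.
Phases therefore never regress along a sequence, and per-phase durations
sum exactly to the trial duration. Markers are configurable
(`phase_markers()`, JSON via `read_markers()`) so the machinery transfers
to other ethograms.

The repertoire's phase column is a *default* used for coloring graph
nodes; the authoritative phase of an occurrence always comes from the
markers.

## Group comparisons

Virgin vs once-mated proportions are compared with a two-proportion
z-test using the pooled standard error and, by default, a continuity
correction of $0.5(1/n_1 + 1/n_2)$. The correction is load-bearing: from
counts reconstructed from the published percentages (22/26 vs 8/15 and
9/26 vs 4/15, via `counts_from_percent()`, rounding ties away from zero),
the corrected statistics are 1.81 and 0.18, matching the printed 1.8 and
0.18, while the uncorrected values are 2.18 and 0.53. Without the
correction, $z^2$ equals the 2×2 Pearson chi-square exactly; with it, the
Yates-corrected chi-square (both identities are tested).

Duration summaries (mean, SEM, n) are compared with
`two_sample_t_from_summary()`, recovering $s^2 = \mathrm{sem}^2 n$. The
pooled-variance form is the default because the published df (39 = 26 +
15 − 2) is the pooled df. For the guarding durations the published t =
0.8 is internally inconsistent with its own df and p; the recomputed
statistics are pooled t = 2.30 (p = 0.027) and Welch t = 2.41 (p =
0.022, matching the printed p ≈ 0.02). The package reports the recomputed
values and documents the discrepancy rather than reproducing it.

## The reference fixtures and their quirks

The four published transition tables ship as plain-text fixtures
(`load_reference_table()`), with printed values kept verbatim as strings
because the source truncates to the printed decimals (3.488 prints as
3.48, 171.798 as 171.7, 1.667 as 1.6). Regression functions
(`expected_regression()`, `chi_square_regression()`) therefore compare at
a tolerance of one unit in the last printed digit plus 0.02.

Transcription choices, each forced by an internal inconsistency of the
printed tables:

* **Virgin-female margins.** The printed FW row (35), FMM column (29) and
  grand total (213) each exceed the starred-cell sums by exactly 13; a
  single unstarred FW→FMM = 13 transition reconciles all three and
  matches the narrative (about half of virgin females kept walking until
  intercepted by the male). The fixture includes this cell flagged
  `significant = FALSE, inferred = TRUE`, so margin conservation holds
  for all four fixtures.
* **Once-mated-female df.** The printed omnibus df (49) corresponds to an
  8×8 grid, while only 7 antecedent rows carry entries; the transcription
  includes the terminal act FWP as a structural zero row so the stored
  grid matches the printed df. The other three tables match their printed
  df (90, 120, 81) as printed.
* **Skip-listed cells.** Four virgin-male expected values (the 3.76
  triplet MEE→MIE, MIE→MM, MM→MG, whose margins give 2.83, and
  MWDF→MATFB, printed 3.95 where its margins give 3.49) and two printed
  chi-square values (MHAM→MW 26.14, a digit transposition of 26.41;
  MHFAR→MW 24.48, irreproducible from either rounding convention) are
  excluded from regression pass/fail but still reported. The printed
  virgin-female omnibus sum (1116.24) exceeds the sum of its listed cells
  (~1102); the recomputed sum is reported as is.

## The sequence simulator

`generator_spec()` defines a phase-structured semi-Markov chain: initial
distribution, transition probabilities with a zero diagonal (simulated
trials are born repeat-collapsed), per-act stopping probabilities, and
per-act duration models (constant, lognormal or gamma; default lognormal
with mean 10 s and log-sd 0.5). Stopping is modeled per act rather than
only through absorbing states because the reference margins imply partial
termination: 27 virgin-male sequences reach guarding but only 5 leave it,
so guarding ends a sequence with probability 22/27. Transition rows stay
probability-normalized conditional on continuing.

`spec_from_analysis()` derives a generator from an analysis or reference
table by row-normalizing observed counts. Initial probabilities come from
observed first acts when trials are available; for the fixtures (which
record only margins) they are imputed from net flow — an act left more
often than it is entered must start sequences. Durations in the shipped
presets are placeholders: the source reports no per-act duration data, so
nothing downstream treats simulated durations as estimates of real ones.

What the simulator emulates: sequence structure, branching probabilities,
terminal behavior, sample sizes (26 and 15 couples). What it does not:
real duration distributions, within-trial nonstationarity (courtship
phases plausibly change transition probabilities over time), between-
individual heterogeneity, and observer segmentation error. Passing
pipeline-closure tests on simulated data therefore validates the
arithmetic and the inference plumbing, not the ethological adequacy of
the first-order model for any particular species.

## Numerical choices and degenerate inputs

Ties in event start times are broken by input row order, then code
(determinism); point events get duration 0. Expected values are computed
in double precision with no rounding unless the compatibility mode is on;
equality in the significance rule is strict ($O = E$ is not significant).
Empty graphs are valid (with a warning); DOT output is deterministic,
with nodes and edges sorted lexicographically and pen widths mapped
affinely onto [0.5, 6.0] within each graph (the source states
proportionality but no scale; a within-graph affine map preserves the
stated monotonicity). Sequences hitting the simulator's `max_length`
safety bound (default 200) are flagged truncated. Seeds are explicit
arguments everywhere randomness enters.

## Problem sizes used by the checks

The test-suite simulations use 2,000 trials for law-of-large-numbers and
pipeline-closure checks (empirical transition frequencies within ±0.03 of
the generator's on rows with ≥100 visits; ≥95% of edges with conditional
probability ≥0.2 recovered as significant), 200 replicates of 20 trials
for the null false-positive-rate property, and ≤10 trials over ≤5 acts
for brute-force oracle equivalence. The analysis scripts run at the
study's own sample sizes (26 and 15 couples).

## Known limitations

No higher-order or stationarity analysis; no multiple-testing correction
(the reference analysis applies none, and the bare O > E criterion's
anti-conservatism is documented above rather than corrected); no fitting
of duration models to data; graph layout is delegated entirely to an
external DOT renderer.
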