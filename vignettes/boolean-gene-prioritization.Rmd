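---
title: "Boolean-framework gene prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean-framework gene prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolerank)
```

This vignette is the package's account of the science it implements:
the scoring model and its assumptions, the parameters that matter, what
the synthetic generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The prioritization model

The core idea is that no single functional attribute separates cancer
genes from the rest — kinases, transcription factors, hubs and
tissue-specific genes are all only mildly enriched — but their
*combinations* are informative. The package encodes each gene as a
7-bit Boolean pattern over (Meth, SP, PK, TS, PTM, TF, Hub) and scores
the pattern by root decomposition.

**Weights.** Each attribute's weight is its phi correlation with a
known-cancer-gene label, `r_phi = sqrt(chi2/N)` on the 2×2 table,
reported unsigned with the enrichment direction kept as metadata. The
chi-square statistic is uncorrected: phi and chi-square then satisfy the
exact identity `r_phi^2 * N = chi2`, which the test suite checks to
1e-10 on random tables. A zero margin (an attribute nobody or everybody
has, or a single-class label) makes phi undefined and is an explicit
error rather than a silent 0.

**Root decomposition.** A pattern with `k` set bits is decomposed into
its `2^k - 1` non-empty sub-patterns ("roots"). Each root's probability
is the *arithmetic mean* of its attributes' weights, and the gene score
is the sum over roots. Because each attribute appears in
`choose(k-1, j-1)` roots of size `j`, the sum collapses to
`((2^k - 1)/k) * sum(w[set bits])`. The implementation enumerates roots
(the defined semantics); tests verify the closed form on all 127
non-empty patterns at 1e-12. Two consequences worth knowing:

* the score grows roughly like `2^k/k` in the number of attributes, so
  pattern breadth dominates individual weights;
* adding an attribute does not always increase the score of a *root*
  (the mean dilutes), but the gene score is strictly increasing in every
  weight at fixed pattern.

**Bit order.** The published shortlist table prints 7-character Boolean
strings without naming which bit is which attribute. The package fixes
the order (Meth, SP, PK, TS, PTM, TF, Hub) and ships
`infer_attribute_order()`, which exhaustively searches all 5040
attribute-to-position assignments for those reproducing the published
scores of the four methylation-free patterns within 1e-4. Exactly two
assignments survive, differing only by swapping PK and TS — and every
published pattern sets PK and TS jointly, so the swap is unobservable.
The tests re-run this search.

**A documented discrepancy.** The two methylation-containing published
patterns (1011001 printed 0.697808, 1011010 printed 0.584684) do not
reproduce under the mean-root model with *any* attribute assignment
(computed 0.643031 and 0.552127 under the fixed order). The package
does not guess at the cause; `check_table2_scores()` reports computed
and printed values side by side with `reproduced = FALSE`. All six
distinct published patterns still clear the 0.5 shortlist cutoff either
way.

**Shortlisting** uses a strict inequality, `score > 0.5`. The cutoff is
an empirical convention — roughly twice the average Boolean score
reported for known cancer genes in earlier colorectal work — and is a
plain parameter of `shortlist()`.

## Rank-product differential expression

For unpaired tumor/normal data the package builds all
`K = n_tumor * n_normal` pairwise log2-ratio lists, ranks genes in each
(descending for up-regulation, ascending for down; ties averaged), and
computes `RP = prod_i(r_i / n)`. Internally everything is done in log
space, so `RP` values around `1e-300` at `K = 100` lists are not a
problem.

**The pfp null.** The percentage of false prediction is
`pfp(g) = E[#null RP <= RP(g)] / rank(g)`, an FDR-type quantity. The
open design question was what "null" means. Permuting ranks
independently within each ratio list looks natural but is wrong here:
the K lists share samples (every list reuses one tumor and one normal
column), so a gene's ranks are strongly correlated across lists, and an
independent-rank null makes the observed null RP distribution far wider
than the reference — on simulated null data about 40% of genes get
called at pfp ≤ 0.05. The package instead permutes gene labels within
each *sample column* and re-derives all rank lists per permutation.
That preserves the inter-list correlation, and the false-call rate on
null data drops to the nominal level (the acceptance tests measure
this). The cost is `n_perm` full re-rankings; `n_perm = 100` (the
default) handles 1,000 genes × 100 lists in a few seconds.

Genes significant in both directions at once (possible with few lists)
are resolved to the direction with the smaller RP and flagged in a
`both_directions` column.

**What power to expect.** With the default simulation conditions
(1,000 genes, 10 vs 10 samples, 2-log2-unit shifts, unit noise, 5%
planted per direction), the recovery rate of planted genes at
pfp ≤ 0.05 sits in the high 80s to low 90s percent depending on the
seed. That is intrinsic to the conditions, not estimator slack: around
rank 45–50 of 50 planted genes the *true* false-discovery proportion
itself crosses 5%, so a calibrated method cannot call materially more.

## Interactome and network stages

The four high-confidence evidence rules (≥ 2 databases, ≥ 2
detection-method classes, domain–domain support, ≥ 2 PMIDs) are
combined **disjunctively**: they read as parallel sufficient criteria,
and OR maximizes coverage while the per-rule provenance columns let a
stricter user re-filter conjunctively. Hub status is degree ≥ 5 in the
filtered network (strictly: a degree-4 node is not a hub), and feeds the
Hub attribute bit.

Co-expression edges require Pearson r strictly greater than 0.5,
*signed* — strong anti-correlation is not a link. Zero-variance genes
are excluded with a warning rather than producing NaN correlations.

Centralities: betweenness uses unweighted, undirected shortest paths
with raw pair counts (no normalization), so a star centre over `m`
leaves scores `choose(m, 2)`; eigenvector centrality is computed per
connected component as the principal eigenvector of the component's
adjacency matrix via a dense symmetric eigendecomposition — chosen over
iterative/ARPACK routines because it is bit-reproducible, which the
pipeline's determinism contract requires — scaled to max 1 within the
component. The node-importance measure is the residual of the OLS fit
of betweenness on eigenvector centrality; residuals sum to zero by
construction and vanish when the two centralities are collinear.

## Clinical layer

The signature score of a sample is the plain sum of its up-gene
expression minus the sum of its down-gene expression, on whatever scale
the input carries (recorded in the output's `scale` attribute; the
published analysis does not state linear vs log for this step).
Signature genes missing from a cohort are skipped with a warning, since
validation platforms often lack probes for a few genes. Group contrasts
use the Welch unequal-variance t-test.

Survival stratification ranks samples by a score, labels the lower 50%
"low" (odd middle sample goes to "low"; ties broken by sample ID for
determinism), and compares groups with the Cox–Mantel log-rank test
(chi-square, 1 df, hypergeometric variance with simultaneous risk-set
handling of ties). The package deliberately applies **no**
multiple-testing correction across per-gene log-rank tests and uses the
less conservative alpha = 0.1 downstream, matching the published
small-cohort convention; with 17 genes tested, users should treat
single-gene survival hits as hypothesis-generating. The combined
three-gene score CHEK1 + AR − LYN is a first-class operation
(`combined_score()`) followed by the same median-split/log-rank path.

## Synthetic data: what it does and does not emulate

The generators exist so every stage is testable without external data:

* `sim_expression()` — log2-Gaussian two-class expression (baselines
  uniform on 6–12, per-gene noise SD 1 by default), planted ±2-log2
  shifts in 5% + 5% of genes, exported on the linear scale to exercise
  the log2 preprocessing path. Defaults mirror a small two-class tumor
  study (10 vs 10 samples, 1,000 genes).
* `sim_attributes()` — attributes are independent Bernoulli draws given
  the class label, so the population phi is known in closed form
  (`analytic_phi()`); default prevalences are mildly enriched in the
  cancer class, in the single-digit-phi regime the weight table lives
  in.
* `sim_interactions()` — uniform random distinct pairs with evidence
  counts `1 + Binomial(2, p)` per field, making each HC rule's firing
  rate `1 - (1-p)^2`, testable against binomial error.
* `sim_clinical()` — exponential event times with a group hazard ratio
  and independent exponential censoring calibrated to a target
  censoring fraction.

Not emulated, by design: array-platform normalization artifacts,
probe-level structure beyond the probe-collapse fixtures, correlated
attributes (real functional attributes co-occur; phi weighting is
marginal either way), gene–gene expression correlation outside planted
blocks, and non-proportional hazards. Passing tests on this synthetic
family therefore demonstrates correctness of the computations and
calibration of the statistics under clean assumptions — not robustness
to the messiness of real cohorts.

## Numerical and testing choices

* Published-score comparisons use tolerance 1e-4: the packaged weights
  are printed at 6 decimal places, so reconstructed scores carry ~3e-6
  rounding already, and the upstream computation's precision is
  unknown.
* Closed-form vs enumeration identities are asserted at 1e-12; the
  phi/chi-square identity at 1e-10.
* Simulation-based checks fix seeds and use 3-sigma binomial Monte-Carlo
  bands. Problem sizes (1,000 genes for calibration/power, 10,000 genes
  for phi recovery, 100 replicates for survival power, 10,000
  label permutations for the log-rank oracle) keep the full suite
  around a minute while leaving the Monte-Carlo bands meaningful.
* The log-rank permutation oracle is compared loosely (±0.15): the
  chi-square reference is asymptotic and an 8-sample fixture is
  deliberately far from asymptopia.

## Known limitations

* The two methylation-containing published scores cannot be reproduced
  under the stated scoring model (above); the package reports, and does
  not resolve, the discrepancy.
* The external 17-gene × 45-sample validation cohort used for the
  published Welch t contrast is third-party supplementary data and is
  not shipped; the corresponding check runs only when a user supplies
  the table under `inst/extdata/validation_cohort_expression.tsv`.
* `N` in the published weight table is not recoverable from the printed
  values (back-solving gives inconsistent 5,800–6,700), so the weights
  are treated as input data, not re-derived.
* Dense eigendecomposition for eigenvector centrality is `O(n^3)` per
  component; fine for the few-thousand-node signalling networks this
  package targets, not for genome-scale graphs.
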