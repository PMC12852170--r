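---
title: "Methods: injured-state markers, gene-set scores, spatial proximity and outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: injured-state markers, gene-set scores, spatial proximity and outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurystates)
```

This vignette is the package's own account of its methods: the statistical
procedures, the tunable parameters and why their defaults are what they are,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices made where the underlying procedure left room.

## Differential expression

`lognormalize()` maps counts to `ln(1 + scale * count / depth)` with
`scale = 10,000` (the single-cell convention; the transform is reversible via
`expm1`, zeros stay zeros). `wilcoxon_de()` runs a two-sided Wilcoxon
rank-sum test per gene between two disjoint cell sets on these values.

* **P-values.** A tie-corrected normal approximation is used in general;
  when the smaller group has at most 8 cells *and* the number of group
  assignments is enumerable (≤ 200,000), the exact two-sided permutation
  p-value is computed by full enumeration. Unconditional enumeration is
  infeasible when the other group is large, so exactness is targeted at the
  regime where the normal approximation is actually poor. No continuity
  correction is applied; on tied large-sample data the result matches
  `wilcox.test(exact = FALSE, correct = FALSE)` to machine precision.
* **Fold-changes.** `log2FC = log2((mean(expm1 A) + 1) / (mean(expm1 B) + 1))`
  — back-transformed means with pseudocount 1. The convention of the popular
  single-cell tools changed across versions; this variant is fixed and
  documented, and its consequences are testable: scaling one group by 2^k
  shifts log2FC by slightly less than k for weakly expressed genes (the
  pseudocount damps the shift) and by k in the limit of high expression.
* **Filters.** `apply_de_filters()` keeps genes with |log2FC| > 1, adjusted
  p < 0.05, and ≥ 10 % expressing cells, where the fraction is evaluated in
  the group in which the gene is *up* (selectable). The BH family is all
  genes tested in one call, matching per-cell-type testing.

## The marker-specificity algorithm

Given a target injured population (TP) and its adjacent injury population
(the nearest other injury state of the same cell type), `select_markers()`
runs four steps:

1. **Candidates** — DE of TP against all other cells; upregulated genes
   passing the standard filters. The candidate step reuses the group-level DE
   thresholds; the procedure's description leaves this open and reusing them
   is the parsimonious reading.
2. **Adjacent filter** — keep genes whose mean back-transformed expression in
   TP strictly exceeds the adjacent population's mean. A tie drops the gene.
3. **Neighborhoods** — PCA of the log-normalized matrix (default 30
   components, centered, unscaled), then for every cell *not* in TP its
   k = 100 nearest cells (Euclidean in the embedding, seed included, ties
   broken by ascending cell id). Any neighborhood containing ≥ 1 TP member is
   excluded.
4. **Specificity** — keep gene *g* iff
   `mean_TP(g) > 1.25 × max_n mean_n(g)` over the retained neighborhoods *n*
   (strictest reading of "greater than 1.25-fold compared to all other
   neighborhoods"; comparison against the mean of neighborhood means is
   available via `neighborhood_stat = "mean"`). Output is ordered by the
   TP-mean / max-neighborhood-mean ratio, and every gene carries an audit row.

The embedding is the major interpretive decision: the neighborhoods are
defined on cells that have no spatial coordinates, so expression-space kNN
(PCA of the log-normalized matrix) is the only coherent reading; the
dimensionality (30) matches standard single-cell practice. The seed cell
counts toward the 100, and "overlap" means at least one TP member. All three
choices are configurable in `marker_query()`.

The neighborhood construction is exactly reproducible by brute force (full
pairwise distances plus explicit means); the test suite verifies equality on
random cohorts, including the overlap flags and the final marker sets. If
every neighborhood overlaps TP the filter refuses with advice to lower k
rather than silently returning an unfiltered set.

## Gene-set scores in bulk cohorts

`score_samples()` computes, per set and sample, the arithmetic mean of log2
expression over the set's genes — identically log2 of the geometric mean of
the linear intensities — minus the mean of that quantity over the control
(nephrectomy) samples. Controls therefore average exactly 0 per set
(enforced to 1e-9 in tests); scores are in log2-fold units relative to
control. Microarray-like values are strictly positive, so no pseudocount is
needed. Duplicate genes are de-duplicated; genes absent from the expression
table are dropped with a reported coverage fraction, and a set below 50 %
coverage is refused rather than silently rescored. Probe-level tables are
collapsed to genes by the arithmetic mean of each gene's probes
(`probe_collapse()`).

`median_stratify()` splits at the median of the **full** scored cohort (all
diagnoses jointly, controls excluded); strata are then crossed with diagnosis
downstream, so a diagnosis subgroup need not split in half. Ties at the
median go *below* — a deterministic rule that only matters for exact ties.

`survival_by_score()` selects each patient's first biopsy, censors
administratively at 36 months (3-year graft-loss horizon; configurable),
tests above- vs below-median within the test diagnosis (TCMR by default) by
log-rank, and BH-adjusts across the gene sets of the call. Kaplan–Meier and
log-rank go through the survival package (`survfit`/`survdiff`), with
hand-computed product-limit and single-event-time values as the test oracle.
Compact letters summarising which strata are mutually non-different are
assigned greedily from pairwise log-rank tests at fdr 0.05 within each set —
the display convention shows letters but no algorithm, so the greedy
insert-absorb scheme is fixed here.

`longitudinal_trajectories()` restricts to patients whose first biopsy
carries the index diagnosis (TCMR), who have follow-up biopsies, and whose
final biopsy is no-rejection, then returns ordered per-patient score series.

## Spatial proximity

For one sample, `cooccurrence_curve()` computes at each grid distance d the
fraction of query-type cells among all cells within ≤ d (cumulative) of any
anchor cell, divided by the query type's marginal fraction. Distances are
Euclidean on centroids in µm; a cell is never its own neighbor, but anchor
cells do count as potential neighbors of *other* anchors (the alternative —
dropping anchors from the pool — is behind `include_anchors = FALSE`, and
per-ring counting behind `per_ring = TRUE`; cumulative ≤ d is the default
because the direct-neighbor definition, ≤ 25 µm, is itself cumulative).
`direct_neighbor_test()` takes the per-sample ratio at 25 µm in the tested
group (the rejecting/allogeneic samples by default), applies a two-sided
one-sample t-test against ratio 1 per (anchor, query) pair and BH across all
pairs of the call. Pairs with fewer than two finite per-sample ratios are
reported untested with a reason rather than dropped.

## The synthetic-data generators

All randomness flows from one root seed through named substreams (`cells`,
`spatial:<sample>`, `bulk`), so each data class regenerates identically and
independently of the others. The defaults are the study conditions the
acceptance checks run under; they were chosen once, from the designs the
pipeline targets, and are not tuned.

**Cell cohorts** (`simulate_cell_cohort()`): negative-binomial counts with a
gene-wise log-normal baseline shared across populations and a single shared
dispersion (`nb_dispersion = 0.5`, i.e. variance µ + 0.5 µ²) — the simplest
model with single-nucleus-like overdispersion. Depths are log-uniform on
2,000–10,000 counts; depth and dispersion are conventional defaults because
sequencing-depth characteristics are rarely reported. Eight populations
emulate a rejecting-kidney mix (healthy PT/TAL, a target and an adjacent
injured PT state, injured TAL, macrophages, T cells, endothelium); planted
markers are the *only* population-distinguishing genes (20 genes at linear
fold 4 for the target state, 30 at fold 3 elsewhere), sit on a fixed
mid-range baseline so the fold is visible above shot noise, and are the
recorded ground truth. Injury and leukocyte populations are drawn 85 % from
the allogeneic group, giving the composition tests a real signal.

**Spatial samples** (`simulate_spatial_sample()`): homogeneous Poisson
background at 0.002 cells/µm² (≈ 2,000 cells/mm², typical of kidney tissue)
over a square field. For a pair with enrichment ρ ≠ 1 the query type is
placed in or out of the union U of 25-µm discs around the anchors with
probability `pi = rho * m / (N − rho * n_B)`, where m is the exactly counted
number of non-query cells in U (anchor self-pairs excluded): the expected
direct-neighbor ratio at the niche radius then equals ρ *by construction*,
which makes the calibration directly testable (ρ = 2 is recovered within
±0.01 at 20,000 cells). ρ < 1 thins the query type out of U; ρ = 0 excludes
it. Enrichment is defined operationally as the value of the statistic under
test, not as a Gibbs interaction. Two consequences to know about: the
per-sample ratio at the niche radius has deliberately small variance (the
in-U count is rounded, not binomial), and planting B near A *dilutes* other
types in the anchor neighborhoods — a real compositional effect, visible as
mild apparent depletion of unplanted types. ρ must satisfy
`rho * m / (N − rho * n_B) ≤ 1`; at the default composition this caps ρ
around 3.

**Bulk cohorts** (`simulate_bulk_cohort()`): gene-wise baselines N(8, 1.5²)
log2 units with residual noise sd 0.2 (microarray-like), one latent N(0, 1)
score per sample and set shifting that set's genes additively, controls at
score 0. Graft-loss times are exponential with
`log hazard = log(rate0) + beta * u`; `beta` is derived from the configured
hazard ratio between above- and below-median strata via
`beta = qnorm(HR / (1 + HR))` (exact for a standard-normal score, since the
mean relative hazard above vs below the median is Φ(β)/Φ(−β)), and `rate0`
is solved numerically so the expected pre-horizon event fraction is 0.40.
Censoring is administrative at 36 months. Twelve TCMR-index patients receive
two follow-up biopsies resolving to NR with the index score persisting,
mirroring the persistence analysis. Diagnoses are drawn NR/TCMR/ABMR/Mixed at
0.50/0.25/0.15/0.10.

What the generators do **not** emulate: transcriptome-wide co-expression
structure, doublets and ambient RNA, batch effects, image-level spatial
artefacts (segmentation errors, transcript spots), informative censoring,
and diagnosis-dependent score distributions unless configured. Passing tests
on this synthetic data therefore demonstrate that the algorithms recover
what they are defined to recover under their stated model — not that the
model captures every property of real tissue.

## Composition and concordance statistics

`composition_ttests()` runs pooled-variance Student's t per cell type
(Welch behind `var_equal = FALSE`), BH across types; zero-variance types are
reported with t = 0, p = 1 and flagged. `arcsin_moderated_ttest()` transforms
proportions by `asin(sqrt(p))` and shrinks each type's pooled variance toward
a prior estimated across types by method of moments on the scaled-F marginal
of the variances (moderated df = residual + prior df). It is a deliberately
simple empirical-Bayes scheme, not a re-implementation of any package's
internals; its testable contracts are the limiting cases (`prior_df = 0`
gives the ordinary t exactly; `prior_df = Inf` uses the prior variance alone)
and null calibration on Dirichlet compositions. `log2fc_concordance()` takes
the union of the top-500 increased and top-500 decreased genes of the
reference dataset, intersects with the comparison dataset and reports
Spearman's ρ (≥ 10 shared genes required).

## Numerical choices and problem sizes

Tie-breaks are deterministic everywhere (kNN by ascending cell id, median
ties below, marker ordering by ratio then gene id), so a fixed seed yields
byte-identical pipeline outputs — verified end-to-end by checksum in the test
suite. The distance boundary is inclusive (24.9 µm is a direct neighbor at
threshold 25, 25.1 µm is not). The test and acceptance runs use: one
5,000-cell × 2,000-gene cohort for marker recovery; 20 cohorts ≤ 500 cells
and 50 spatial patterns ≤ 2,000 cells for brute-force equivalence; one
~20,000-cell field for spatial calibration plus 200 four-sample CSR
replicates for test size; 100 cohorts of n = 300 (40 % events, HR 2.5) for
log-rank power and 200 null cohorts for fdr calibration — sizes at which
every targeted property is measurable with comfortable margins.

## Known limitations

The Wilcoxon exact path is bounded by enumerability; very unbalanced small
groups fall back to the normal approximation. The compact-letter assignment
is greedy and can produce redundant letter groups on pathological test
patterns. The spatial simulator calibrates one pair per query type per
sample; overlapping enrichment structures interact and only the single-pair
case is guaranteed. Cox regression and multivariable adjustment are out of
scope; the survival analysis is the descriptive KM / log-rank design.
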