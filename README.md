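# injurystates

Injured tubular-epithelial cell states — dedifferentiated, VCAM1/HAVCR1-like
subpopulations of proximal tubule (PT) and thick ascending limb (TAL) cells —
appear during kidney-allograft rejection and predict graft outcome. This
package implements the quantitative pipeline that links those states to
outcome, for analysts working with single-nucleus RNA-seq, Xenium-style
segmented-cell spatial data, and bulk (microarray-like) transplant-biopsy
cohorts:

1. **Differential expression** per cell type: two-sided Wilcoxon rank-sum
   tests on log-normalized expression with Benjamini–Hochberg correction and
   the study filters |log2FC| > 1, adjusted p < 0.05, and ≥ 10 % expressing
   cells in the upregulated group.
2. **Marker-specificity algorithm** for a target injured population TP:
   (i) candidate genes from DE of TP vs all other cells; (ii) keep genes with
   higher mean expression in TP than in the adjacent injury population;
   (iii) build 100-cell nearest-neighbor neighborhoods (PCA space) around
   every non-TP cell and drop neighborhoods overlapping TP; (iv) keep gene
   *g* iff mean<sub>TP</sub>(g) > 1.25 × max over retained neighborhoods of
   the neighborhood mean.
3. **Gene-set scoring of bulk cohorts**: per sample,
   score = mean log2 expression over marker genes − the same quantity
   averaged over nephrectomy controls (the log2 geometric-mean convention;
   controls average exactly 0), with full-cohort **median-split**
   stratification, Kaplan–Meier curves, within-diagnosis log-rank tests and
   fdr across gene sets, and longitudinal trajectories for TCMR patients
   resolving to no rejection.
4. **Spatial proximity**: co-occurrence ratio
   r(d) = P(type B | within ≤ d of a type-A cell) / P(type B) on centroid
   distances, evaluated on a 5–50 µm grid; a cell within ≤ 25 µm is a direct
   neighbor, and per-pair enrichment is tested across samples with a
   two-sided one-sample t-test against ratio 1, BH-corrected.
5. **Cohort statistics**: composition comparisons (Student's t and
   arcsine-transformed empirical-Bayes moderated t), and cross-dataset
   log2FC concordance (Spearman on the union of top-500 increased and
   top-500 decreased genes).
6. **Synthetic-data generators** for all three input classes with planted,
   recoverable ground truth: clustered negative-binomial counts with planted
   marker fold-changes, spatial point patterns whose direct-neighbor ratio is
   calibrated to a target ρ, and bulk cohorts whose graft-loss hazard depends
   on a latent gene-set score. One root seed drives everything through named
   substreams.

All user-facing functions take and return tibbles (or light S3 containers
with `tidy()`/`glance()`/`autoplot()` methods), so results drop straight into
dplyr/ggplot2 workflows.

## Worked example

```r
library(injurystates)

cfg <- sim_config(seed = 7)                      # 5,000 cells x 2,000 genes
sim <- simulate_cell_cohort(cfg)
sim$cohort
#> <cell_cohort> 5000 cells x 2000 genes; 8 clusters, 6 samples, groups: allogeneic/syngeneic

ms <- select_markers(sim$cohort, marker_query("PT_Injury_2", "PT_Injury_1"))
ms
#> <marker_set> PT_Injury_2: 20 genes (fold threshold 1.25, k = 100)
#>   g0077, g0078, g0064, g0075, g0076, g0074, g0079, g0070, g0073, g0066, ...
```

The 20 selected genes are exactly the 20 markers planted for the target
injury population (`sim$truth$planted_markers`). Scoring a simulated bulk
cohort with this set and stratifying at the full-cohort median:

```r
bulk <- simulate_bulk_cohort(cfg, list(ms))
sc   <- score_samples(bulk$cohort, list(ms))
tidy(survival_by_score(bulk$cohort, sc))
#> # A tibble: 1 × 8
#>   set         n_above n_below statistic p_value tested reason     fdr
#> 1 PT_Injury_2      43      38      7.72 0.00547 TRUE   <NA>   0.00547
```

TCMR patients above the median marker score lose their grafts significantly
faster than those below (log-rank chi-square 7.7, fdr 0.005 at the simulated
hazard ratio of 2.5). Spatial co-localization of the injured state with
leukocytes:

```r
cells <- dplyr::bind_rows(lapply(1:5, function(i)
  simulate_spatial_sample(cfg, paste0("s", i))$cells))
direct_neighbor_test(cells, tibble::tibble(
  anchor = "PT_Injury", query = c("Macrophage", "T_cell")))
#>   anchor    query      n_samples mean_ratio statistic  p_value     padj direction
#> 1 PT_Injury Macrophage         5      2.00    3939.   2.49e-14 4.98e-14 enrichment
#> 2 PT_Injury T_cell             5      0.884     -7.30 1.87e- 3 1.87e- 3 depletion
```

Macrophages sit near injured PT cells at twice the rate expected under
spatial randomness (the planted ρ = 2); T cells, placed at random, are
slightly diluted out of the crowded anchor neighborhoods.

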