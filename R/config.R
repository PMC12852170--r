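#' Default cell populations for the single-nucleus simulator
#'
#' Eight populations emulating a transplant-kidney nephrectomy/biopsy mix:
#' healthy proximal tubule (PT) and thick ascending limb (TAL), a target
#' injured PT state, the adjacent injured PT state used as the specificity
#' contrast, an injured TAL state, two leukocyte populations and endothelium.
#' `group_bias` is the probability that a cell of the population comes from
#' the allogeneic (rejecting) group; injury and leukocyte populations are
#' strongly enriched there.
#'
#' @return A tibble with columns `name`, `proportion`, `role`, `group_bias`.
#' @export
default_populations <- function() {
  tibble(
    name = c("PT", "TAL", "PT_Injury_2", "PT_Injury_1",
             "TAL_Injury", "Macrophage", "T_cell", "Endothelial"),
    proportion = c(0.30, 0.15, 0.10, 0.10, 0.08, 0.10, 0.09, 0.08),
    role = c("healthy", "healthy", "target_injury", "adjacent_injury",
             "other", "leukocyte", "leukocyte", "other"),
    group_bias = c(0.35, 0.35, 0.85, 0.85, 0.85, 0.85, 0.85, 0.50)
  )
}

#' Default planted marker table
#'
#' Assigns disjoint blocks of gene indices as upregulated markers: 20 genes at
#' linear fold 4 for the target injury population and 20-30 genes at fold 3
#' for every other population, so that populations are separable in expression
#' space and every planted effect is recoverable from the counts.
#'
#' @param populations Population tibble (see [default_populations()]).
#' @param n_target Number of target-population markers (default 20).
#' @param fold_target Linear fold-change of target markers (default 4).
#' @param n_other,fold_other Block size and fold for the remaining populations.
#' @return A tibble with columns `population`, `gene`, `fold`.
#' @export
default_planted_markers <- function(populations = default_populations(),
                                    n_target = 20, fold_target = 4,
                                    n_other = 30, fold_other = 3) {
  idx <- 1L
  out <- vector("list", nrow(populations))
  for (i in seq_len(nrow(populations))) {
    n_i <- if (populations$role[i] == "target_injury") n_target else n_other
    f_i <- if (populations$role[i] == "target_injury") fold_target else fold_other
    out[[i]] <- tibble(
      population = populations$name[i],
      gene = seq.int(idx, idx + n_i - 1L),
      fold = f_i
    )
    idx <- idx + n_i
  }
  bind_rows(out)
}

#' Default spatial-sample settings
#'
#' A Xenium-like segmented-cell field: homogeneous background at the given
#' density, with selected (anchor, query) type pairs co-localized so that the
#' expected direct-neighbor co-occurrence ratio at the niche radius equals
#' `rho` (`rho > 1` enrichment, `rho < 1` depletion, `rho = 1` complete
#' spatial randomness).
#'
#' @param field_size_um Side length of the square field in micrometers.
#' @param density_cells_per_um2 Expected cell density (cells / square um).
#' @param niche_radius_um Radius at which `rho` is calibrated; also the
#'   direct-neighbor distance used downstream.
#' @param cell_types Tibble `type`, `proportion` of marginal type frequencies.
#' @param pairs Tibble `anchor`, `query`, `rho`; each query type may appear in
#'   at most one pair.
#' @return A list of class `spatial_config`.
#' @export
spatial_config <- function(field_size_um = 2000,
                           density_cells_per_um2 = 0.002,
                           niche_radius_um = 25,
                           cell_types = tibble(
                             type = c("Epithelial", "PT_Injury", "Macrophage",
                                      "T_cell", "Stroma"),
                             proportion = c(0.50, 0.08, 0.12, 0.08, 0.22)
                           ),
                           pairs = tibble(anchor = "PT_Injury",
                                          query = "Macrophage",
                                          rho = 2)) {
  assert_that(all(pairs$rho >= 0), "spatial enrichment rho must be >= 0")
  assert_that(abs(sum(cell_types$proportion) - 1) < 1e-8,
              "spatial cell-type proportions must sum to 1")
  assert_that(!anyDuplicated(pairs$query),
              "each query type may appear in at most one spatial pair")
  structure(list(field_size_um = field_size_um,
                 density_cells_per_um2 = density_cells_per_um2,
                 niche_radius_um = niche_radius_um,
                 cell_types = cell_types, pairs = pairs),
            class = "spatial_config")
}

#' Default bulk-cohort settings
#'
#' Emulates a microarray transplant-biopsy cohort with nephrectomy controls:
#' log2 expression with gene-wise baselines, per-sample latent gene-set scores
#' that shift marker-gene expression, and exponential graft-loss times whose
#' hazard rises with the score. The survival effect is parameterised as the
#' hazard ratio between samples above vs below the median score; the baseline
#' rate is solved so that the expected pre-horizon event fraction matches
#' `event_fraction`.
#'
#' @param n_samples Number of case biopsies.
#' @param n_controls Number of nephrectomy control biopsies (default 4).
#' @param score_sd Standard deviation of the latent per-sample score.
#' @param diagnosis_shift Named additive score shift per diagnosis.
#' @param fixed_score If non-NULL, every case sample gets exactly this latent
#'   score (used to plant a uniform known elevation).
#' @param hazard_ratio Target hazard ratio between above- and below-median
#'   score strata (applied to the first marker set; others get no effect
#'   unless `beta` is supplied per set downstream).
#' @param event_fraction Expected fraction of graft losses before the horizon.
#' @param horizon_months Administrative censoring horizon (months).
#' @param diagnosis_probs Marginal probabilities of the four MMDx diagnoses.
#' @param n_followup Number of TCMR-index patients given two follow-up
#'   biopsies resolving to no-rejection, with the index score persisting.
#' @param noise_sd Residual log2 noise per gene and sample.
#' @return A list of class `bulk_config`.
#' @export
bulk_config <- function(n_samples = 300, n_controls = 4,
                        score_sd = 1,
                        diagnosis_shift = c(NR = 0, TCMR = 0, ABMR = 0, Mixed = 0),
                        fixed_score = NULL,
                        hazard_ratio = 2.5,
                        event_fraction = 0.40,
                        horizon_months = 36,
                        diagnosis_probs = c(NR = 0.50, TCMR = 0.25,
                                            ABMR = 0.15, Mixed = 0.10),
                        n_followup = 12,
                        noise_sd = 0.2) {
  assert_that(n_controls >= 1, "need at least one control sample")
  assert_that(abs(sum(diagnosis_probs) - 1) < 1e-8,
              "diagnosis probabilities must sum to 1")
  structure(list(n_samples = n_samples, n_controls = n_controls,
                 score_sd = score_sd, diagnosis_shift = diagnosis_shift,
                 fixed_score = fixed_score, hazard_ratio = hazard_ratio,
                 event_fraction = event_fraction,
                 horizon_months = horizon_months,
                 diagnosis_probs = diagnosis_probs,
                 n_followup = n_followup, noise_sd = noise_sd),
            class = "bulk_config")
}

#' Simulation configuration
#'
#' One object drives all three generators ([simulate_cell_cohort()],
#' [simulate_spatial_sample()], [simulate_bulk_cohort()]). All randomness
#' derives from `seed` through named substreams, so the three data classes can
#' be regenerated independently and reproducibly.
#'
#' @param seed Root seed (integer).
#' @param n_genes,n_cells Dimensions of the single-cell count matrix.
#' @param populations Tibble `name`, `proportion`, `role`, `group_bias`.
#' @param planted_markers Tibble `population`, `gene` (index), `fold`
#'   (linear fold >= 1).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2), shared across genes.
#' @param library_size_range Min/max per-cell depth; depths are drawn
#'   log-uniformly over this range.
#' @param n_samples_per_group Biological replicates per group for the cell
#'   cohort.
#' @param groups Two group labels (control group first).
#' @param spatial A [spatial_config()].
#' @param bulk A [bulk_config()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L, n_cells = 5000L,
                       populations = default_populations(),
                       planted_markers = default_planted_markers(populations),
                       nb_dispersion = 0.5,
                       library_size_range = c(2000, 10000),
                       n_samples_per_group = 3L,
                       groups = c("syngeneic", "allogeneic"),
                       spatial = spatial_config(),
                       bulk = bulk_config()) {
  assert_that(abs(sum(populations$proportion) - 1) < 1e-8,
              "population proportions must sum to 1")
  assert_that(all(planted_markers$fold >= 1),
              "planted marker fold-changes must be >= 1")
  assert_that(all(planted_markers$gene >= 1 & planted_markers$gene <= n_genes),
              "planted marker gene indices must lie in 1..n_genes")
  assert_that(all(planted_markers$population %in% populations$name),
              "planted markers reference unknown populations")
  assert_that(nb_dispersion > 0, "nb_dispersion must be positive")
  assert_that(length(groups) == 2L, "exactly two groups are supported")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_cells = as.integer(n_cells), populations = populations,
                 planted_markers = planted_markers,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 groups = groups, spatial = spatial, bulk = bulk),
            class = "sim_config")
}

gene_names <- function(n) sprintf("g%04d", seq_len(n))
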