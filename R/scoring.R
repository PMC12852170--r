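#' Score bulk samples against marker gene sets
#'
#' Per set, the raw score of a sample is the mean log2 expression over the
#' set's genes (equivalently, log2 of the geometric mean of the linear
#' intensities); the final score subtracts the mean raw score over the
#' control samples, so scores are in log2 units relative to control and the
#' mean score over controls is exactly 0 per set. Duplicate gene entries
#' within a set are de-duplicated; genes missing from the expression table
#' are dropped with a reported coverage fraction, and a set is refused when
#' coverage falls below `min_coverage`.
#'
#' @param cohort A [bulk_cohort()].
#' @param sets Named list of gene-id vectors or `marker_set` objects.
#' @param min_coverage Minimum fraction of set genes that must be present
#'   (default 0.5).
#' @return A tibble `sample`, `set`, `score`, `coverage`, `n_genes_used`,
#'   `is_control`.
#' @export
score_samples <- function(cohort, sets, min_coverage = 0.5) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  sets <- as_gene_sets(sets)
  assert_that(length(cohort$controls) >= 1, "need at least one control sample")
  expr <- cohort$expression
  ctrl <- cohort$controls

  purrr::map_dfr(names(sets), function(nm) {
    genes <- unique(sets[[nm]])
    assert_that(length(genes) > 0, paste("empty marker set:", nm))
    present <- intersect(genes, rownames(expr))
    coverage <- length(present) / length(genes)
    if (length(present) == 0) {
      abort(paste0("marker set '", nm, "' has no genes in the expression table"))
    }
    if (coverage < min_coverage) {
      abort(sprintf(
        "marker set '%s' coverage %.0f%% is below the required %.0f%%",
        nm, 100 * coverage, 100 * min_coverage))
    }
    if (coverage < 1) {
      inform(sprintf("marker set '%s': %d/%d genes matched (%.0f%% coverage)",
                     nm, length(present), length(genes), 100 * coverage))
    }
    raw <- colMeans(expr[present, , drop = FALSE])
    score <- raw - mean(raw[ctrl])
    tibble(sample = colnames(expr), set = nm, score = unname(score),
           coverage = coverage, n_genes_used = length(present),
           is_control = colnames(expr) %in% ctrl)
  })
}

#' Median stratification of gene-set scores
#'
#' Splits samples at the median score of the full (non-control) cohort, all
#' diagnoses jointly: samples strictly above the median are `"above"`, ties
#' at the median go `"below"`. The strata can then be crossed with diagnosis
#' downstream.
#'
#' @param scores A [score_samples()] result.
#' @param cohort The [bulk_cohort()] the scores came from (used to exclude
#'   controls from the median); NULL uses the `is_control` column.
#' @param set_name Set to stratify; default all sets in `scores`.
#' @return `scores` (controls dropped) with added columns `median_score`,
#'   `stratum`.
#' @export
median_stratify <- function(scores, cohort = NULL, set_name = NULL) {
  ctrl <- if (!is.null(cohort)) cohort$controls else
    unique(scores$sample[scores$is_control])
  sc <- filter(scores, !.data$sample %in% ctrl)
  if (!is.null(set_name)) sc <- filter(sc, .data$set %in% set_name)
  assert_that(nrow(sc) >= 2, "need at least two scored non-control samples")
  sc |>
    group_by(.data$set) |>
    mutate(median_score = median(.data$score),
           stratum = ifelse(.data$score > .data$median_score,
                            "above", "below")) |>
    ungroup()
}

#' Collapse probe-level expression to gene level
#'
#' Per gene, the arithmetic mean of its probes' log2 values. Unmapped probes
#' are dropped with a reported count; a probe mapped to several genes
#' contributes to each (with a warning).
#'
#' @param expression Tibble whose first column holds probe ids and remaining
#'   columns log2 sample values, or a probes x samples matrix with probe row
#'   names.
#' @param map Tibble with columns `probe`, `gene`.
#' @return A tibble with a `gene` column followed by the sample columns.
#' @export
probe_collapse <- function(expression, map) {
  assert_that(nrow(map) > 0, "probe-to-gene mapping is empty")
  assert_that(all(c("probe", "gene") %in% names(map)),
              "map must have columns probe and gene")
  if (is.matrix(expression)) {
    expression <- as_tibble(expression, rownames = "probe")
  }
  probe_col <- names(expression)[1]
  probes <- expression[[1]]
  if (anyDuplicated(map$probe)) {
    warn("some probes map to multiple genes; they contribute to each")
  }
  unmapped <- setdiff(probes, map$probe)
  if (length(unmapped) > 0) {
    inform(sprintf("%d unmapped probe(s) dropped", length(unmapped)))
  }
  expression |>
    dplyr::rename(probe = all_of(probe_col)) |>
    dplyr::inner_join(map, by = "probe", relationship = "many-to-many") |>
    select(-"probe") |>
    group_by(.data$gene) |>
    summarise(across(dplyr::where(is.numeric), mean), .groups = "drop")
}

#' Longitudinal score trajectories after an index diagnosis
#'
#' Restricts to patients whose first biopsy carries the index diagnosis, who
#' have at least two biopsies, and whose final biopsy is a no-rejection
#' diagnosis, then returns the ordered per-patient score series for the
#' requested sets.
#'
#' @param scores A [score_samples()] result.
#' @param cohort The matching [bulk_cohort()].
#' @param index_diagnosis Diagnosis of the first biopsy (default `"TCMR"`).
#' @param final_diagnosis Required diagnosis of the last biopsy
#'   (default `"NR"`).
#' @param sets Sets to include; default all.
#' @return A tibble `patient_id`, `biopsy_index`, `sample`, `diagnosis`,
#'   `set`, `score`, ordered by patient and biopsy.
#' @export
longitudinal_trajectories <- function(scores, cohort,
                                      index_diagnosis = "TCMR",
                                      final_diagnosis = "NR",
                                      sets = NULL) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  clin <- cohort$clinical
  keep <- clin |>
    group_by(.data$patient_id) |>
    filter(n() >= 2,
           .data$diagnosis[which.min(.data$biopsy_index)] == index_diagnosis,
           .data$diagnosis[which.max(.data$biopsy_index)] == final_diagnosis) |>
    ungroup()
  sc <- scores
  if (!is.null(sets)) sc <- filter(sc, .data$set %in% sets)
  keep |>
    dplyr::inner_join(sc, by = c(sample_id = "sample"),
                      relationship = "many-to-many") |>
    arrange(.data$patient_id, .data$biopsy_index, .data$set) |>
    select("patient_id", "biopsy_index", sample = "sample_id",
           "diagnosis", "set", "score")
}
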