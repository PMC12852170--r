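#' Marker-selection query
#'
#' Bundles the parameters of the four-step marker-specificity algorithm: the
#' target injured population (TP), the adjacent injured population used as
#' the specificity contrast, the candidate differential-expression filters,
#' the neighborhood size and the embedding dimensionality.
#'
#' @param target Cluster id of the target population.
#' @param adjacent Cluster id of the adjacent injury population (must differ).
#' @param fold_threshold Specificity fold: TP mean must exceed
#'   `fold_threshold` times every retained neighborhood mean (default 1.25).
#' @param k Neighborhood size, seed cell included (default 100).
#' @param n_pcs Number of principal components for the kNN embedding
#'   (default 30).
#' @param min_log2fc,max_padj,min_frac Candidate DE filters (defaults 1,
#'   0.05, 0.10).
#' @param neighborhood_stat `"max"` (default, TP mean compared against the
#'   maximum neighborhood mean) or `"mean"` (against the mean of neighborhood
#'   means).
#' @return An object of class `marker_query`.
#' @export
marker_query <- function(target, adjacent, fold_threshold = 1.25, k = 100,
                         n_pcs = 30, min_log2fc = 1, max_padj = 0.05,
                         min_frac = 0.10,
                         neighborhood_stat = c("max", "mean")) {
  assert_that(!identical(target, adjacent),
              "target and adjacent populations must differ")
  assert_that(k >= 2, "neighborhood size k must be >= 2")
  assert_that(fold_threshold > 1, "fold threshold must exceed 1")
  structure(list(target = target, adjacent = adjacent,
                 fold_threshold = fold_threshold, k = as.integer(k),
                 n_pcs = as.integer(n_pcs), min_log2fc = min_log2fc,
                 max_padj = max_padj, min_frac = min_frac,
                 neighborhood_stat = match.arg(neighborhood_stat)),
            class = "marker_query")
}

#' Candidate markers: target population vs all other cells
#'
#' Step 1 of the marker algorithm: differential expression of the target
#' population against all remaining cells, retaining upregulated genes under
#' the standard filters of the query.
#'
#' @param cohort A [cell_cohort()].
#' @param query A [marker_query()].
#' @param norm Optional precomputed [lognormalize()] result.
#' @return Tibble of candidate genes with their DE statistics.
#' @export
candidate_markers <- function(cohort, query, norm = NULL) {
  stopifnot(inherits(query, "marker_query"))
  tp <- cells_of(cohort, query$target)
  assert_that(length(tp) > 0,
              paste("target population is empty:", query$target))
  norm <- norm %||% lognormalize(cohort)
  rest <- setdiff(cohort$cells$cell_id, tp)
  de <- wilcoxon_de(norm, tp, rest)
  up <- apply_de_filters(de, query$min_log2fc, query$max_padj,
                         query$min_frac, frac_group = "up")
  filter(up, .data$direction == "up")
}

#' Adjacent-population specificity filter
#'
#' Step 2: keep genes whose mean back-transformed expression in the target
#' population strictly exceeds the mean in the adjacent injury population.
#'
#' @param genes Character vector of gene ids.
#' @param cohort A [cell_cohort()].
#' @param query A [marker_query()].
#' @param norm Optional precomputed [lognormalize()] result.
#' @return The retained gene ids (original order preserved).
#' @export
adjacent_filter <- function(genes, cohort, query, norm = NULL) {
  stopifnot(inherits(query, "marker_query"))
  if (length(genes) == 0) return(character(0))
  norm <- norm %||% lognormalize(cohort)
  adj <- cells_of(cohort, query$adjacent)
  assert_that(length(adj) > 0,
              paste("adjacent population is empty:", query$adjacent))
  tp <- cells_of(cohort, query$target)
  tp_mean <- expm1_means(norm, match(tp, rownames(norm$values)), genes)
  adj_mean <- expm1_means(norm, match(adj, rownames(norm$values)), genes)
  genes[tp_mean > adj_mean]
}

# PCA scores (cells x n_pcs) of the centered log-normalized matrix, via the
# gene-gene covariance eigendecomposition (genes are usually the smaller side)
pca_embed <- function(norm, n_pcs) {
  x <- as.matrix(norm$values)
  n_pcs <- min(n_pcs, ncol(x), nrow(x) - 1L)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(x) - 1L)
  ev <- eigen(cv, symmetric = TRUE)
  xc %*% ev$vectors[, seq_len(n_pcs), drop = FALSE]
}

#' Build k-nearest-neighbor neighborhoods around non-target cells
#'
#' Step 3: embeds all cells by PCA of the log-normalized matrix and, for each
#' cell not in the target population, records its `k` nearest cells (seed
#' included, Euclidean distance in the embedding, ties broken by cell-id
#' order). Neighborhoods containing at least one target-population member are
#' flagged for exclusion.
#'
#' @param cohort A [cell_cohort()].
#' @param query A [marker_query()].
#' @param norm Optional precomputed [lognormalize()] result.
#' @param embedding Optional precomputed cells x dims embedding matrix (rows
#'   in cohort cell order); bypasses the PCA.
#' @return An object of class `neighborhood_set`: list with `seeds` (cell
#'   ids), `members` (k x n_seeds matrix of cell ids), `overlaps_target`
#'   (logical per seed) and `k`.
#' @export
build_neighborhoods <- function(cohort, query, norm = NULL, embedding = NULL) {
  stopifnot(inherits(query, "marker_query"))
  k <- query$k
  assert_that(nrow(cohort$counts) >= k,
              sprintf("need at least k = %d cells, have %d", k,
                      nrow(cohort$counts)))
  norm <- norm %||% lognormalize(cohort)
  emb <- embedding %||% pca_embed(norm, query$n_pcs)
  ids <- cohort$cells$cell_id
  in_tp <- cohort$cells$cluster %in% query$target
  seeds <- which(!in_tp)
  assert_that(length(seeds) > 0, "no cells outside the target population")
  id_rank <- rank(ids, ties.method = "first")

  members <- matrix(NA_integer_, nrow = k, ncol = length(seeds))
  block <- max(1L, floor(2e7 / nrow(emb)))
  for (start in seq(1L, length(seeds), by = block)) {
    sub <- seeds[start:min(start + block - 1L, length(seeds))]
    d2 <- cross_dist2(emb[sub, , drop = FALSE], emb)
    for (j in seq_along(sub)) {
      ord <- order(d2[j, ], id_rank)
      members[, start + j - 1L] <- ord[seq_len(k)]
    }
  }
  overlaps <- apply(members, 2, function(m) any(in_tp[m]))
  structure(list(seeds = ids[seeds],
                 members = matrix(ids[members], nrow = k),
                 overlaps_target = overlaps, k = k),
            class = "neighborhood_set")
}

#' @export
print.neighborhood_set <- function(x, ...) {
  cat(sprintf("<neighborhood_set> %d neighborhoods of k = %d (%d overlap target and are excluded)\n",
              length(x$seeds), x$k, sum(x$overlaps_target)))
  invisible(x)
}

#' Neighborhood specificity filter
#'
#' Step 4: a gene is kept when its mean back-transformed expression in the
#' target population exceeds `fold_threshold` times the neighborhood mean of
#' every retained (non-overlapping) neighborhood (or, with
#' `neighborhood_stat = "mean"`, the mean of neighborhood means). Produces the
#' final marker set, ordered by the TP-mean / max-neighborhood-mean ratio.
#'
#' @param genes Character vector of gene ids surviving steps 1-2.
#' @param neighborhoods A [build_neighborhoods()] result.
#' @param cohort A [cell_cohort()].
#' @param query A [marker_query()].
#' @param norm Optional precomputed [lognormalize()] result.
#' @param name Name of the resulting marker set.
#' @return An object of class `marker_set`.
#' @export
neighborhood_specificity_filter <- function(genes, neighborhoods, cohort,
                                            query, norm = NULL,
                                            name = query$target) {
  stopifnot(inherits(query, "marker_query"),
            inherits(neighborhoods, "neighborhood_set"))
  norm <- norm %||% lognormalize(cohort)
  keep_nb <- which(!neighborhoods$overlaps_target)
  if (length(keep_nb) == 0) {
    abort("all neighborhoods overlap the target population; consider a smaller k")
  }
  tp <- cells_of(cohort, query$target)
  adj <- cells_of(cohort, query$adjacent)
  gidx <- match(genes, colnames(norm$values))
  assert_that(!anyNA(gidx), "unknown gene ids")

  if (length(genes) == 0) {
    return(new_marker_set(name, character(0),
                          audit = empty_audit(), query = query))
  }

  vals <- as.matrix(norm$values[, gidx, drop = FALSE])
  vals <- expm1(vals)
  rownames(vals) <- rownames(norm$values)
  tp_mean <- colMeans(vals[tp, , drop = FALSE])
  adj_mean <- if (length(adj) > 0) colMeans(vals[adj, , drop = FALSE]) else
    rep(NA_real_, length(genes))

  nb_means <- vapply(keep_nb, function(i) {
    colMeans(vals[neighborhoods$members[, i], , drop = FALSE])
  }, numeric(length(genes)))
  nb_means <- matrix(nb_means, nrow = length(genes))
  max_nb <- apply(nb_means, 1, max)
  stat_nb <- if (query$neighborhood_stat == "max") max_nb else
    rowMeans(nb_means)

  keep <- tp_mean > query$fold_threshold * stat_nb
  audit <- tibble(gene = genes, tp_mean = tp_mean, adjacent_mean = adj_mean,
                  max_neighborhood_mean = max_nb,
                  ratio = ifelse(max_nb > 0, tp_mean / max_nb, Inf),
                  kept = keep)
  sel <- audit[audit$kept, , drop = FALSE]
  sel <- sel[order(-sel$ratio, sel$gene), , drop = FALSE]
  new_marker_set(name, sel$gene, audit = audit, query = query,
                 n_neighborhoods = length(keep_nb))
}

empty_audit <- function() {
  tibble(gene = character(0), tp_mean = numeric(0),
         adjacent_mean = numeric(0), max_neighborhood_mean = numeric(0),
         ratio = numeric(0), kept = logical(0))
}

new_marker_set <- function(name, genes, audit, query, n_neighborhoods = NA) {
  structure(list(name = name, genes = genes, audit = audit,
                 thresholds = list(fold_threshold = query$fold_threshold,
                                   k = query$k, n_pcs = query$n_pcs,
                                   min_log2fc = query$min_log2fc,
                                   max_padj = query$max_padj,
                                   min_frac = query$min_frac,
                                   neighborhood_stat = query$neighborhood_stat),
                 n_neighborhoods = n_neighborhoods),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %s: %d genes (fold threshold %.3g, k = %d)\n",
              x$name, length(x$genes), x$thresholds$fold_threshold,
              x$thresholds$k))
  if (length(x$genes) > 0)
    cat("  ", paste(head(x$genes, 10), collapse = ", "),
        if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.marker_set <- function(x, ...) {
  mutate(x$audit, set = x$name, .before = 1)
}

#' Run the full four-step marker-specificity algorithm
#'
#' Convenience wrapper: candidate DE vs all other cells, adjacent-population
#' filter, kNN neighborhood construction with target-overlap exclusion, and
#' the neighborhood specificity filter.
#'
#' @inheritParams neighborhood_specificity_filter
#' @return A `marker_set`.
#' @export
select_markers <- function(cohort, query, name = query$target, norm = NULL) {
  norm <- norm %||% lognormalize(cohort)
  cand <- candidate_markers(cohort, query, norm = norm)
  genes <- adjacent_filter(cand$gene, cohort, query, norm = norm)
  nbs <- build_neighborhoods(cohort, query, norm = norm)
  neighborhood_specificity_filter(genes, nbs, cohort, query, norm = norm,
                                  name = name)
}
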