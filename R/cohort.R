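#' Construct a single-cell cohort
#'
#' Container for a sparse cells-by-genes count matrix with per-cell cluster,
#' sample and group labels — the substrate of differential expression and
#' marker selection.
#'
#' @param counts Sparse (or dense) non-negative integer matrix, cells x genes.
#' @param cells Tibble with columns `cell_id`, `cluster`, `sample`, `group`,
#'   one row per matrix row.
#' @return An object of class `cell_cohort`.
#' @export
cell_cohort <- function(counts, cells) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  cells <- as_tibble(cells)
  need <- c("cell_id", "cluster", "sample", "group")
  assert_that(all(need %in% names(cells)),
              paste("cell metadata must contain:", paste(need, collapse = ", ")))
  assert_that(nrow(cells) == nrow(counts),
              "cell metadata rows must match count-matrix rows")
  assert_that(!anyDuplicated(cells$cell_id), "cell ids must be unique")
  assert_that(!anyDuplicated(colnames(counts)), "gene ids must be unique")
  assert_that(!any(counts@x < 0), "counts must be non-negative")
  assert_that(all(counts@x == round(counts@x)), "counts must be integers")
  assert_that(!any(is.na(cells$cluster)) && !any(is.na(cells$sample)) &&
                !any(is.na(cells$group)), "every cell needs all three labels")
  rownames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells), class = "cell_cohort")
}

#' @export
print.cell_cohort <- function(x, ...) {
  cat(sprintf("<cell_cohort> %d cells x %d genes; %d clusters, %d samples, groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              dplyr::n_distinct(x$cells$cluster),
              dplyr::n_distinct(x$cells$sample),
              paste(unique(x$cells$group), collapse = "/")))
  invisible(x)
}

#' @export
dim.cell_cohort <- function(x) dim(x$counts)

cells_of <- function(cohort, cluster) {
  cohort$cells$cell_id[cohort$cells$cluster %in% cluster]
}
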