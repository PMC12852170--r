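#' Write / read a single-cell cohort as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv`,
#' `barcodes.tsv` and a `cells.csv` metadata table into a directory.
#'
#' @param cohort A [cell_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cell_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cell_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cohort$counts), file.path(dir, "matrix.mtx"))
  writeLines(colnames(cohort$counts), file.path(dir, "features.tsv"))
  writeLines(cohort$cells$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.csv(cohort$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_cell_cohort
#' @export
read_cell_cohort <- function(dir) {
  m <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  genes <- readLines(file.path(dir, "features.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  colnames(m) <- genes
  rownames(m) <- barcodes
  cells <- as_tibble(utils::read.csv(file.path(dir, "cells.csv")))
  cell_cohort(m, cells)
}

#' Write / read marker sets in GMT format
#'
#' One line per set: name, description, then the gene ids, tab-separated.
#'
#' @param sets Named list of gene vectors or `marker_set` objects.
#' @param path Output file.
#' @return `path`, invisibly (write); a named list of gene vectors (read).
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_sets(sets)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "injurystates", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[`, character(1), 1))
}

#' Write / read a spatial segmented-cell table
#'
#' @param cells Tibble `cell_id`, `x_um`, `y_um`, `cell_type`, `sample_id`,
#'   `group`.
#' @param path CSV file path.
#' @return `path`, invisibly (write); the tibble (read).
#' @export
write_spatial_cells <- function(cells, path) {
  utils::write.csv(cells[, c("cell_id", "x_um", "y_um", "cell_type",
                             "sample_id", "group")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spatial_cells
#' @export
read_spatial_cells <- function(path) {
  as_tibble(utils::read.csv(path))
}

#' Write / read a bulk cohort as plain-text tables
#'
#' Writes `expression.tsv` (genes x samples, log2), `clinical.tsv` and
#' `controls.txt` into a directory.
#'
#' @param cohort A [bulk_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bulk_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(cohort$controls, file.path(dir, "controls.txt"))
  invisible(dir)
}

#' @rdname write_bulk_cohort
#' @export
read_bulk_cohort <- function(dir) {
  expr <- utils::read.delim(file.path(dir, "expression.tsv"),
                            check.names = FALSE)
  clinical <- as_tibble(utils::read.delim(file.path(dir, "clinical.tsv")))
  controls <- readLines(file.path(dir, "controls.txt"))
  bulk_cohort(expr, clinical, controls)
}
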