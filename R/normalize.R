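#' Log-normalize a count cohort
#'
#' Depth-normalizes each cell to `scale` total counts and applies
#' `log(1 + x)`: `value[c, g] = ln(1 + scale * count[c, g] / total[c])`.
#' Sparsity is preserved (zeros map to zeros) and the transform is reversible
#' via `expm1`.
#'
#' @param cohort A [cell_cohort()].
#' @param scale Scale factor (default 10,000).
#' @return An object of class `lognorm`: list with `values` (sparse cells x
#'   genes), `scale`, and the cell metadata.
#' @export
lognormalize <- function(cohort, scale = 1e4) {
  stopifnot(inherits(cohort, "cell_cohort"))
  assert_that(scale > 0, "scale factor must be positive")
  totals <- Matrix::rowSums(cohort$counts)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    abort(paste0("cells with zero total counts cannot be normalized: ",
                 paste(head(cohort$cells$cell_id[zero], 10), collapse = ", "),
                 if (length(zero) > 10) ", ..." else ""))
  }
  values <- cohort$counts * 1.0
  values@x <- log1p(scale * values@x / totals[values@i + 1L])
  structure(list(values = values, scale = scale, cells = cohort$cells),
            class = "lognorm")
}

#' @export
print.lognorm <- function(x, ...) {
  cat(sprintf("<lognorm> %d cells x %d genes (scale %g)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

# mean of expm1(log-normalized values) per gene over a set of rows; the
# back-transformed scale on which fold-changes and marker means are defined
expm1_means <- function(norm, rows, genes = NULL) {
  v <- norm$values[rows, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  m <- v
  m@x <- expm1(m@x)
  Matrix::colMeans(m)
}
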