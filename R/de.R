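#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around the standard step-up procedure: adjusted
#' `p[i] = min over j with p[j] >= p[i] of (m * p[j] / rank[j])`, capped at 1.
#' Order-preserving under input permutation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p) {
  assert_that(!anyNA(p) && all(p >= 0) && all(p <= 1),
              "p-values must lie in [0, 1] and contain no NA")
  p.adjust(p, method = "BH")
}

#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Two-sided Wilcoxon rank-sum test per gene between two disjoint cell sets on
#' log-normalized values, with tie-corrected normal approximation (exact
#' enumeration of all group assignments when the smaller group has at most 8
#' cells and the enumeration is tractable). Fold-changes follow the
#' back-transformed-mean convention:
#' `log2FC = log2((mean(expm1(A)) + 1) / (mean(expm1(B)) + 1))`.
#' P-values are Benjamini-Hochberg adjusted across all genes in the call.
#'
#' @param norm A [lognormalize()] result.
#' @param cells_a,cells_b Disjoint, non-empty character vectors of cell ids.
#' @return A tibble `gene`, `log2fc`, `p_value`, `padj`, `frac_a`, `frac_b`,
#'   `direction` (`"up"` if higher in `cells_a`).
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b) {
  stopifnot(inherits(norm, "lognorm"))
  assert_that(length(cells_a) > 0 && length(cells_b) > 0,
              "both cell sets must be non-empty")
  assert_that(length(intersect(cells_a, cells_b)) == 0,
              "cell sets must be disjoint")
  ia <- match(cells_a, rownames(norm$values))
  ib <- match(cells_b, rownames(norm$values))
  assert_that(!anyNA(ia) && !anyNA(ib), "unknown cell ids")

  va <- as.matrix(norm$values[ia, , drop = FALSE])
  vb <- as.matrix(norm$values[ib, , drop = FALSE])
  na <- length(ia); nb <- length(ib); n <- na + nb

  ea <- colMeans(expm1(va)); eb <- colMeans(expm1(vb))
  log2fc <- log2((ea + 1) / (eb + 1))
  frac_a <- colMeans(va > 0); frac_b <- colMeans(vb > 0)

  m <- min(na, nb)
  exact <- m <= 8 && choose(n, m) <= 2e5
  pvals <- vapply(seq_len(ncol(va)), function(g) {
    wilcox_p(c(va[, g], vb[, g]), na, exact)
  }, numeric(1))

  tibble(gene = colnames(norm$values), log2fc = unname(log2fc),
         p_value = pvals, padj = benjamini_hochberg(pvals),
         frac_a = unname(frac_a), frac_b = unname(frac_b),
         direction = ifelse(log2fc >= 0, "up", "down"))
}

# two-sided Wilcoxon rank-sum p for pooled values v, first na entries = group
# A; exact enumeration or tie-corrected normal approximation
wilcox_p <- function(v, na, exact = FALSE) {
  n <- length(v)
  nb <- n - na
  r <- rank(v)
  w_obs <- sum(r[seq_len(na)])
  mu_a <- na * (n + 1) / 2
  if (exact) {
    m <- min(na, nb)
    ridx <- if (na <= nb) seq_len(na) else (na + 1):n
    w_small <- sum(r[ridx])
    mu_s <- m * (n + 1) / 2
    combs <- combn(n, m)
    w_all <- colSums(matrix(r[combs], nrow = m))
    return(mean(abs(w_all - mu_s) >= abs(w_small - mu_s) - 1e-9))
  }
  ties <- table(v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w_obs - mu_a) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Filter a differential-expression table
#'
#' Applies the study's significance and expression filters: absolute log2
#' fold-change above `min_abs_log2fc`, adjusted p below `max_padj`, and
#' fraction of expressing cells at least `min_frac` in the selected group.
#' With `frac_group = "up"` (default) the fraction is taken in the group where
#' the gene is higher — group A for upregulated genes, group B for
#' downregulated ones.
#'
#' @param de A [wilcoxon_de()] result.
#' @param min_abs_log2fc Minimum |log2FC| (exclusive; default 1).
#' @param max_padj Maximum adjusted p (exclusive; default 0.05).
#' @param min_frac Minimum expressing fraction (inclusive; default 0.10).
#' @param frac_group One of `"up"`, `"group1"`, `"group2"`, `"either"`.
#' @return The filtered tibble, ordered by descending |log2FC| with gene id
#'   as tiebreak.
#' @export
apply_de_filters <- function(de, min_abs_log2fc = 1, max_padj = 0.05,
                             min_frac = 0.10,
                             frac_group = c("up", "group1", "group2", "either")) {
  frac_group <- match.arg(frac_group)
  assert_that(is.finite(min_abs_log2fc) && is.finite(max_padj) &&
                is.finite(min_frac), "thresholds must be finite")
  frac_ok <- switch(
    frac_group,
    up = ifelse(de$log2fc >= 0, de$frac_a, de$frac_b) >= min_frac,
    group1 = de$frac_a >= min_frac,
    group2 = de$frac_b >= min_frac,
    either = pmax(de$frac_a, de$frac_b) >= min_frac
  )
  out <- de[abs(de$log2fc) > min_abs_log2fc & de$padj < max_padj & frac_ok, ,
            drop = FALSE]
  out[order(-abs(out$log2fc), out$gene), , drop = FALSE]
}
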