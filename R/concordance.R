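#' Cross-dataset log2 fold-change concordance
#'
#' Selects the `top_n` most increased and `top_n` most decreased genes by
#' log2 fold-change in the reference dataset, intersects them with the genes
#' of the second dataset, and reports the Spearman correlation of the paired
#' log2 fold-changes.
#'
#' @param de_a Reference differential-expression tibble (`gene`, `log2fc`).
#' @param de_b Comparison tibble (`gene`, `log2fc`).
#' @param top_n Number of increased and of decreased genes (default 500).
#' @return A one-row tibble `rho`, `p_value`, `n_genes`.
#' @export
log2fc_concordance <- function(de_a, de_b, top_n = 500) {
  assert_that(all(c("gene", "log2fc") %in% names(de_a)) &&
                all(c("gene", "log2fc") %in% names(de_b)),
              "inputs need columns gene and log2fc")
  up <- de_a$gene[order(-de_a$log2fc, de_a$gene)][seq_len(min(top_n, nrow(de_a)))]
  dn <- de_a$gene[order(de_a$log2fc, de_a$gene)][seq_len(min(top_n, nrow(de_a)))]
  sel <- union(up, dn)
  shared <- intersect(sel, de_b$gene)
  assert_that(length(shared) >= 10,
              sprintf("only %d shared genes; need at least 10", length(shared)))
  xa <- de_a$log2fc[match(shared, de_a$gene)]
  xb <- de_b$log2fc[match(shared, de_b$gene)]
  ct <- suppressWarnings(cor.test(xa, xb, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         n_genes = length(shared))
}
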