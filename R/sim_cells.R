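#' Simulate a clustered single-nucleus count cohort
#'
#' Draws negative-binomial counts for `n_cells` cells in the configured
#' populations. Gene-wise baseline relative abundances are drawn once
#' (log-normal) and shared across populations; planted marker genes are
#' multiplied by their linear fold-change in their own population only, so the
#' planted markers are exactly the population-distinguishing genes and the
#' ground truth is recoverable from the counts. Per-cell depths are
#' log-uniform over the configured range; cells are assigned to biological
#' samples nested in the two groups, with per-population group bias.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a [cell_cohort()]) and `truth`
#'   (a list holding the planted marker table, the population table and the
#'   per-gene baseline abundances).
#' @export
simulate_cell_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_substream(config$seed, "cells", {
    pop <- config$populations
    n_pop <- nrow(pop)
    n_cells <- config$n_cells
    n_genes <- config$n_genes

    # deterministic rounding of population sizes (largest remainder)
    raw <- pop$proportion * n_cells
    sizes <- floor(raw)
    rem <- n_cells - sum(sizes)
    if (rem > 0) {
      take <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[take] <- sizes[take] + 1L
    }
    planted_pops <- unique(config$planted_markers$population)
    empty_planted <- planted_pops[sizes[match(planted_pops, pop$name)] == 0L]
    if (length(empty_planted) > 0) {
      abort(paste0("population(s) with planted markers received zero cells: ",
                   paste(empty_planted, collapse = ", ")))
    }

    base_w <- exp(rnorm(n_genes, 0, 1))
    # planted markers sit on a fixed mid-range baseline so their fold-change
    # is visible above shot noise at typical depths
    marker_idx <- unique(config$planted_markers$gene)
    base_w[marker_idx] <- exp(0.5)

    # population x gene relative-abundance matrix
    W <- matrix(rep(base_w, each = n_pop), nrow = n_pop)
    for (i in seq_len(nrow(config$planted_markers))) {
      p <- match(config$planted_markers$population[i], pop$name)
      g <- config$planted_markers$gene[i]
      W[p, g] <- W[p, g] * config$planted_markers$fold[i]
    }
    W <- W / rowSums(W)

    cluster <- rep(pop$name, sizes)
    depth <- exp(runif(n_cells, log(config$library_size_range[1]),
                       log(config$library_size_range[2])))

    counts <- matrix(0L, n_cells, n_genes)
    for (p in seq_len(n_pop)) {
      rows <- which(cluster == pop$name[p])
      if (length(rows) == 0) next
      mu <- outer(depth[rows], W[p, ])
      counts[rows, ] <- rnbinom(length(mu), mu = mu,
                                size = 1 / config$nb_dispersion)
    }

    # group and sample labels: per-population biased coin for the group,
    # uniform sample within group
    grp2 <- rbinom(n_cells, 1, pop$group_bias[match(cluster, pop$name)])
    group <- config$groups[grp2 + 1L]
    samp_no <- sample.int(config$n_samples_per_group, n_cells, replace = TRUE)
    sample_id <- paste0(group, "_s", samp_no)

    cells <- tibble(
      cell_id = sprintf("cell%05d", seq_len(n_cells)),
      cluster = cluster, sample = sample_id, group = group
    )
    colnames(counts) <- gene_names(n_genes)
    cohort <- cell_cohort(counts, cells)

    truth <- list(
      planted_markers = mutate(config$planted_markers,
                               gene_id = gene_names(n_genes)[gene]),
      populations = pop,
      baseline_weights = base_w
    )
    list(cohort = cohort, truth = truth)
  })
}
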