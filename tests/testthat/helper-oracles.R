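# Independent brute-force oracles and small fixture builders.

# exhaustive-permutation two-sided Wilcoxon rank-sum p, via the Mann-Whitney
# U statistic (pair counting, not ranks)
oracle_wilcox_p <- function(a, b) {
  u_stat <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  mu <- na * (n - na) / 2
  obs <- abs(u_stat(a, b) - mu)
  sets <- combn(n, na)
  devs <- apply(sets, 2, function(idx) {
    abs(u_stat(pool[idx], pool[-idx]) - mu)
  })
  mean(devs >= obs - 1e-9)
}

# sort-based Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# hand product-limit estimator on event times (censorings at tied times
# processed after events)
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ut, survival = out)
}

# full-pairwise-distance kNN neighborhoods (k nearest incl. seed, cell-id
# tie-break) around every non-target cell, with target-overlap flags
oracle_neighborhoods <- function(emb, ids, in_tp, k) {
  d <- as.matrix(dist(emb))
  id_rank <- rank(ids, ties.method = "first")
  seeds <- which(!in_tp)
  members <- sapply(seeds, function(s) {
    ord <- order(d[s, ], id_rank)
    ids[ord[seq_len(k)]]
  })
  list(seeds = ids[seeds], members = matrix(members, nrow = k),
       overlaps_target = apply(matrix(members, nrow = k), 2,
                               function(m) any(in_tp[match(m, ids)])))
}

# O(n^2) co-occurrence ratio at each grid distance
oracle_cooccurrence <- function(cells, anchor, query, grid) {
  n <- nrow(cells)
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  arows <- which(cells$cell_type == anchor)
  md <- sapply(seq_len(n), function(i) {
    dd <- d[i, setdiff(arows, i)]
    if (length(dd) == 0) Inf else min(dd)
  })
  n_query <- sum(cells$cell_type == query)
  marginal <- n_query / n
  sapply(grid, function(g) {
    within <- md <= g
    if (sum(within) == 0) return(NaN)
    if (n_query == 0) return(0)
    (sum(within & cells$cell_type == query) / sum(within)) / marginal
  })
}

# small labelled cohort with chosen count matrix
make_cohort <- function(counts, clusters, samples = NULL, groups = NULL) {
  n <- nrow(counts)
  colnames(counts) <- colnames(counts) %||% sprintf("g%03d", seq_len(ncol(counts)))
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    cluster = clusters,
    sample = samples %||% rep("s1", n),
    group = groups %||% rep("allogeneic", n)
  )
  cell_cohort(counts, cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# lognorm object with prescribed values (cells x genes), for kernel tests
make_norm <- function(values, cell_ids = NULL) {
  values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  values <- methods::as(values, "generalMatrix")
  rownames(values) <- cell_ids %||% sprintf("c%04d", seq_len(nrow(values)))
  colnames(values) <- colnames(values) %||% sprintf("g%03d", seq_len(ncol(values)))
  cells <- tibble::tibble(cell_id = rownames(values),
                          cluster = "x", sample = "s1", group = "g1")
  structure(list(values = values, scale = 1e4, cells = cells),
            class = "lognorm")
}

# random CSR spatial sample
make_csr_sample <- function(n, types, probs, L = 600, sample_id = "s1",
                            group = "allogeneic") {
  tibble::tibble(
    cell_id = sprintf("%s_c%05d", sample_id, seq_len(n)),
    x_um = runif(n, 0, L), y_um = runif(n, 0, L),
    cell_type = sample(types, n, replace = TRUE, prob = probs),
    sample_id = sample_id, group = group
  )
}
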