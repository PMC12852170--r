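# small synthetic cohort with one exclusive target marker, one shared gene
# and unstructured background, used across the marker tests
make_marker_cohort <- function(seed = 1, n_per = 60, n_genes = 60) {
  set.seed(seed)
  clusters <- rep(c("tp", "adj", "other"), each = n_per)
  counts <- matrix(rnbinom(3 * n_per * n_genes, mu = 3, size = 2),
                   nrow = 3 * n_per)
  counts[clusters == "tp", 1] <- rnbinom(n_per, mu = 30, size = 2)   # exclusive
  counts[clusters %in% c("tp", "adj"), 2] <-
    rnbinom(2 * n_per, mu = 30, size = 2)                            # shared w/ adjacent
  make_cohort(counts, clusters)
}

test_that("candidate step keeps planted exclusive genes, drops null genes", {
  co <- make_marker_cohort()
  q <- marker_query("tp", "adj", k = 20, n_pcs = 10)
  cand <- candidate_markers(co, q)
  expect_true("g001" %in% cand$gene)
  expect_true("g002" %in% cand$gene)   # specificity enforced later, not here
  expect_false("g010" %in% cand$gene)  # unstructured background gene
  expect_error(candidate_markers(
    co, marker_query("missing", "adj")), "empty")
})

test_that("adjacent filter applies a strict inequality on back-transformed means", {
  co <- make_marker_cohort()
  q <- marker_query("tp", "adj")
  norm <- lognormalize(co)
  kept <- adjacent_filter(c("g001", "g002"), co, q, norm)
  expect_true("g001" %in% kept)
  # exact tie is dropped: gene with identical values everywhere
  co2 <- make_cohort(matrix(5, nrow = 6, ncol = 2),
                     clusters = rep(c("tp", "adj"), each = 3))
  expect_length(adjacent_filter(c("g001", "g002"), co2, q,
                                lognormalize(co2)), 0)
})

test_that("neighborhoods match the brute-force oracle incl. overlap flags", {
  for (seed in 1:3) {
    co <- make_marker_cohort(seed = seed, n_per = 40, n_genes = 30)
    q <- marker_query("tp", "adj", k = 15, n_pcs = 8)
    norm <- lognormalize(co)
    nbs <- build_neighborhoods(co, q, norm)
    emb <- stats::prcomp(as.matrix(norm$values), center = TRUE,
                         scale. = FALSE)$x[, 1:8]
    ora <- oracle_neighborhoods(emb, co$cells$cell_id,
                                co$cells$cluster == "tp", k = 15)
    expect_identical(nbs$seeds, ora$seeds)
    expect_identical(nbs$members, ora$members)
    expect_identical(nbs$overlaps_target, ora$overlaps_target)
  }
})

test_that("neighborhood boundary and error cases behave", {
  co <- make_marker_cohort(n_per = 10, n_genes = 20)
  expect_error(build_neighborhoods(
    co, marker_query("tp", "adj", k = 31)), "at least k")
  # k equal to the full cell count: single giant neighborhood per seed
  nbs <- build_neighborhoods(co, marker_query("tp", "adj", k = 30, n_pcs = 5))
  expect_true(all(nbs$overlaps_target))  # every neighborhood spans all cells
})

test_that("the 1.25-fold neighborhood rule is applied literally", {
  # gene 1: expressed only in tp (kept: tp_mean > 1.25 * 0)
  # gene 2: tp mean 1.0 vs neighborhood mean 0.9 (dropped: 1.0 <= 1.125)
  vals <- matrix(0, nrow = 40, ncol = 2)
  vals[1:10, 1] <- 1.0
  vals[1:10, 2] <- 1.0
  vals[11:40, 2] <- 0.9
  vals <- log1p(vals)  # store on log scale so expm1-means recover them
  counts <- matrix(0L, 40, 2)
  counts[vals > 0] <- 1L
  counts <- cbind(counts, 10L)  # third gene keeps every cell at positive depth
  colnames(counts) <- NULL
  co <- make_cohort(counts, clusters = rep(c("tp", "bg"), c(10, 30)))
  norm <- lognormalize(co)
  norm$values[, 1:2] <- Matrix::Matrix(vals, sparse = TRUE)
  q <- marker_query("tp", "bg_unused", k = 10, n_pcs = 2)
  # build neighborhoods in a space where tp is isolated, so all 30 bg seeds
  # get pure-bg neighborhoods
  emb <- cbind(c(rep(100, 10), runif(30)), 0)
  nbs <- build_neighborhoods(co, q, norm, embedding = emb)
  ms <- neighborhood_specificity_filter(c("g001", "g002"), nbs, co, q, norm,
                                        name = "toy")
  expect_equal(ms$genes, "g001")
  expect_true(all(ms$audit$kept == c(TRUE, FALSE)))
})

test_that("all-overlapping neighborhoods raise an advisory error", {
  co <- make_marker_cohort(n_per = 10, n_genes = 20)
  q <- marker_query("tp", "adj", k = 30, n_pcs = 5)
  nbs <- build_neighborhoods(co, q)
  expect_error(neighborhood_specificity_filter("g001", nbs, co, q),
               "smaller k")
})

test_that("marker pipeline is monotone in the fold threshold and deterministic", {
  cfg <- sim_config(seed = 31, n_genes = 400, n_cells = 900)
  sim <- simulate_cell_cohort(cfg)
  norm <- lognormalize(sim$cohort)
  sets <- lapply(c(1.25, 2, 4), function(f) {
    q <- marker_query("PT_Injury_2", "PT_Injury_1", fold_threshold = f,
                      k = 40, n_pcs = 15)
    select_markers(sim$cohort, q, norm = norm)$genes
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))

  q <- marker_query("PT_Injury_2", "PT_Injury_1", k = 40, n_pcs = 15)
  cand <- candidate_markers(sim$cohort, q, norm = norm)
  expect_true(all(sets[[1]] %in% cand$gene))

  rerun <- select_markers(sim$cohort, q, norm = norm)$genes
  expect_identical(select_markers(sim$cohort, q, norm = norm)$genes, rerun)
})

test_that("planted exclusive markers are recovered with high precision", {
  hits <- sapply(1:5, function(i) {
    cfg <- sim_config(seed = 200 + i, n_genes = 400, n_cells = 1200)
    sim <- simulate_cell_cohort(cfg)
    q <- marker_query("PT_Injury_2", "PT_Injury_1", k = 50, n_pcs = 15)
    ms <- select_markers(sim$cohort, q)
    truth <- sim$truth$planted_markers
    tp_genes <- truth$gene_id[truth$population == "PT_Injury_2"]
    c(sens = length(intersect(ms$genes, tp_genes)) / length(tp_genes),
      fp = length(setdiff(ms$genes, tp_genes)))
  })
  expect_gte(mean(hits["sens", ]), 0.9)
  expect_lte(mean(hits["fp", ] / 20), 0.2)
})
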