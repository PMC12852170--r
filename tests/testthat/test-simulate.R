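test_that("identical seeds reproduce all three generators exactly", {
  cfg <- sim_config(seed = 11, n_genes = 300, n_cells = 600,
                    spatial = spatial_config(field_size_um = 400))
  a <- simulate_cell_cohort(cfg)
  b <- simulate_cell_cohort(cfg)
  expect_identical(as.matrix(a$cohort$counts), as.matrix(b$cohort$counts))
  expect_identical(a$cohort$cells, b$cohort$cells)

  sa <- simulate_spatial_sample(cfg, "s1")
  sb <- simulate_spatial_sample(cfg, "s1")
  expect_identical(sa$cells, sb$cells)

  sets <- list(m1 = sprintf("g%04d", 1:15))
  ba <- simulate_bulk_cohort(cfg, sets)
  bb <- simulate_bulk_cohort(cfg, sets)
  expect_identical(ba$cohort$clinical, bb$cohort$clinical)
  expect_identical(ba$cohort$expression, bb$cohort$expression)
})

test_that("generator substreams are independent of each other", {
  cfg <- sim_config(seed = 11, n_genes = 300, n_cells = 400,
                    spatial = spatial_config(field_size_um = 400))
  a <- simulate_spatial_sample(cfg, "s1")
  invisible(simulate_cell_cohort(cfg))  # interleaved use of another stream
  b <- simulate_spatial_sample(cfg, "s1")
  expect_identical(a$cells, b$cells)
})

test_that("fold-change 1 for all planted markers leaves populations exchangeable", {
  pops <- default_populations()
  pm <- default_planted_markers(pops)
  pm$fold <- 1
  cfg <- sim_config(seed = 4, n_genes = 400, n_cells = 2000,
                    populations = pops, planted_markers = pm)
  sim <- simulate_cell_cohort(cfg)
  counts <- as.matrix(sim$cohort$counts)
  tp <- sim$cohort$cells$cluster == "PT_Injury_2"
  # depth-normalized t-test per gene: rejections should sit near alpha
  cpm <- counts / rowSums(counts)
  p <- apply(cpm, 2, function(v) stats::t.test(v[tp], v[!tp])$p.value)
  expect_lt(mean(p < 0.01), 0.04)
  expect_gt(mean(p < 0.01), 0)
})

test_that("planted fold-changes are recoverable from the counts", {
  cfg <- sim_config(seed = 8, n_genes = 500, n_cells = 2500)
  sim <- simulate_cell_cohort(cfg)
  counts <- as.matrix(sim$cohort$counts)
  cpm <- counts / rowSums(counts)
  truth <- sim$truth$planted_markers
  tg <- truth[truth$population == "PT_Injury_2", ]
  tp <- sim$cohort$cells$cluster == "PT_Injury_2"
  expect_gte(sum(tp), 200)
  ratio <- colMeans(cpm[tp, tg$gene]) / colMeans(cpm[!tp, tg$gene])
  expect_true(all(abs(ratio - tg$fold) / tg$fold < 0.25))
})

test_that("a planted-marker population with zero cells is an error", {
  pops <- tibble::tibble(
    name = c("big", "tiny"), proportion = c(0.999, 0.001),
    role = c("healthy", "target_injury"), group_bias = c(0.5, 0.5))
  pm <- tibble::tibble(population = "tiny", gene = 1:5, fold = 4)
  cfg <- sim_config(seed = 1, n_genes = 50, n_cells = 100,
                    populations = pops, planted_markers = pm)
  expect_error(simulate_cell_cohort(cfg), "tiny")
})

test_that("CSR spatial samples have co-occurrence ratios centred at 1", {
  sp <- spatial_config(field_size_um = 1000,
                       pairs = tibble::tibble(anchor = "PT_Injury",
                                              query = "Macrophage", rho = 1))
  cfg <- sim_config(seed = 21, spatial = sp)
  ratios <- sapply(1:6, function(i) {
    s <- simulate_spatial_sample(cfg, paste0("s", i))
    cooccurrence_curve(s$cells, "PT_Injury", "Macrophage", grid = 25)$ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
})

test_that("negative enrichment rho is rejected and depletion works", {
  expect_error(spatial_config(pairs = tibble::tibble(
    anchor = "a", query = "b", rho = -1)), "rho")
  sp <- spatial_config(field_size_um = 1500,
                       pairs = tibble::tibble(anchor = "PT_Injury",
                                              query = "Macrophage", rho = 0.5))
  cfg <- sim_config(seed = 5, spatial = sp)
  s <- simulate_spatial_sample(cfg, "s1")
  r <- cooccurrence_curve(s$cells, "PT_Injury", "Macrophage", grid = 25)$ratio
  expect_lt(abs(r - 0.5), 0.15)
})

test_that("a requested type that draws zero cells is absent with a warning", {
  sp <- spatial_config(field_size_um = 250,
                       cell_types = tibble::tibble(
                         type = c("a", "b", "rare"),
                         proportion = c(0.6, 0.3999, 1e-4)),
                       pairs = tibble::tibble(anchor = "a", query = "b",
                                              rho = 1))
  cfg <- sim_config(seed = 3, spatial = sp)
  expect_warning(s <- simulate_spatial_sample(cfg, "s1"), "rare")
  expect_false("rare" %in% s$cells$cell_type)
})

test_that("bulk generator plants recoverable uniform scores", {
  cfg <- sim_config(seed = 9, n_genes = 300,
                    bulk = bulk_config(n_samples = 80, fixed_score = 1,
                                       n_followup = 0))
  sets <- list(inj = sprintf("g%04d", 1:20))
  sim <- simulate_bulk_cohort(cfg, sets)
  sc <- score_samples(sim$cohort, sets)
  cases <- sc[!sc$is_control, ]
  expect_lt(abs(mean(cases$score) - 1), 0.05)
  expect_lt(abs(mean(sc$score[sc$is_control])), 1e-9)
})

test_that("empty marker sets and null-hazard calibration behave", {
  cfg <- sim_config(seed = 2, n_genes = 300)
  expect_error(simulate_bulk_cohort(cfg, list(bad = character(0))), "empty")

  # beta = 0: median-split log-rank rejects at about the nominal rate
  rej <- sapply(1:40, function(i) {
    cfgi <- sim_config(seed = 100 + i, n_genes = 300,
                       bulk = bulk_config(n_samples = 120, hazard_ratio = 1,
                                          n_followup = 0))
    sim <- simulate_bulk_cohort(cfgi, list(s1 = sprintf("g%04d", 1:10)))
    st <- median_stratify(score_samples(sim$cohort, list(s1 = sprintf("g%04d", 1:10))),
                          sim$cohort)
    d <- dplyr::inner_join(st, sim$cohort$clinical,
                           by = c(sample = "sample_id"))
    a <- d[d$stratum == "above", ]; b <- d[d$stratum == "below", ]
    logrank_test(a$time_months, a$event, b$time_months, b$event)$p_value < 0.05
  })
  expect_lte(mean(rej), 0.2)
})

test_that("bulk event fraction tracks the configured target", {
  cfg <- sim_config(seed = 14, n_genes = 300,
                    bulk = bulk_config(n_samples = 400, n_followup = 0))
  sim <- simulate_bulk_cohort(cfg, list(s1 = sprintf("g%04d", 1:10)))
  first <- sim$cohort$clinical[sim$cohort$clinical$biopsy_index == 1, ]
  expect_lt(abs(mean(first$event) - 0.40), 0.08)
})
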