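# tiny deterministic bulk cohort: 4 genes x (3 cases + 2 controls)
make_toy_bulk <- function(case_shift = c(1, 1, 1)) {
  genes <- sprintf("g%04d", 1:4)
  base <- c(8, 6, 7, 9)
  expr <- cbind(sapply(case_shift, function(s) base + c(s, s, 0, 0)),
                base, base)
  dimnames(expr) <- list(genes, c("B1", "B2", "B3", "N1", "N2"))
  clinical <- tibble::tibble(
    sample_id = c("B1", "B2", "B3"), patient_id = c("P1", "P2", "P3"),
    biopsy_index = 1L, diagnosis = c("TCMR", "NR", "TCMR"),
    time_months = c(10, 20, 30), event = c(1L, 0L, 1L))
  bulk_cohort(expr, clinical, controls = c("N1", "N2"))
}

test_that("scores are control-normalized log2 geometric means", {
  co <- make_toy_bulk()
  sets <- list(inj = c("g0001", "g0002"))
  sc <- score_samples(co, sets)
  # every marker gene exactly 2x control -> score 1.0
  expect_equal(sc$score[sc$sample == "B1"], 1.0)
  # control mean exactly zero
  expect_lt(abs(mean(sc$score[sc$is_control])), 1e-12)
  # singleton set = that gene's value minus control mean
  s1 <- score_samples(co, list(one = "g0001"))
  expect_equal(s1$score[s1$sample == "B2"],
               co$expression["g0001", "B2"] - 8)
  # log2-mean equals log2 of the geometric mean of linear values
  lin <- 2^co$expression[c("g0001", "g0002"), "B1"]
  geo <- log2(prod(lin)^(1 / 2))
  raw_ctrl <- mean(log2(2^co$expression[c("g0001", "g0002"), c("N1", "N2")]))
  expect_equal(sc$score[sc$sample == "B1"], geo - raw_ctrl, tolerance = 1e-9)
})

test_that("scores are shift-equivariant and order/duplication invariant", {
  co <- make_toy_bulk(case_shift = c(0.5, -0.2, 1.3))
  sets <- list(inj = c("g0001", "g0002"))
  sc <- score_samples(co, sets)
  # shifting marker genes everywhere (cases AND controls) changes nothing
  co2 <- co
  co2$expression[c("g0001", "g0002"), ] <-
    co2$expression[c("g0001", "g0002"), ] + 3
  expect_equal(score_samples(co2, sets)$score, sc$score)
  # shifting only one case moves that score by exactly the shift
  co3 <- co
  co3$expression[c("g0001", "g0002"), "B1"] <-
    co3$expression[c("g0001", "g0002"), "B1"] + 0.7
  sc3 <- score_samples(co3, sets)
  expect_equal(sc3$score[sc3$sample == "B1"] - sc$score[sc$sample == "B1"],
               0.7)
  # gene order and duplicates do not matter
  expect_equal(score_samples(co, list(inj = c("g0002", "g0001", "g0001")))$score,
               sc$score)
})

test_that("missing genes are tolerated to 50% coverage, then refused", {
  co <- make_toy_bulk()
  expect_message(
    sc <- score_samples(co, list(inj = c("g0001", "g0002", "nope", "nah"))),
    "coverage")
  expect_equal(unique(sc$coverage), 0.5)
  expect_error(score_samples(co, list(inj = c("g0001", "x", "y", "z"))),
               "coverage")
  expect_error(score_samples(co, list(inj = c("x", "y"))), "no genes")
})

test_that("median stratification uses the full cohort and sends ties below", {
  sc <- tibble::tibble(sample = paste0("B", 1:4), set = "s",
                       score = c(0, 1, 2, 3), is_control = FALSE)
  st <- median_stratify(sc)
  expect_equal(st$stratum, c("below", "below", "above", "above"))
  # all equal -> everything below
  sc$score <- rep(2, 4)
  expect_true(all(median_stratify(sc)$stratum == "below"))
  # full-population median: a diagnosis subgroup need not split in half
  co <- make_toy_bulk(case_shift = c(2, -1, 3))   # TCMR scores 2 and 3
  scc <- score_samples(co, list(inj = c("g0001", "g0002")))
  st2 <- median_stratify(scc, co)
  tc <- dplyr::inner_join(st2, co$clinical, by = c(sample = "sample_id"))
  expect_equal(sum(tc$stratum == "above" & tc$diagnosis == "TCMR"), 1)
  expect_equal(sum(tc$stratum == "below" & tc$diagnosis == "TCMR"), 1)
})

test_that("probe collapse averages probes and handles edge cases", {
  expr <- tibble::tibble(probe = c("p1", "p2", "p3", "p4"),
                         s1 = c(4, 6, 5, 9), s2 = c(2, 4, 3, 7))
  map <- tibble::tibble(probe = c("p1", "p2", "p3"),
                        gene = c("gA", "gA", "gB"))
  expect_message(out <- probe_collapse(expr, map), "unmapped")
  expect_equal(out$s1[out$gene == "gA"], 5)   # mean of 4 and 6
  expect_equal(out$s1[out$gene == "gB"], 5)   # single probe unchanged
  # multi-mapped probe contributes to both genes, with a warning
  map2 <- tibble::tibble(probe = c("p1", "p1"), gene = c("gA", "gB"))
  expect_warning(out2 <- probe_collapse(expr[1, ], map2), "multiple")
  expect_equal(out2$s1, c(4, 4))
  expect_error(probe_collapse(expr, map[0, ]), "empty")
})

test_that("longitudinal trajectories follow the resolution selection rule", {
  genes <- sprintf("g%04d", 1:2)
  base <- c(8, 8)
  samples <- c("A1", "A2", "A3",   # TCMR -> NR -> NR (kept)
               "B1", "B2",         # TCMR -> TCMR (final not NR: excluded)
               "C1",               # single biopsy: excluded
               "N1")
  expr <- cbind(base + 1.5, base + 1.5, base + 1.5,
                base + 2, base + 2, base, base)
  dimnames(expr) <- list(genes, samples)
  clinical <- tibble::tibble(
    sample_id = samples[1:6],
    patient_id = c("PA", "PA", "PA", "PB", "PB", "PC"),
    biopsy_index = c(1L, 2L, 3L, 1L, 2L, 1L),
    diagnosis = c("TCMR", "NR", "NR", "TCMR", "TCMR", "TCMR"),
    time_months = 10, event = 0L)
  co <- bulk_cohort(expr, clinical, controls = "N1")
  sc <- score_samples(co, list(inj = genes))
  tr <- longitudinal_trajectories(sc, co)
  expect_setequal(unique(tr$patient_id), "PA")
  expect_equal(tr$biopsy_index, 1:3)
  expect_equal(tr$score, rep(1.5, 3))   # constant expression -> flat series
})

test_that("generator persistence shows up in scored trajectories", {
  cfg <- sim_config(seed = 17, n_genes = 300,
                    bulk = bulk_config(n_samples = 120, fixed_score = 1.5,
                                       n_followup = 8))
  sets <- list(inj = sprintf("g%04d", 1:20))
  sim <- simulate_bulk_cohort(cfg, sets)
  sc <- score_samples(sim$cohort, sets)
  tr <- longitudinal_trajectories(sc, sim$cohort)
  expect_gt(nrow(tr), 0)
  post <- tr$score[tr$biopsy_index > 1]
  expect_lt(max(abs(post - 1.5)), 0.3)   # score persists after resolution
})
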