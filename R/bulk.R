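#' Construct a bulk transcriptomic cohort
#'
#' Log2-scale expression (microarray-like) together with a clinical table and
#' the set of control ("nephrectomy") samples used as the scoring baseline.
#'
#' @param expression Genes x samples numeric matrix of log2 expression with
#'   gene row names, or a tibble whose first column (`gene`) holds gene ids.
#' @param clinical Tibble with columns `sample_id`, `patient_id`,
#'   `biopsy_index`, `diagnosis` (`NR`, `TCMR`, `ABMR`, `Mixed`),
#'   `time_months`, `event` (0/1; NA allowed for follow-up biopsies).
#' @param controls Character vector of control sample ids (columns of
#'   `expression`).
#' @return An object of class `bulk_cohort`.
#' @export
bulk_cohort <- function(expression, clinical, controls) {
  if (is.data.frame(expression)) {
    genes <- expression[[1]]
    expression <- as.matrix(expression[, -1, drop = FALSE])
    rownames(expression) <- genes
  }
  clinical <- as_tibble(clinical)
  need <- c("sample_id", "patient_id", "biopsy_index", "diagnosis",
            "time_months", "event")
  assert_that(all(need %in% names(clinical)),
              paste("clinical table must contain:", paste(need, collapse = ", ")))
  assert_that(all(clinical$sample_id %in% colnames(expression)),
              "every clinical sample must be present in the expression matrix")
  assert_that(all(controls %in% colnames(expression)),
              "every control sample must be present in the expression matrix")
  assert_that(all(is.na(clinical$time_months) | clinical$time_months >= 0),
              "times must be non-negative")
  assert_that(all(is.finite(expression)),
              "expression must be finite log2 values")
  structure(list(expression = expression, clinical = clinical,
                 controls = controls),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("<bulk_cohort> %d genes x %d samples (%d controls, %d clinical rows)\n",
              nrow(x$expression), ncol(x$expression), length(x$controls),
              nrow(x$clinical)))
  invisible(x)
}

#' Simulate a bulk transplant-biopsy cohort with outcome
#'
#' Generates log2 expression for case biopsies and nephrectomy controls. Each
#' marker set gets a per-sample latent score that additively shifts the log2
#' expression of its genes over the control baseline (controls sit at score
#' 0). Graft-loss times are exponential with
#' `log hazard = log(rate0) + sum(beta * u)` where `u` is the standardized
#' latent score; `beta` for the first set is derived from the configured
#' hazard ratio between above- and below-median strata
#' (`beta = qnorm(HR / (1 + HR))` for a standard-normal score), other sets
#' carry no effect. The baseline rate is solved so the expected fraction of
#' events before the censoring horizon matches the configured target;
#' censoring is administrative at the horizon. A configurable number of
#' TCMR-index patients receive two follow-up biopsies resolving to NR with
#' the index score persisting.
#'
#' @param config A [sim_config()] (its `bulk` component and `n_genes`
#'   are used).
#' @param marker_sets Named list of gene-id vectors, or a list of
#'   [`marker_set`][select_markers()] objects.
#' @return A list with `cohort` (a [bulk_cohort()]) and `truth` (latent score
#'   table, `beta` per set, baseline rate).
#' @export
simulate_bulk_cohort <- function(config, marker_sets) {
  stopifnot(inherits(config, "sim_config"))
  sets <- as_gene_sets(marker_sets)
  assert_that(length(sets) >= 1, "need at least one marker set")
  for (nm in names(sets)) {
    assert_that(length(sets[[nm]]) > 0, paste("empty marker set:", nm))
  }
  bk <- config$bulk
  genes <- gene_names(config$n_genes)
  for (nm in names(sets)) {
    assert_that(all(sets[[nm]] %in% genes),
                paste("marker set", nm, "contains genes outside the simulated universe"))
  }

  with_substream(config$seed, "bulk", {
    n <- bk$n_samples
    baseline <- rnorm(config$n_genes, 8, 1.5)
    names(baseline) <- genes
    diagnosis <- sample(names(bk$diagnosis_probs), n, replace = TRUE,
                        prob = bk$diagnosis_probs)
    sample_id <- sprintf("B%04d", seq_len(n))
    patient_id <- sprintf("P%04d", seq_len(n))

    u <- matrix(rnorm(n * length(sets)), n, length(sets),
                dimnames = list(sample_id, names(sets)))
    s <- bk$score_sd * u +
      matrix(bk$diagnosis_shift[diagnosis], n, length(sets))
    if (!is.null(bk$fixed_score)) s[] <- bk$fixed_score

    beta <- setNames(rep(0, length(sets)), names(sets))
    if (bk$hazard_ratio != 1) {
      beta[1] <- qnorm(bk$hazard_ratio / (1 + bk$hazard_ratio))
    }
    lp <- drop(u %*% beta)
    h <- bk$horizon_months
    rate0 <- uniroot(function(lr) {
      mean(1 - exp(-exp(lr + lp) * h)) - bk$event_fraction
    }, c(-20, 5))$root
    t_raw <- rexp(n, rate = exp(rate0 + lp))
    event <- as.integer(t_raw <= h)
    time_months <- pmin(t_raw, h)

    clinical <- tibble(sample_id, patient_id, biopsy_index = 1L,
                       diagnosis, time_months, event)
    score_tab <- tibble(sample = rep(sample_id, length(sets)),
                        set = rep(names(sets), each = n),
                        u = as.vector(u), s = as.vector(s))

    # follow-up biopsies for TCMR-index patients resolving to NR, with the
    # index score persisting
    tcmr <- which(diagnosis == "TCMR")
    fu <- head(tcmr, bk$n_followup)
    fu_clin <- NULL; fu_s <- NULL; fu_id <- character(0)
    if (length(fu) > 0) {
      fu_id <- as.vector(t(outer(sample_id[fu], c("_f2", "_f3"), paste0)))
      fu_clin <- tibble(sample_id = fu_id,
                        patient_id = rep(patient_id[fu], each = 2),
                        biopsy_index = rep(c(2L, 3L), length(fu)),
                        diagnosis = "NR",
                        time_months = NA_real_, event = NA_integer_)
      fu_s <- s[rep(fu, each = 2), , drop = FALSE]
      rownames(fu_s) <- fu_id
      score_tab <- bind_rows(score_tab,
                             tibble(sample = rep(fu_id, length(sets)),
                                    set = rep(names(sets), each = length(fu_id)),
                                    u = NA_real_, s = as.vector(fu_s)))
    }

    ctrl_id <- sprintf("CTRL%02d", seq_len(bk$n_controls))
    all_ids <- c(sample_id, fu_id, ctrl_id)
    s_all <- rbind(s, fu_s,
                   matrix(0, bk$n_controls, length(sets),
                          dimnames = list(ctrl_id, names(sets))))

    expr <- matrix(baseline, config$n_genes, length(all_ids)) +
      matrix(rnorm(config$n_genes * length(all_ids), 0, bk$noise_sd),
             config$n_genes, length(all_ids))
    dimnames(expr) <- list(genes, all_ids)
    for (j in seq_along(sets)) {
      gi <- match(sets[[j]], genes)
      expr[gi, ] <- expr[gi, ] + rep(s_all[, j], each = length(gi))
    }

    clinical <- bind_rows(clinical, fu_clin)
    cohort <- bulk_cohort(expr, clinical, ctrl_id)
    list(cohort = cohort,
         truth = list(scores = score_tab, beta = beta,
                      baseline_rate = exp(rate0), baseline_means = baseline))
  })
}

as_gene_sets <- function(marker_sets) {
  if (inherits(marker_sets, "marker_set")) marker_sets <- list(marker_sets)
  out <- lapply(marker_sets, function(m) {
    if (inherits(m, "marker_set")) m$genes else as.character(m)
  })
  nms <- names(marker_sets) %||% rep("", length(marker_sets))
  for (i in seq_along(out)) {
    if (!nzchar(nms[i] %||% "")) {
      nms[i] <- if (inherits(marker_sets[[i]], "marker_set"))
        marker_sets[[i]]$name else paste0("set", i)
    }
  }
  assert_that(!anyDuplicated(nms), "marker set names must be unique")
  setNames(out, nms)
}
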