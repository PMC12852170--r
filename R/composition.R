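#' Per-sample cell-type composition of a cohort
#'
#' @param cohort A [cell_cohort()].
#' @return A wide tibble: `sample`, `group`, then one proportion column per
#'   cluster; proportions sum to 1 per sample.
#' @export
cell_composition <- function(cohort) {
  stopifnot(inherits(cohort, "cell_cohort"))
  cohort$cells |>
    dplyr::count(.data$sample, .data$group, .data$cluster) |>
    group_by(.data$sample) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    select(-"n") |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "proportion",
                       values_fill = 0)
}

check_composition <- function(composition) {
  num <- vapply(composition, is.numeric, logical(1))
  mat <- as.matrix(composition[, num, drop = FALSE])
  assert_that(all(mat >= 0) && all(mat <= 1),
              "proportions must lie in [0, 1]")
  assert_that(all(abs(rowSums(mat) - 1) < 1e-9),
              "per-sample proportions must sum to 1")
  mat
}

resolve_groups <- function(composition, groups) {
  if (is.data.frame(groups)) {
    g <- groups$group[match(composition$sample, groups$sample)]
  } else if (!is.null(names(groups))) {
    g <- unname(groups[composition$sample])
  } else if ("group" %in% names(composition)) {
    g <- composition$group
  } else {
    g <- groups
  }
  assert_that(!anyNA(g) && length(g) == nrow(composition),
              "could not resolve a group for every sample")
  lv <- unique(g)
  assert_that(length(lv) == 2, "exactly two groups are required")
  assert_that(min(table(g)) >= 2, "need at least 2 samples per group")
  factor(g, levels = lv)
}

#' Student's t-tests on cell-type proportions
#'
#' Per cell type, a two-sided two-sample t-test (pooled variance by default)
#' of the proportions between the two groups, Benjamini-Hochberg adjusted
#' across cell types. Cell types with zero variance in both groups (including
#' types absent everywhere) get t = 0, p = 1 and are flagged.
#'
#' @param composition Wide tibble from [cell_composition()] (columns `sample`,
#'   optionally `group`, then one numeric column per cell type).
#' @param groups Group labels: a `sample`/`group` tibble, a named vector, or
#'   NULL to use the `group` column.
#' @param var_equal Pooled-variance Student's t (default TRUE); FALSE gives
#'   Welch.
#' @return A tibble `cell_type`, `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `padj`, `degenerate`.
#' @export
composition_ttests <- function(composition, groups = NULL, var_equal = TRUE) {
  mat <- check_composition(composition)
  g <- resolve_groups(composition, groups)
  a <- g == levels(g)[1]
  res <- purrr::map_dfr(colnames(mat), function(ct) {
    xa <- mat[a, ct]; xb <- mat[!a, ct]
    if (sd(c(xa, xb)) == 0 || (sd(xa) == 0 && sd(xb) == 0)) {
      return(tibble(cell_type = ct, mean_a = mean(xa), mean_b = mean(xb),
                    statistic = 0, p_value = 1, degenerate = TRUE))
    }
    tt <- t.test(xa, xb, var.equal = var_equal)
    tibble(cell_type = ct, mean_a = mean(xa), mean_b = mean(xb),
           statistic = unname(tt$statistic), p_value = tt$p.value,
           degenerate = FALSE)
  })
  mutate(res, padj = benjamini_hochberg(.data$p_value),
         .after = "p_value")
}

#' Arcsine-transformed moderated t-tests on proportions
#'
#' Proportions are variance-stabilized with `y = asin(sqrt(p))`, then each
#' cell type is compared between the two groups with an empirical-Bayes
#' moderated t: the residual variance is shrunk towards a prior variance
#' whose scale and degrees of freedom are estimated across cell types by
#' method of moments (matching the scaled-F marginal distribution of the
#' per-type variances); the moderated t has `residual df + prior df` degrees
#' of freedom. `prior_df = 0` disables moderation (ordinary t on transformed
#' values); `prior_df = Inf` uses the prior variance alone.
#'
#' @inheritParams composition_ttests
#' @param prior_df Optional prior degrees-of-freedom override.
#' @return A tibble `cell_type`, `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `padj`, `df`, `prior_df`, `prior_var`.
#' @export
arcsin_moderated_ttest <- function(composition, groups = NULL,
                                   prior_df = NULL) {
  mat <- check_composition(composition)
  g <- resolve_groups(composition, groups)
  a <- g == levels(g)[1]
  y <- asin(sqrt(mat))
  n1 <- sum(a); n2 <- sum(!a)
  d_r <- n1 + n2 - 2
  assert_that(d_r >= 1, "need residual degrees of freedom >= 1")

  m1 <- colMeans(y[a, , drop = FALSE])
  m2 <- colMeans(y[!a, , drop = FALSE])
  ss <- vapply(seq_len(ncol(y)), function(j) {
    sum((y[a, j] - m1[j])^2) + sum((y[!a, j] - m2[j])^2)
  }, numeric(1))
  s2 <- ss / d_r

  if (is.null(prior_df)) {
    mom <- fit_variance_prior(s2, d_r)
    d0 <- mom$prior_df; s02 <- mom$prior_var
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(prior_df) && prior_df > 0)
      mean(s2) else mean(s2)
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d_r * s2) / (d0 + d_r)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, (m1 - m2) / se, 0)
  df <- d_r + d0
  p <- ifelse(se > 0, 2 * pt(-abs(tt), df = df), 1)
  tibble(cell_type = colnames(mat), mean_a = m1, mean_b = m2,
         statistic = tt, p_value = p, padj = benjamini_hochberg(p),
         df = df, prior_df = d0, prior_var = s02)
}

# method-of-moments fit of the scaled-inverse-chi-square variance prior:
# marginally s2/s0^2 ~ F(d_r, d0); match mean and variance of s2
fit_variance_prior <- function(s2, d_r) {
  m <- mean(s2)
  v <- var(s2)
  if (!is.finite(v) || v <= 0 || m <= 0) {
    return(list(prior_df = Inf, prior_var = m))
  }
  cv2 <- v / m^2
  denom <- cv2 * d_r - 2
  if (denom <= 0) {
    return(list(prior_df = Inf, prior_var = m))
  }
  d0 <- (4 * cv2 * d_r + 2 * d_r - 4) / denom
  if (d0 <= 4) d0 <- 4.001   # keep the F variance finite
  s02 <- m * (d0 - 2) / d0
  list(prior_df = d0, prior_var = s02)
}
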