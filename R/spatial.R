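# min distance from every cell to any anchor cell (self-pairing excluded),
# computed in blocks to bound memory
min_dist_to_anchors <- function(cells, anchor_rows, block = 2000L) {
  n <- nrow(cells)
  ax <- cells$x_um[anchor_rows]
  ay <- cells$y_um[anchor_rows]
  md <- rep(Inf, n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(cells$x_um[rows]^2 + cells$y_um[rows]^2, ax^2 + ay^2, "+") -
      2 * (cells$x_um[rows] %o% ax + cells$y_um[rows] %o% ay)
    d2[d2 < 0] <- 0
    self <- cbind(match(anchor_rows, rows), seq_along(anchor_rows))
    self <- self[!is.na(self[, 1]), , drop = FALSE]
    if (nrow(self) > 0) d2[self] <- Inf
    md[rows] <- sqrt(apply(d2, 1, min))
  }
  md
}

#' Distance-binned co-occurrence of two cell types
#'
#' For each distance `d` on the grid, computes the fraction of query-type
#' cells among all cells lying within Euclidean distance `<= d` of any
#' anchor-type cell (anchor self-pairs excluded), divided by the query type's
#' marginal fraction in the sample. A ratio of 1 means the query type is found
#' near anchors no more than expected under spatial randomness; values above
#' 1 indicate enrichment, below 1 depletion.
#'
#' @param cells Tibble for one sample: `cell_id`, `x_um`, `y_um`, `cell_type`.
#' @param anchor,query Cell-type labels.
#' @param grid Strictly increasing vector of positive distances (um); default
#'   5 to 50 um in steps of 5.
#' @param per_ring Count neighbors in half-open rings `(d_prev, d]` instead of
#'   cumulatively within `<= d` (default FALSE).
#' @param include_anchors Count anchor-type cells in the neighbor pool
#'   (self-pairs always excluded; default TRUE). When FALSE, anchors are
#'   dropped from both the neighbor pool and the marginal.
#' @return A tibble `anchor`, `query`, `sample_id`, `distance`, `n_neighbors`,
#'   `n_query_neighbors`, `ratio` (NaN where no cell lies within `d` of an
#'   anchor).
#' @export
cooccurrence_curve <- function(cells, anchor, query,
                               grid = seq(5, 50, by = 5),
                               per_ring = FALSE, include_anchors = TRUE) {
  cells <- as_tibble(cells)
  assert_that(all(grid > 0) && all(diff(grid) > 0),
              "distance grid must be positive and strictly increasing")
  assert_that(all(is.finite(cells$x_um)) && all(is.finite(cells$y_um)),
              "coordinates must be finite")
  anchor_rows <- which(cells$cell_type == anchor)
  assert_that(length(anchor_rows) > 0,
              paste("no anchor cells of type", anchor))
  sample_id <- if ("sample_id" %in% names(cells)) cells$sample_id[1] else NA_character_

  md <- min_dist_to_anchors(cells, anchor_rows)
  pool <- if (include_anchors) rep(TRUE, nrow(cells)) else
    cells$cell_type != anchor
  n_query <- sum(cells$cell_type == query & pool)
  marginal <- n_query / sum(pool)

  lower <- if (per_ring) c(-Inf, grid[-length(grid)]) else rep(-Inf, length(grid))
  res <- purrr::map_dfr(seq_along(grid), function(i) {
    within <- pool & md <= grid[i] & md > lower[i]
    denom <- sum(within)
    num <- sum(within & cells$cell_type == query)
    ratio <- if (denom == 0) NaN
    else if (n_query == 0) 0
    else (num / denom) / marginal
    tibble(distance = grid[i], n_neighbors = denom,
           n_query_neighbors = num, ratio = ratio)
  })
  mutate(res, anchor = anchor, query = query, sample_id = sample_id,
         .before = 1)
}

#' Direct-neighbor enrichment test across samples
#'
#' For each (anchor, query) pair, computes the per-sample co-occurrence ratio
#' at the direct-neighbor threshold (25 um by default) in the tested group and
#' tests the ratios against 1 with a two-sided one-sample t-test;
#' Benjamini-Hochberg correction is applied across all pairs tested in the
#' call.
#'
#' @param cells Tibble over all samples: `cell_id`, `x_um`, `y_um`,
#'   `cell_type`, `sample_id`, `group`.
#' @param pairs Tibble with columns `anchor`, `query`.
#' @param threshold Direct-neighbor distance in um (default 25).
#' @param group Group whose samples are tested (default `"allogeneic"`); NULL
#'   tests all samples.
#' @param per_ring,include_anchors Passed to [cooccurrence_curve()].
#' @return A tibble `anchor`, `query`, `n_samples`, `mean_ratio`, `statistic`,
#'   `p_value`, `padj`, `direction`, `tested`, `reason`, plus a
#'   `sample_ratios` list-column.
#' @export
direct_neighbor_test <- function(cells, pairs, threshold = 25,
                                 group = "allogeneic",
                                 per_ring = FALSE, include_anchors = TRUE) {
  cells <- as_tibble(cells)
  if (!is.null(group)) {
    assert_that("group" %in% names(cells), "cells table lacks a group column")
    cells <- filter(cells, .data$group == .env$group)
    assert_that(nrow(cells) > 0, "no cells in the requested group")
  }
  split_cells <- split(cells, cells$sample_id)

  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    ratios <- vapply(split_cells, function(s) {
      if (!pairs$anchor[i] %in% s$cell_type) return(NA_real_)
      cooccurrence_curve(s, pairs$anchor[i], pairs$query[i],
                         grid = threshold, per_ring = per_ring,
                         include_anchors = include_anchors)$ratio
    }, numeric(1))
    ok <- is.finite(ratios)
    if (sum(ok) < 2) {
      return(tibble(anchor = pairs$anchor[i], query = pairs$query[i],
                    n_samples = sum(ok), mean_ratio = mean(ratios[ok]),
                    statistic = NA_real_, p_value = NA_real_,
                    direction = NA_character_, tested = FALSE,
                    reason = "fewer than 2 finite per-sample ratios",
                    sample_ratios = list(ratios)))
    }
    r <- ratios[ok]
    if (sd(r) == 0) {
      stat <- if (mean(r) == 1) 0 else NA_real_
      p <- if (mean(r) == 1) 1 else NA_real_
      if (is.na(p)) {
        return(tibble(anchor = pairs$anchor[i], query = pairs$query[i],
                      n_samples = length(r), mean_ratio = mean(r),
                      statistic = NA_real_, p_value = NA_real_,
                      direction = ifelse(mean(r) > 1, "enrichment", "depletion"),
                      tested = FALSE, reason = "zero variance across samples",
                      sample_ratios = list(ratios)))
      }
      tt <- list(statistic = stat, p.value = p)
    } else {
      tt <- t.test(r, mu = 1)
    }
    tibble(anchor = pairs$anchor[i], query = pairs$query[i],
           n_samples = length(r), mean_ratio = mean(r),
           statistic = unname(tt$statistic), p_value = tt$p.value,
           direction = if (mean(r) >= 1) "enrichment" else "depletion",
           tested = TRUE, reason = NA_character_,
           sample_ratios = list(ratios))
  })
  res$padj <- NA_real_
  res$padj[res$tested] <- benjamini_hochberg(res$p_value[res$tested])
  dplyr::relocate(res, "padj", .after = "p_value")
}
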