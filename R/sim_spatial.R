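#' Simulate a segmented-cell spatial sample
#'
#' Places cells in a square field by a homogeneous Poisson process and labels
#' them with the configured cell types. For every (anchor, query) pair with
#' enrichment ratio `rho != 1`, the query type is redistributed relative to
#' the union U of niche-radius discs around the anchor cells: a fraction
#' `pi_B = rho * m / (N - rho * n_B)` of query cells is placed uniformly
#' inside U and the rest uniformly outside, where `m` is the exactly counted
#' number of non-query cells within the niche radius of an anchor (anchor
#' self-pairs excluded) and `N`, `n_B` are the total and query cell counts.
#' By construction the expected direct-neighbor co-occurrence ratio at the
#' niche radius equals `rho`; `rho < 1` thins the query type out of U
#' (hard-core depletion), `rho = 0` excludes it entirely.
#'
#' @param config A [sim_config()] (its `spatial` component is used).
#' @param sample_id Sample identifier written into the output table.
#' @param group Group label (default `"allogeneic"`).
#' @return A list with `cells` (tibble `cell_id`, `x_um`, `y_um`, `cell_type`,
#'   `sample_id`, `group`) and `truth` (the pair table with the achievable
#'   placement fraction actually used).
#' @export
simulate_spatial_sample <- function(config, sample_id, group = "allogeneic") {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$spatial
  area <- sp$field_size_um^2
  assert_that(sp$density_cells_per_um2 * area >= 100,
              "expected cell count (density x area) must be >= 100")

  with_substream(config$seed, paste0("spatial:", sample_id), {
    n_total <- rpois(1, sp$density_cells_per_um2 * area)
    types <- sp$cell_types$type
    n_by_type <- as.vector(rmultinom(1, n_total, sp$cell_types$proportion))
    names(n_by_type) <- types
    absent <- types[n_by_type == 0]
    if (length(absent) > 0) {
      warn(paste("requested cell type(s) absent from simulated sample:",
                 paste(absent, collapse = ", ")))
    }

    L <- sp$field_size_um
    r <- sp$niche_radius_um
    enriched <- sp$pairs[sp$pairs$rho != 1 &
                           sp$pairs$anchor %in% types &
                           sp$pairs$query %in% types, , drop = FALSE]
    free_types <- setdiff(types, enriched$query)

    type <- rep(free_types, n_by_type[free_types])
    x <- runif(length(type), 0, L)
    y <- runif(length(type), 0, L)

    truth <- mutate(sp$pairs, pi_in = NA_real_)
    for (i in seq_len(nrow(enriched))) {
      a_type <- enriched$anchor[i]
      q_type <- enriched$query[i]
      rho <- enriched$rho[i]
      n_b <- n_by_type[[q_type]]
      if (n_b == 0) next
      anchors <- tibble(cell_id = which(type == a_type),
                        x_um = x[type == a_type], y_um = y[type == a_type])
      if (nrow(anchors) == 0) {
        # no anchors: nothing to co-localize with, fall back to CSR
        type <- c(type, rep(q_type, n_b))
        x <- c(x, runif(n_b, 0, L)); y <- c(y, runif(n_b, 0, L))
        next
      }
      idx <- neighbor_index(anchors, r)
      in_u <- within_radius_of_any(idx, x, y)
      # anchors within r of themselves do not count (self-pairing excluded):
      # recount anchors against the other anchors only
      a_rows <- which(type == a_type)
      for (j in a_rows) {
        others <- anchors[anchors$x_um != x[j] | anchors$y_um != y[j], ]
        in_u[j] <- nrow(others) > 0 &&
          any((others$x_um - x[j])^2 + (others$y_um - y[j])^2 <= r^2)
      }
      m_fixed <- sum(in_u)
      n_after <- length(type) + n_b
      pi_in <- rho * m_fixed / (n_after - rho * n_b)
      pi_in <- min(max(pi_in, 0), 1)
      truth$pi_in[truth$anchor == a_type & truth$query == q_type] <- pi_in
      n_in <- round(pi_in * n_b)
      pts_in <- sample_region(idx, n_in, L, inside = TRUE)
      pts_out <- sample_region(idx, n_b - n_in, L, inside = FALSE)
      type <- c(type, rep(q_type, n_b))
      x <- c(x, pts_in$x, pts_out$x)
      y <- c(y, pts_in$y, pts_out$y)
    }

    ord <- sample.int(length(type))   # shuffle so row order carries no signal
    cells <- tibble(
      cell_id = sprintf("%s_c%05d", sample_id, seq_along(type)),
      x_um = x[ord], y_um = y[ord], cell_type = type[ord],
      sample_id = sample_id, group = group
    )
    list(cells = cells, truth = truth)
  })
}

# rejection-sample n uniform points inside (or outside) the union of discs
# covered by a neighbor_index
sample_region <- function(index, n, L, inside = TRUE) {
  if (n <= 0) return(list(x = numeric(0), y = numeric(0)))
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < 10000L) {
    m <- max(2L * (n - length(xs)), 100L)
    cx <- runif(m, 0, L); cy <- runif(m, 0, L)
    ok <- within_radius_of_any(index, cx, cy)
    if (!inside) ok <- !ok
    xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
    tries <- tries + 1L
  }
  assert_that(length(xs) >= n,
              "could not place cells in the requested region (region too small)")
  list(x = xs[seq_len(n)], y = ys[seq_len(n)])
}
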