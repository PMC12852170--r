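#' Build a radius-query index over a segmented-cell table
#'
#' Grid-bucket spatial index supporting "all cells within distance <= r of
#' cell c" queries with results identical to brute-force enumeration and
#' deterministic ordering by cell id.
#'
#' @param cells Tibble with columns `cell_id`, `x_um`, `y_um`.
#' @param radius Query radius in micrometers (> 0).
#' @return An object of class `neighbor_index`.
#' @export
neighbor_index <- function(cells, radius) {
  cells <- as_tibble(cells)
  assert_that(radius > 0, "radius must be positive")
  assert_that(all(is.finite(cells$x_um)) && all(is.finite(cells$y_um)),
              "coordinates must be finite")
  assert_that(!anyDuplicated(cells$cell_id), "cell ids must be unique")
  gx <- floor(cells$x_um / radius)
  gy <- floor(cells$y_um / radius)
  key <- paste(gx, gy)
  structure(list(cells = cells, radius = radius, gx = gx, gy = gy,
                 buckets = split(seq_len(nrow(cells)), key)),
            class = "neighbor_index")
}

bucket_candidates <- function(index, gx, gy) {
  keys <- as.vector(outer(gx + (-1:1), gy + (-1:1),
                          function(a, b) paste(a, b)))
  unlist(index$buckets[keys], use.names = FALSE)
}

#' Query all cells within the index radius of a cell
#'
#' @param index A [neighbor_index()].
#' @param cell_id Id of the focal cell (must be in the indexed table).
#' @param include_self Include the focal cell itself (default FALSE).
#' @return Character vector of neighbor cell ids, sorted by cell id.
#' @export
neighbors_within <- function(index, cell_id, include_self = FALSE) {
  i <- match(cell_id, index$cells$cell_id)
  assert_that(!is.na(i), paste("unknown cell id:", cell_id))
  cand <- bucket_candidates(index, index$gx[i], index$gy[i])
  d2 <- (index$cells$x_um[cand] - index$cells$x_um[i])^2 +
    (index$cells$y_um[cand] - index$cells$y_um[i])^2
  hit <- cand[d2 <= index$radius^2]
  if (!include_self) hit <- setdiff(hit, i)
  sort(index$cells$cell_id[hit])
}

# TRUE for each (x, y) point lying within <= radius of any indexed cell
within_radius_of_any <- function(index, x, y) {
  r2 <- index$radius^2
  vapply(seq_along(x), function(j) {
    cand <- bucket_candidates(index, floor(x[j] / index$radius),
                              floor(y[j] / index$radius))
    if (length(cand) == 0) return(FALSE)
    any((index$cells$x_um[cand] - x[j])^2 +
          (index$cells$y_um[cand] - y[j])^2 <= r2)
  }, logical(1))
}
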