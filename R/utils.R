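#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   left_join bind_rows desc n across all_of row_number
#' @importFrom stats median pnorm pt qnorm rnorm rnbinom runif rexp rbinom
#'   p.adjust prcomp sd var t.test cor.test setNames uniroot pchisq rmultinom
#' @importFrom utils combn head
NULL

# Deterministic 32-bit substream seed derived from a root seed and a stream
# name, so each generator (cells / spatial / bulk / ...) can be re-run
# independently of the others under one root seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# squared Euclidean cross-distances between rows of a and rows of b,
# computed blockwise to bound memory on large embeddings
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
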