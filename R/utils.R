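#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds. Lehmer-style step keeps all arithmetic
# exact in doubles (< 2^53) and the result inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  a <- as.numeric(seed) %% 2147483647
  h <- (a * 48271) %% 2147483647
  as.integer((h + as.numeric(index) * 104729) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Reflect an integer index into [1, n] (mirror boundary, no repeated edge).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n - 2L
  r <- (i - 1L) %% period
  r <- ifelse(r >= n, period - r, r)
  r + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b binary arrays (0/1 or logical) on the same grid.
#' @return `2|A∩B| / (|A|+|B|)`; defined as 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- a != 0
  b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

`%||%` <- function(x, y) if (is.null(x)) y else x
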