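#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Largest-remainder rounding to integer counts
#'
#' Rounds a non-negative vector to integers that sum exactly to `total`,
#' assigning the leftover units to the largest fractional remainders
#' (ties resolved by position).
#'
#' @param x numeric vector of non-negative quotas.
#' @param total integer the result must sum to; defaults to `round(sum(x))`.
#' @return integer vector, same length as `x`, summing to `total`.
#' @export
largest_remainder <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= -1e-9), total >= 0)
  x <- pmax(x, 0)
  if (sum(x) == 0) {
    out <- integer(length(x))
    if (total > 0) out[seq_len(total)] <- 1L  # degenerate: spread arbitrarily
    return(out)
  }
  q <- x / sum(x) * total
  base <- floor(q)
  need <- total - sum(base)
  if (need > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(need)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Moving-window sum over a matrix with truncated (non-wrapping) edges.
# radius r gives a (2r+1) x (2r+1) window; computed with cumulative sums.
win_sum <- function(m, r) {
  if (r <= 0) return(m)
  n <- nrow(m); p <- ncol(m)
  cs <- apply(m, 2, cumsum)
  hi <- pmin(seq_len(n) + r, n)
  lo <- seq_len(n) - r                       # rows below 1 contribute 0
  cs0 <- rbind(0, cs)
  rw <- cs0[hi + 1L, , drop = FALSE] - cs0[pmax(lo, 1L), , drop = FALSE]
  cs2 <- t(apply(rw, 1, cumsum))
  if (n == 1L) cs2 <- matrix(cs2, nrow = 1L)
  hj <- pmin(seq_len(p) + r, p)
  lj <- seq_len(p) - r
  cs20 <- cbind(0, cs2)
  cs20[, hj + 1L, drop = FALSE] - cs20[, pmax(lj, 1L), drop = FALSE]
}

round2 <- function(x) round(x, 2)
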