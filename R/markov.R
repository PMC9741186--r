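#' Project class areas forward with a Markov transition matrix
#'
#' Multiplies the area row-vector by the transition matrix `steps` times.
#' Total area is conserved for any row-stochastic matrix; the output epoch
#' label is advanced by `steps * step_years` when the input epoch parses as
#' a year.
#'
#' @param areas an [area_table()] whose classes match the matrix dimnames.
#' @param p a [transition_matrix()].
#' @param steps positive integer number of applications.
#' @return A projected [area_table()].
#' @examples
#' a <- area_table(c("a", "b"), c(100, 0))
#' p <- transition_matrix(matrix(c(0.5, 0, 0.5, 1), 2,
#'                               dimnames = list(c("a", "b"), c("a", "b"))))
#' project_areas(a, p, steps = 2)  # 25, 75
#' @export
project_areas <- function(areas, p, steps = 1) {
  stopifnot(steps >= 1, steps == round(steps))
  cls <- rownames(p$probs)
  if (!setequal(areas$class, cls))
    stop("class sets of areas and matrix differ")
  v <- areas$area_km2[match(cls, areas$class)]
  for (s in seq_len(steps)) v <- as.numeric(v %*% p$probs)
  ep <- attr(areas, "epoch")
  ep_num <- suppressWarnings(as.numeric(ep))
  if (!is.na(ep_num)) ep <- as.character(ep_num + steps * p$step_years)
  area_table(cls, v, epoch = ep)
}

#' Stationary class-share distribution of a transition matrix
#'
#' Power iteration from the uniform distribution until the L1 change drops
#' below `tol` (default 1e-10) or `max_iter` iterations; non-convergence
#' (e.g. periodic chains) is an error.
#'
#' @param p a [transition_matrix()].
#' @param tol convergence tolerance on the L1 step change.
#' @param max_iter iteration cap.
#' @return Named probability vector `v` with `v = vP` (within 1e-8).
#' @export
stationary_distribution <- function(p, tol = 1e-10, max_iter = 1e6) {
  k <- nrow(p$probs)
  v <- rep(1 / k, k)
  for (it in seq_len(max_iter)) {
    v2 <- as.numeric(v %*% p$probs)
    if (sum(abs(v2 - v)) < tol) {
      names(v2) <- rownames(p$probs)
      return(v2)
    }
    v <- v2
  }
  stop("power iteration did not converge (periodic chain?)")
}
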