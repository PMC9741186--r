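#' Agreement statistics from a square contingency table
#'
#' Computes overall agreement, Cohen's kappa and per-class producer/user
#' agreement from joint class counts (rows = map 1, columns = map 2).
#' When expected agreement equals 1 (both maps constant), kappa is defined
#' as 1 if the maps agree and 0 otherwise.
#'
#' @param counts square non-negative matrix of joint counts or areas.
#' @return A list of class `agreement_report`: `overall_agreement`, `kappa`,
#'   `producer_accuracy`, `user_accuracy`, `n` (grand total).
#' @examples
#' agreement_stats(matrix(c(45, 15, 5, 35), 2))  # kappa = 0.60
#' @export
agreement_stats <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n <= 0) stop("no jointly-valid cells")
  po <- sum(diag(counts)) / n
  pe <- sum(rowSums(counts) * colSums(counts)) / n^2
  kap <- if (abs(1 - pe) < 1e-15) {
    if (po >= 1 - 1e-15) 1 else 0
  } else (po - pe) / (1 - pe)
  prod_acc <- diag(counts) / rowSums(counts)
  user_acc <- diag(counts) / colSums(counts)
  structure(list(overall_agreement = po, kappa = kap,
                 producer_accuracy = prod_acc, user_accuracy = user_acc,
                 n = n),
            class = "agreement_report")
}

#' Cohen's kappa agreement between two categorical maps
#'
#' Cell-wise agreement over jointly-valid cells, chance-corrected with
#' expected agreement from the marginal class shares. The conventional
#' acceptance rule for CA-Markov simulations is kappa > 0.75.
#'
#' @param g1,g2 aligned [landuse_grid()] objects.
#' @return An `agreement_report` (see [agreement_stats()]).
#' @export
kappa_agreement <- function(g1, g2) {
  tab <- cross_tabulate(g1, g2) / g1$cell_size^2
  agreement_stats(unclass(tab))
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement: overall %.4f, kappa %.4f (n = %g)\n",
              x$overall_agreement, x$kappa, x$n))
  invisible(x)
}
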