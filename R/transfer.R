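#' Land-use transfer matrix
#'
#' Origin × destination areas (km²) between two epochs, in scheme order.
#' The diagonal is persistence; off-diagonals are conversions.
#'
#' @param entries square numeric matrix of non-negative areas, with class
#'   names as dimnames.
#' @param origin_epoch,destination_epoch epoch labels.
#' @return A matrix of class `transfer_matrix`.
#' @export
transfer_matrix <- function(entries, origin_epoch = "0",
                            destination_epoch = "1") {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries)) stop("transfer matrix must be square")
  if (any(entries < 0)) stop("transfer areas must be >= 0")
  if (is.null(rownames(entries))) stop("transfer matrix needs class dimnames")
  colnames(entries) <- colnames(entries) %||% rownames(entries)
  structure(entries, class = c("transfer_matrix", "matrix"),
            origin_epoch = as.character(origin_epoch),
            destination_epoch = as.character(destination_epoch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-tabulate two aligned land-use grids
#'
#' Entry (i, j) is cell_size² times the count of cells holding class i in
#' `g1` and class j in `g2`. Cells that are nodata in either epoch are
#' excluded, so marginals cover jointly-valid area only.
#'
#' @param g1,g2 aligned [landuse_grid()] objects (earlier, later epoch).
#' @return A [transfer_matrix()] in km².
#' @export
cross_tabulate <- function(g1, g2) {
  al <- check_alignment(g1, g2)
  if (!al$aligned)
    stop("grids are not aligned: ", paste(al$reasons, collapse = ", "))
  sc <- g1$scheme
  keep <- valid_mask(g1) & valid_mask(g2)
  i <- factor(match(g1$values[keep], sc$codes), levels = seq_len(n_classes(sc)))
  j <- factor(match(g2$values[keep], sc$codes), levels = seq_len(n_classes(sc)))
  tab <- table(i, j) * g1$cell_size^2
  m <- matrix(as.numeric(tab), n_classes(sc),
              dimnames = list(sc$names, sc$names))
  transfer_matrix(m, g1$epoch, g2$epoch)
}

#' Per-class net area change of a transfer matrix
#'
#' Net change of class k = inflow (column sum minus persistence) minus
#' outflow (row sum minus persistence); positive values are net inflow.
#' Nets always sum to zero.
#'
#' @param tm a [transfer_matrix()].
#' @return Named numeric vector of net changes, km².
#' @export
net_change <- function(tm) {
  d <- diag(tm)
  (colSums(tm) - d) - (rowSums(tm) - d)
}

#' Fraction of an origin class converted to a destination class
#'
#' 100 × entry(origin, dest) / origin row total. The denominator is the
#' class's full origin-epoch area including persistence, the convention
#' under which quoted conversion percentages reproduce from transfer tables.
#'
#' @param tm a [transfer_matrix()].
#' @param origin,dest class names.
#' @return Percentage (0–100).
#' @export
conversion_fraction <- function(tm, origin, dest) {
  rt <- sum(tm[origin, ])
  if (rt <= 0) stop("origin class '", origin, "' has zero area")
  100 * tm[origin, dest] / rt
}

#' Row-stochastic transition probability matrix
#'
#' @param probs square matrix with entries in \[0, 1\] and rows summing to 1
#'   (within 1e-9), class names as dimnames.
#' @param step_years number of years one application represents.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(probs, step_years = 10) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) stop("transition matrix must be square")
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]")
  if (any(abs(rowSums(probs) - 1) > 1e-9))
    stop("rows must sum to 1")
  structure(list(probs = probs, step_years = step_years),
            class = "transition_matrix")
}

#' Convert a transfer matrix to transition probabilities
#'
#' P_ij = entry(i, j) / row total i. Rows with zero origin area become
#' identity rows (the class persists), keeping the matrix row-stochastic.
#'
#' @param tm a [transfer_matrix()].
#' @param step_years duration the matrix spans, years.
#' @return A [transition_matrix()].
#' @export
to_probabilities <- function(tm, step_years = 10) {
  rt <- rowSums(tm)
  p <- matrix(as.numeric(tm), nrow(tm), ncol(tm), dimnames = dimnames(tm))
  p <- p / ifelse(rt > 0, rt, 1)
  zero <- which(rt == 0)
  for (k in zero) { p[k, ] <- 0; p[k, k] <- 1 }
  transition_matrix(p, step_years = step_years)
}

#' Write a transfer or transition matrix as CSV with class labels
#' @param m a [transfer_matrix()] or plain labelled matrix.
#' @param path output path.
#' @param totals add a `total` row and column (ignored on read).
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path, totals = FALSE) {
  x <- unclass(as.matrix(m))
  if (totals) {
    x <- rbind(cbind(x, total = rowSums(x)),
               total = c(colSums(x), sum(x)))
  }
  utils::write.csv(data.frame(class = rownames(x), x, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a square labelled matrix from CSV
#'
#' Accepts the output of [write_matrix_csv()]; a `total` row/column, if
#' present, is dropped.
#'
#' @param path CSV path (first column = class labels).
#' @param origin_epoch,destination_epoch labels for the result.
#' @return A [transfer_matrix()].
#' @export
read_transfer_matrix <- function(path, origin_epoch = "0",
                                 destination_epoch = "1") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rn <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- rn
  keep_r <- tolower(rn) != "total"
  keep_c <- tolower(colnames(m)) != "total"
  transfer_matrix(m[keep_r, keep_c, drop = FALSE],
                  origin_epoch, destination_epoch)
}
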