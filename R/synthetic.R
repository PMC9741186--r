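#' Synthetic multi-epoch landscape scenario
#'
#' Defines a reproducible generating process for categorical landscapes:
#' spatially autocorrelated class patches with target proportions, evolved
#' through a known row-stochastic transition matrix, optionally coupled to
#' the local neighborhood composition.
#'
#' The default scenario mimics a six-class provincial landscape dominated
#' by forest, grassland and cropland (shares 0.18 / 0.57 / 0.23 with three
#' minor classes), with mild spatial clustering of transitions.
#'
#' @param rows,cols grid dimensions.
#' @param class_proportions non-negative vector summing to 1 (one entry per
#'   scheme class).
#' @param correlation_length patch smoothing radius in cells (0 = i.i.d.).
#' @param true_matrix the generating [transition_matrix()].
#' @param clustering weight in \[0, 1\] coupling a cell's transition to its
#'   neighborhood composition (0 = independent Markov cells).
#' @param n_epochs number of epochs (>= 2).
#' @param seed integer RNG seed.
#' @param scheme a [category_scheme()].
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(rows = 200, cols = 200,
                               class_proportions = c(0.1813, 0.5721, 0.2291,
                                                     0.0073, 0.0047, 0.0055),
                               correlation_length = 3,
                               true_matrix = default_true_matrix(),
                               clustering = 0.3, n_epochs = 2, seed = 7,
                               scheme = yunnan_scheme()) {
  class_proportions <- class_proportions / sum(class_proportions)
  if (length(class_proportions) != n_classes(scheme))
    stop("need one proportion per scheme class")
  if (any(class_proportions < 0)) stop("proportions must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (n_epochs < 2) stop("need at least two epochs")
  if (clustering < 0 || clustering > 1) stop("clustering must lie in [0, 1]")
  structure(list(rows = rows, cols = cols,
                 class_proportions = class_proportions,
                 correlation_length = correlation_length,
                 true_matrix = true_matrix, clustering = clustering,
                 n_epochs = n_epochs, seed = seed, scheme = scheme),
            class = "synthetic_scenario")
}

#' Default six-class generating matrix (strong persistence, mild exchange)
#' @return A [transition_matrix()].
#' @export
default_true_matrix <- function() {
  nm <- yunnan_scheme()$names
  p <- matrix(0.02, 6, 6, dimnames = list(nm, nm))
  diag(p) <- 0.90
  transition_matrix(p, step_years = 10)
}

# Smooth a gaussian noise field with repeated truncated box blurs.
smooth_field <- function(rows, cols, radius, passes = 3) {
  f <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (radius > 0) {
    ones <- matrix(1, rows, cols)
    for (p in seq_len(passes)) f <- win_sum(f, radius) / win_sum(ones, radius)
  }
  f
}

#' Generate a spatially autocorrelated categorical landscape
#'
#' One smoothed gaussian field per class; cells are assigned by sequential
#' quantile cuts — each class in turn claims its largest-remainder quota of
#' remaining cells in descending order of its field — so realized class
#' counts match the target proportions exactly and patches inherit the
#' fields' correlation length. Bit-reproducible given the scenario seed.
#'
#' @param s a [synthetic_scenario()].
#' @param epoch epoch label for the result.
#' @return A [landuse_grid()] with no nodata cells.
#' @export
generate_landscape <- function(s, epoch = "1") {
  sc <- s$scheme
  K <- n_classes(sc)
  with_seed(s$seed, {
    fields <- lapply(seq_len(K), function(k)
      smooth_field(s$rows, s$cols, s$correlation_length))
    n_cell <- s$rows * s$cols
    quota <- largest_remainder(s$class_proportions, total = n_cell)
    v <- integer(n_cell)
    remaining <- rep(TRUE, n_cell)
    for (k in seq_len(K)) {
      if (quota[k] == 0) next
      idx <- which(remaining)
      take <- idx[order(fields[[k]][idx], decreasing = TRUE)[seq_len(quota[k])]]
      v[take] <- sc$codes[k]
      remaining[take] <- FALSE
    }
    landuse_grid(matrix(v, s$rows, s$cols), cell_size = 1, epoch = epoch,
                 scheme = sc)
  })
}

#' Evolve a landscape one epoch under a known transition process
#'
#' Each cell of class i draws its next class from the mixture
#' `(1 - clustering) * P[i, ] + clustering * q`, where `q` is `P[i, ]`
#' reweighted by the 5×5 neighborhood class composition and renormalized
#' (falling back to `P[i, ]` where the reweighted row has no mass).
#' `clustering = 0` gives independent Markov cells, so cross-tabulating
#' consecutive epochs recovers P up to sampling noise.
#'
#' @param grid a [landuse_grid()].
#' @param p a [transition_matrix()].
#' @param clustering weight in \[0, 1\].
#' @param seed integer RNG seed (NULL = current stream).
#' @return A [landuse_grid()] for the next epoch.
#' @export
evolve_landscape <- function(grid, p, clustering = 0, seed = NULL) {
  sc <- grid$scheme
  K <- n_classes(sc)
  vm <- valid_mask(grid)
  cls <- match(grid$values, sc$codes)
  probs <- p$probs[cls[vm], , drop = FALSE]           # n_valid x K base rows
  if (clustering > 0) {
    comp <- neighborhood_suitability(
      grid, allocation_config(neighborhood_size = 5, persistence_bonus = 0))
    w <- vapply(seq_len(K), function(k) comp[, , k][vm], numeric(sum(vm)))
    q <- probs * w
    rs <- rowSums(q)
    ok <- rs > 0
    q[ok, ] <- q[ok, ] / rs[ok]
    q[!ok, ] <- probs[!ok, ]
    probs <- (1 - clustering) * probs + clustering * q
  }
  with_seed(seed, {
    u <- stats::runif(nrow(probs))
    cum <- t(apply(probs, 1, cumsum))
    nxt <- rowSums(u > cum) + 1L
    nxt[nxt > K] <- K
    v <- grid$values
    v[vm] <- sc$codes[nxt]
    ep <- suppressWarnings(as.numeric(grid$epoch))
    ep <- if (is.na(ep)) grid$epoch else as.character(ep + p$step_years)
    landuse_grid(v, cell_size = grid$cell_size, epoch = ep, scheme = sc,
                 xll = grid$xll, yll = grid$yll, crs = grid$crs)
  })
}

#' Generate a multi-epoch series with its generating matrix
#'
#' [generate_landscape()] followed by `n_epochs - 1` applications of
#' [evolve_landscape()], with per-epoch seeds derived from the scenario
#' seed. Returns the grids alongside the true matrix for recovery tests.
#'
#' @param s a [synthetic_scenario()].
#' @return List with `grids` (list of [landuse_grid()]) and `true_matrix`.
#' @export
make_series <- function(s) {
  g <- generate_landscape(s, epoch = "1")
  grids <- vector("list", s$n_epochs)
  grids[[1]] <- g
  for (e in seq_len(s$n_epochs - 1)) {
    grids[[e + 1]] <- evolve_landscape(grids[[e]], s$true_matrix,
                                       clustering = s$clustering,
                                       seed = s$seed + e)
  }
  list(grids = grids, true_matrix = s$true_matrix)
}
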