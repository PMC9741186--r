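#' Configuration for cellular-automata allocation
#'
#' @param neighborhood_size odd window edge length in cells (>= 3).
#' @param iterations_per_step number of allocation rounds per Markov step;
#'   each round moves an equal share of the step's net change, letting
#'   suitability (recomputed every round) steer growth along patch edges.
#' @param seed integer RNG seed for tie-breaking (NULL = current stream).
#' @param persistence_bonus additive suitability in \[0, 1\] for a cell
#'   keeping its current class.
#' @return A list of class `allocation_config`.
#' @export
allocation_config <- function(neighborhood_size = 5, iterations_per_step = 10,
                              seed = NULL, persistence_bonus = 0.2) {
  if (neighborhood_size < 3 || neighborhood_size %% 2 != 1)
    stop("neighborhood_size must be odd and >= 3")
  if (iterations_per_step < 1) stop("iterations_per_step must be >= 1")
  if (persistence_bonus < 0 || persistence_bonus > 1)
    stop("persistence_bonus must lie in [0, 1]")
  structure(list(neighborhood_size = as.integer(neighborhood_size),
                 iterations_per_step = as.integer(iterations_per_step),
                 seed = seed, persistence_bonus = persistence_bonus),
            class = "allocation_config")
}

#' Neighborhood suitability stack
#'
#' Suitability of class k at a cell is the fraction of non-nodata cells of
#' class k within the (truncated) window centered on the cell, plus the
#' persistence bonus if the cell currently holds k, clipped to \[0, 1\].
#' Nodata cells get NA suitability for every class.
#'
#' @param grid a [landuse_grid()].
#' @param config an [allocation_config()].
#' @return 3-d array `[rows, cols, classes]` with values in \[0, 1\].
#' @export
neighborhood_suitability <- function(grid, config = allocation_config()) {
  sc <- grid$scheme
  r <- (config$neighborhood_size - 1L) %/% 2L
  vm <- valid_mask(grid)
  denom <- win_sum(vm * 1, r)
  out <- array(NA_real_, c(dim(grid$values), n_classes(sc)),
               dimnames = list(NULL, NULL, sc$names))
  for (k in seq_len(n_classes(sc))) {
    ind <- (grid$values == sc$codes[k] & vm) * 1
    s <- win_sum(ind, r) / pmax(denom, 1)
    s <- s + config$persistence_bonus * (grid$values == sc$codes[k])
    s[s > 1] <- 1
    s[!vm] <- NA_real_
    out[, , k] <- s
  }
  out
}

#' Reallocate cells to hit target class areas
#'
#' Targets (km²) are converted to integer cell counts by largest-remainder
#' rounding over the grid's non-nodata cells. Growing classes claim cells
#' in descending suitability from the cells of shrinking classes, each
#' shrinking class releasing at most its surplus; classes whose count does
#' not change keep all their cells, and cells of growing classes are never
#' taken. Exact ties are broken uniformly at random under the config seed,
#' so runs are reproducible.
#'
#' @param grid a [landuse_grid()].
#' @param targets an [area_table()] whose total matches the grid's
#'   non-nodata area to within one cell.
#' @param suitability stack from [neighborhood_suitability()] (computed if
#'   NULL).
#' @param config an [allocation_config()].
#' @return A [landuse_grid()] whose class cell counts equal the rounded
#'   targets exactly.
#' @export
allocate_step <- function(grid, targets, suitability = NULL,
                          config = allocation_config()) {
  sc <- grid$scheme
  if (!setequal(targets$class, sc$names)) stop("target classes do not match scheme")
  if (is.null(suitability)) suitability <- neighborhood_suitability(grid, config)
  vm <- valid_mask(grid)
  n_valid <- sum(vm)
  tgt_area <- targets$area_km2[match(sc$names, targets$class)]
  if (any(tgt_area < 0)) stop("infeasible targets: negative area")
  tot_cells <- sum(tgt_area) / grid$cell_size^2
  if (abs(tot_cells - n_valid) > 1 + 1e-9)
    stop("infeasible targets: total differs from grid area by more than one cell")
  n_tgt <- largest_remainder(tgt_area, total = n_valid)

  with_seed(config$seed, {
    v <- grid$values
    cls_idx <- match(v, sc$codes)            # NA at nodata
    cur <- tabulate(cls_idx[vm], nbins = n_classes(sc))
    delta <- n_tgt - cur
    nr <- nrow(v)
    shrinkers <- which(delta < 0)
    growers <- which(delta > 0)
    pool <- which(vm & cls_idx %in% shrinkers)
    if (length(pool) && length(growers)) {
      cand <- expand.grid(cell = pool, class = growers)
      cand$suit <- suitability[cbind((cand$cell - 1L) %% nr + 1L,
                                     (cand$cell - 1L) %/% nr + 1L,
                                     cand$class)]
      ord <- order(-cand$suit, stats::runif(nrow(cand)))
      need <- integer(n_classes(sc)); need[growers] <- delta[growers]
      cap <- integer(n_classes(sc)); cap[shrinkers] <- -delta[shrinkers]
      taken <- logical(length(v))
      for (i in ord) {
        k <- cand$class[i]; ce <- cand$cell[i]
        k0 <- cls_idx[ce]
        if (need[k] > 0L && cap[k0] > 0L && !taken[ce]) {
          v[ce] <- sc$codes[k]
          need[k] <- need[k] - 1L
          cap[k0] <- cap[k0] - 1L
          taken[ce] <- TRUE
        }
      }
    }
    landuse_grid(v, cell_size = grid$cell_size, epoch = grid$epoch,
                 scheme = sc, xll = grid$xll, yll = grid$yll, crs = grid$crs)
  })
}

#' CA-Markov simulation of future land-use maps
#'
#' Each step projects the current class areas one Markov step and allocates
#' the change spatially: `iterations_per_step` rounds move equal fractions
#' of the step's net change, recomputing neighborhood suitability every
#' round so change accretes along class boundaries. At the end of every
#' step the per-class cell counts equal the largest-remainder-rounded
#' Markov targets exactly.
#'
#' @param grid starting [landuse_grid()].
#' @param p a [transition_matrix()].
#' @param steps number of Markov steps to simulate.
#' @param config an [allocation_config()].
#' @return List of [landuse_grid()]s, one per step.
#' @export
simulate_landuse <- function(grid, p, steps = 1,
                             config = allocation_config()) {
  out <- vector("list", steps)
  cur <- grid
  for (s in seq_len(steps)) {
    start <- class_areas(cur)
    target <- project_areas(start, p, 1)
    R <- config$iterations_per_step
    for (it in seq_len(R)) {
      frac <- it / R
      inter <- area_table(start$class,
                          start$area_km2 +
                            frac * (target$area_km2[match(start$class, target$class)] -
                                      start$area_km2),
                          epoch = attr(target, "epoch"))
      cur <- allocate_step(cur, inter, config = config)
    }
    cur$epoch <- attr(target, "epoch")
    out[[s]] <- cur
  }
  out
}

# Rook-adjacency join count: number of equal-class neighbor pairs.
# Used as a spatial-coherence diagnostic for allocated maps.
#' Same-class join count of a grid (rook adjacency)
#' @param grid a [landuse_grid()].
#' @return Integer count of horizontally/vertically adjacent same-class
#'   non-nodata cell pairs.
#' @export
join_count <- function(grid) {
  v <- grid$values; vm <- valid_mask(grid)
  nr <- nrow(v); nc <- ncol(v)
  h <- sum(v[, -nc] == v[, -1] & vm[, -nc] & vm[, -1])
  vt <- sum(v[-nr, ] == v[-1, ] & vm[-nr, ] & vm[-1, ])
  h + vt
}
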