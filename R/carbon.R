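# Unit conversion: Table-style densities are t/hm2, areas km2. 1 km2 = 100 hm2.
HM2_PER_KM2 <- 100
T_PER_MT <- 1e6  # tonnes per 10^6 t reporting unit

#' Four-pool carbon density table
#'
#' Per-class carbon densities (t/hm²) for the four pools: aboveground
#' biomass, belowground biomass, soil, and dead organic matter. A class's
#' total density is the sum of its four pools.
#'
#' @param class character class names (one row per scheme class).
#' @param above,below,soil,dead non-negative pool densities, t/hm².
#' @return A data.frame of class `carbon_density_table`.
#' @export
carbon_density_table <- function(class, above, below, soil, dead) {
  d <- data.frame(class = as.character(class), above = above, below = below,
                  soil = soil, dead = dead, stringsAsFactors = FALSE)
  if (any(as.matrix(d[-1]) < 0)) stop("densities must be >= 0")
  if (anyDuplicated(d$class)) stop("duplicate class rows")
  class(d) <- c("carbon_density_table", "data.frame")
  d
}

#' Read a density table from CSV (header `class,above,below,soil,dead`)
#' @param path CSV path.
#' @return A [carbon_density_table()].
#' @export
read_density_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "above", "below", "soil", "dead")
  if (!all(need %in% names(d))) stop("expected columns ",
                                     paste(need, collapse = ","))
  carbon_density_table(d$class, d$above, d$below, d$soil, d$dead)
}

#' Total carbon density of a class (four-pool sum)
#' @param dens a [carbon_density_table()].
#' @param cls class name.
#' @return Density in t/hm².
#' @export
class_density <- function(dens, cls) {
  i <- match(cls, dens$class)
  if (any(is.na(i))) stop("unknown class: ", paste(cls[is.na(i)], collapse = ", "))
  dens$above[i] + dens$below[i] + dens$soil[i] + dens$dead[i]
}

#' Carbon stock report from class areas and densities
#'
#' Stock of class i = density_i (t/hm²) × area_i (km²) × 100 (hm²/km²),
#' reported in 10^6 t; the total is the sum over classes and contribution
#' shares are percentages of the total. Full precision is kept throughout;
#' rounding is left to printing.
#'
#' @param areas an [area_table()].
#' @param dens a [carbon_density_table()] covering the same classes.
#' @return A list of class `carbon_stock_report`: `epoch`, `table`
#'   (data.frame with class, area_km2, density_t_hm2, stock_Mt,
#'   contribution_pct) and `total_Mt`.
#' @export
stock_by_class <- function(areas, dens) {
  if (!setequal(areas$class, dens$class))
    stop("class sets of areas and densities differ")
  ci <- class_density(dens, areas$class)
  stock <- ci * areas$area_km2 * HM2_PER_KM2 / T_PER_MT
  total <- sum(stock)
  contrib <- if (total > 0) 100 * stock / total else rep(0, length(stock))
  structure(list(epoch = attr(areas, "epoch") %||% "0",
                 table = data.frame(class = areas$class,
                                    area_km2 = areas$area_km2,
                                    density_t_hm2 = ci,
                                    stock_Mt = stock,
                                    contribution_pct = contrib,
                                    stringsAsFactors = FALSE),
                 total_Mt = total),
            class = "carbon_stock_report")
}

#' @export
print.carbon_stock_report <- function(x, ...) {
  cat(sprintf("carbon stock report [%s]: total %.2f x 10^6 t\n",
              x$epoch, x$total_Mt))
  tb <- x$table
  tb$stock_Mt <- round(tb$stock_Mt, 2)
  tb$contribution_pct <- round(tb$contribution_pct, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Per-cell carbon stock map
#'
#' Each non-nodata cell carries its class's total density times the cell
#' area: density (t/hm²) × cell_size² (km²) × 100 (hm²/km²), i.e. tonnes
#' per cell. Nodata cells are NA.
#'
#' @param grid a [landuse_grid()].
#' @param dens a [carbon_density_table()].
#' @return Numeric matrix (t per cell), same shape as the grid.
#' @export
stock_map <- function(grid, dens) {
  sc <- grid$scheme
  per_class <- class_density(dens, sc$names) * grid$cell_size^2 * HM2_PER_KM2
  idx <- match(grid$values, sc$codes)
  out <- matrix(per_class[idx], nrow(grid$values), ncol(grid$values))
  out[!valid_mask(grid)] <- NA_real_
  out
}

#' Decompose the stock change between two epochs
#'
#' Per-class deltas (later minus earlier, 10^6 t), the total delta, gross
#' decrease/increase (sums of negative and positive deltas), and each
#' declining (rising) class's share of the gross decrease (increase).
#' Shares are 0 when there is no decrease (increase).
#'
#' @param a,b `carbon_stock_report`s for the earlier and later epoch.
#' @return A list of class `stock_change_report`: `table` (class, delta_Mt,
#'   share_of_decrease_pct, share_of_increase_pct), `total_delta_Mt`,
#'   `gross_decrease_Mt`, `gross_increase_Mt`.
#' @export
stock_change <- function(a, b) {
  if (!setequal(a$table$class, b$table$class))
    stop("class sets differ between reports")
  i <- match(a$table$class, b$table$class)
  delta <- b$table$stock_Mt[i] - a$table$stock_Mt
  dec <- -sum(delta[delta < 0]); inc <- sum(delta[delta > 0])
  sh_dec <- ifelse(delta < 0 & dec > 0, 100 * (-delta) / dec, 0)
  sh_inc <- ifelse(delta > 0 & inc > 0, 100 * delta / inc, 0)
  structure(list(table = data.frame(class = a$table$class, delta_Mt = delta,
                                    share_of_decrease_pct = sh_dec,
                                    share_of_increase_pct = sh_inc,
                                    stringsAsFactors = FALSE),
                 total_delta_Mt = sum(delta),
                 gross_decrease_Mt = dec, gross_increase_Mt = inc,
                 from = a$epoch, to = b$epoch),
            class = "stock_change_report")
}

#' Mean total stock over several epoch reports
#' @param reports non-empty list of `carbon_stock_report`s.
#' @return Arithmetic mean of the totals, 10^6 t.
#' @export
mean_total <- function(reports) {
  if (!length(reports)) stop("need at least one report")
  mean(vapply(reports, function(r) r$total_Mt, numeric(1)))
}

#' Climate context for density correction
#'
#' Reference and study-area mean annual temperature (°C) and precipitation
#' (mm), used by [adjust_density_table()].
#'
#' @param ref_temp,ref_precip reference climate.
#' @param study_temp,study_precip study-area climate.
#' @return A list of class `climate_context`.
#' @export
climate_context <- function(ref_temp, ref_precip, study_temp, study_precip) {
  if (ref_precip < 0 || study_precip < 0) stop("precipitation must be >= 0")
  structure(list(ref_temp = ref_temp, ref_precip = ref_precip,
                 study_temp = study_temp, study_precip = study_precip),
            class = "climate_context")
}

#' Climate-adjust a carbon density table (pluggable hook)
#'
#' Scales pools by the ratio of a density proxy evaluated at the study
#' climate to the proxy at the reference climate. `relations$biomass`
#' scales the above, below and dead pools; `relations$soil` scales the
#' soil pool. Each relation is a function `f(temp, precip)` returning a
#' positive proxy; the defaults are identity (ratio 1, table unchanged).
#' This is an explicit preprocessing hook — bundled density tables are
#' treated as already corrected and the hook is never applied silently.
#'
#' @param dens a [carbon_density_table()].
#' @param climate a [climate_context()].
#' @param relations list with functions `biomass` and `soil`.
#' @return A [carbon_density_table()] with scaled pools.
#' @export
adjust_density_table <- function(dens, climate,
                                 relations = list(
                                   biomass = function(temp, precip) 1,
                                   soil = function(temp, precip) 1)) {
  ratio <- function(f) {
    ref <- f(climate$ref_temp, climate$ref_precip)
    if (ref == 0) stop("density proxy is zero at the reference climate")
    f(climate$study_temp, climate$study_precip) / ref
  }
  rb <- ratio(relations$biomass); rs <- ratio(relations$soil)
  carbon_density_table(dens$class, dens$above * rb, dens$below * rb,
                       dens$soil * rs, dens$dead * rb)
}
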