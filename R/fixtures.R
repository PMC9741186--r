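# Bundled case-study tables for a six-class provincial landscape
# (Yunnan Province, 1990-2030): carbon densities, epoch areas and the
# 1990-2020 / 2020-2030 transfer matrices.

extdata <- function(file) {
  p <- system.file("extdata", file, package = "luccarbon")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  p
}

#' Bundled four-pool carbon density table (t/hm²)
#' @return A [carbon_density_table()] with one row per scheme class.
#' @export
yunnan_density_table <- function() read_density_table(extdata("carbon_density_yunnan.csv"))

#' Bundled per-epoch class areas (km²)
#' @param epoch one of `"1990"`, `"2000"`, `"2015"`, `"2018"`, `"2020"`,
#'   or NULL for all epochs.
#' @return An [area_table()], or a named list of them when `epoch` is NULL.
#' @export
yunnan_area_table <- function(epoch = NULL) {
  d <- utils::read.csv(extdata("landuse_area_yunnan.csv"),
                       check.names = FALSE, stringsAsFactors = FALSE)
  epochs <- setdiff(names(d), "class")
  get1 <- function(e) area_table(d$class, d[[e]], epoch = e)
  if (is.null(epoch)) return(stats::setNames(lapply(epochs, get1), epochs))
  if (!epoch %in% epochs) stop("no bundled areas for epoch ", epoch)
  get1(epoch)
}

#' Bundled land-use transfer matrices (km²)
#'
#' Origin rows × destination columns in scheme order. `"1990_2020"` is the
#' observed 1990→2020 matrix; `"2020_2030"` the projected 2020→2030 one.
#'
#' @param period `"1990_2020"` or `"2020_2030"`.
#' @return A [transfer_matrix()].
#' @export
yunnan_transfer <- function(period = c("1990_2020", "2020_2030")) {
  period <- match.arg(period)
  ep <- strsplit(period, "_")[[1]]
  read_transfer_matrix(extdata(paste0("transfer_", period, "_yunnan.csv")),
                       origin_epoch = ep[1], destination_epoch = ep[2])
}
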