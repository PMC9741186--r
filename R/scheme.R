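#' Categorical land-use class scheme
#'
#' A scheme pairs integer raster codes with class labels and designates a
#' nodata sentinel. All grids, transfer matrices and carbon tables in the
#' package are indexed in scheme order.
#'
#' @param codes integer vector of unique class codes.
#' @param names character vector of unique class labels, same length.
#' @param nodata integer sentinel not among `codes` (default -9999).
#' @return An object of class `category_scheme`.
#' @examples
#' category_scheme(1:2, c("forest", "other"))
#' @export
category_scheme <- function(codes, names, nodata = -9999L) {
  codes <- as.integer(codes)
  nodata <- as.integer(nodata)
  if (anyDuplicated(codes)) stop("class codes must be unique")
  if (anyDuplicated(names)) stop("class names must be unique")
  if (length(codes) != length(names)) stop("codes and names differ in length")
  if (nodata %in% codes) stop("nodata code must not be a class code")
  structure(list(codes = codes, names = as.character(names), nodata = nodata),
            class = "category_scheme")
}

#' Six-class provincial land-use scheme
#'
#' The default scheme used by the bundled case-study fixtures: codes 1..6 for
#' cropland, forest land, grassland, water area, construction land and unused
#' land, in that order.
#'
#' @return A `category_scheme` with six classes.
#' @export
yunnan_scheme <- function() {
  category_scheme(1:6, c("cropland", "forest_land", "grassland",
                         "water_area", "construction_land", "unused_land"))
}

n_classes <- function(scheme) length(scheme$codes)

#' @export
print.category_scheme <- function(x, ...) {
  cat("category_scheme:", length(x$codes), "classes, nodata =", x$nodata, "\n")
  print(data.frame(code = x$codes, name = x$names), row.names = FALSE)
  invisible(x)
}
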