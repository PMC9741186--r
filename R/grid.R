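#' Categorical land-use grid
#'
#' A rectangular raster of integer class codes with a cell size in km, an
#' epoch label and a [category_scheme()]. Nodata cells hold the scheme's
#' nodata sentinel. Values are stored row-major with the origin at the
#' top-left, the usual raster convention.
#'
#' @param values integer matrix of class codes (nodata cells hold
#'   `scheme$nodata`).
#' @param cell_size cell edge length in km (> 0).
#' @param epoch epoch label, e.g. `"1990"`.
#' @param scheme a [category_scheme()].
#' @param xll,yll coordinates of the lower-left corner (map units = km).
#' @param crs free-form CRS identifier string.
#' @return An object of class `landuse_grid`.
#' @examples
#' g <- landuse_grid(matrix(1L, 3, 3), cell_size = 1, epoch = "1990",
#'                   scheme = yunnan_scheme())
#' class_areas(g)
#' @export
landuse_grid <- function(values, cell_size = 1, epoch = "0",
                         scheme = yunnan_scheme(), xll = 0, yll = 0, crs = "") {
  if (!is.matrix(values)) stop("values must be a matrix")
  storage.mode(values) <- "integer"
  if (cell_size <= 0) stop("cell_size must be > 0")
  bad <- setdiff(unique(as.vector(values)), c(scheme$codes, scheme$nodata))
  if (length(bad)) {
    i <- which(values == bad[1])[1]
    stop(sprintf("unknown class code %d: %d cell(s), first at row %d col %d",
                 bad[1], sum(values == bad[1]),
                 (i - 1) %% nrow(values) + 1, (i - 1) %/% nrow(values) + 1))
  }
  structure(list(values = values, cell_size = cell_size,
                 epoch = as.character(epoch), scheme = scheme,
                 xll = xll, yll = yll, crs = crs),
            class = "landuse_grid")
}

valid_mask <- function(grid) grid$values != grid$scheme$nodata

#' @export
print.landuse_grid <- function(x, ...) {
  cat(sprintf("landuse_grid [%s]: %d x %d cells, %.3g km cells, %d nodata\n",
              x$epoch, nrow(x$values), ncol(x$values), x$cell_size,
              sum(!valid_mask(x))))
  invisible(x)
}

#' Read a land-use grid from an ESRI ASCII grid file
#'
#' Header NODATA values are mapped to the scheme's nodata code; any other
#' code not in the scheme is rejected with its count and first location.
#'
#' @param path path to a `.asc` file.
#' @param scheme a [category_scheme()].
#' @param epoch epoch label to attach.
#' @param crs CRS identifier to attach.
#' @return A [landuse_grid()].
#' @export
read_landuse_grid <- function(path, scheme = yunnan_scheme(), epoch = "0",
                              crs = "") {
  if (!file.exists(path)) stop("cannot read file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !grepl("^[-0-9.]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); i <- i + 1
    } else break
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ESRI ASCII header: missing ", k)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("grid body size does not match header")
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value))
    m[m == as.integer(hdr$nodata_value)] <- scheme$nodata
  landuse_grid(m, cell_size = hdr$cellsize, epoch = epoch, scheme = scheme,
               xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
               yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
               crs = crs)
}

#' Write a land-use grid to an ESRI ASCII grid file
#'
#' Codes are written bit-exactly; nodata cells are written as the scheme's
#' nodata sentinel, declared in the `NODATA_value` header. Map units are km,
#' matching the grid's `cell_size`.
#'
#' @param grid a [landuse_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landuse_grid <- function(grid, path) {
  m <- grid$values
  hdr <- c(sprintf("ncols %d", ncol(m)),
           sprintf("nrows %d", nrow(m)),
           sprintf("xllcorner %.10g", grid$xll),
           sprintf("yllcorner %.10g", grid$yll),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %d", grid$scheme$nodata))
  body <- apply(m, 1, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(hdr, body), path); TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write file: ", path)
  invisible(path)
}

#' Per-class area table
#'
#' @param classes character vector of class names.
#' @param area_km2 non-negative areas in km².
#' @param epoch epoch label.
#' @return A data.frame of class `area_table` with columns `class`,
#'   `area_km2` and an `epoch` attribute.
#' @export
area_table <- function(classes, area_km2, epoch = "0") {
  if (any(area_km2 < 0)) stop("areas must be >= 0")
  out <- data.frame(class = as.character(classes), area_km2 = area_km2,
                    stringsAsFactors = FALSE)
  attr(out, "epoch") <- as.character(epoch)
  class(out) <- c("area_table", "data.frame")
  out
}

#' Per-class areas of a grid
#'
#' Area of class i = (count of non-nodata cells of class i) × cell_size².
#'
#' @param grid a [landuse_grid()].
#' @return An [area_table()] in scheme order (absent classes get area 0).
#' @export
class_areas <- function(grid) {
  sc <- grid$scheme
  v <- grid$values[valid_mask(grid)]
  cnt <- tabulate(match(v, sc$codes), nbins = n_classes(sc))
  area_table(sc$names, cnt * grid$cell_size^2, epoch = grid$epoch)
}

#' Check that two grids share a common spatial support
#'
#' Report-only gate used by cross-epoch operations: compares shape, cell
#' size, georeference (corner + CRS) and nodata masks.
#'
#' @param a,b [landuse_grid()] objects.
#' @return A list with `aligned` (logical: shape, cell size and georeference
#'   all agree), `masks_equal`, and `reasons` (character vector of failing
#'   components among `"shape"`, `"cell_size"`, `"georeference"`, `"nodata_mask"`).
#' @export
check_alignment <- function(a, b) {
  reasons <- character()
  if (!all(dim(a$values) == dim(b$values))) reasons <- c(reasons, "shape")
  if (a$cell_size != b$cell_size) reasons <- c(reasons, "cell_size")
  if (a$xll != b$xll || a$yll != b$yll || !identical(a$crs, b$crs))
    reasons <- c(reasons, "georeference")
  masks_equal <- !("shape" %in% reasons) &&
    all(valid_mask(a) == valid_mask(b))
  if (!masks_equal) reasons <- c(reasons, "nodata_mask")
  list(aligned = !any(c("shape", "cell_size", "georeference") %in% reasons),
       masks_equal = masks_equal, reasons = reasons)
}

#' Write an area table as CSV
#' @param x an [area_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(x, path) {
  utils::write.csv(data.frame(class = x$class, area_km2 = x$area_km2),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an area table from CSV (header `class,area_km2`)
#' @param path CSV path.
#' @param epoch epoch label to attach.
#' @return An [area_table()].
#' @export
read_area_table <- function(path, epoch = "0") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("class", "area_km2") %in% names(d)))
    stop("expected columns class,area_km2")
  area_table(d$class, d$area_km2, epoch = epoch)
}
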