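# Small grid builders shared across the suite.

scheme2 <- category_scheme(1:2, c("crop", "forest"))

mk_grid <- function(m, cell = 1, epoch = "0", scheme = yunnan_scheme(), ...) {
  landuse_grid(matrix(as.integer(m), nrow = nrow(m), ncol = ncol(m)),
               cell_size = cell, epoch = epoch, scheme = scheme, ...)
}

# A reproducible random six-class grid with optional nodata holes.
random_grid <- function(nr = 12, nc = 12, seed = 1, nodata_frac = 0,
                        scheme = yunnan_scheme(), cell = 1) {
  set.seed(seed)
  v <- matrix(sample(scheme$codes, nr * nc, replace = TRUE), nr, nc)
  if (nodata_frac > 0) {
    holes <- sample(nr * nc, round(nodata_frac * nr * nc))
    v[holes] <- scheme$nodata
  }
  landuse_grid(v, cell_size = cell, epoch = "0", scheme = scheme)
}

valid_mask_for_test <- function(g) g$values != g$scheme$nodata

expect_grid_equal <- function(a, b) {
  expect_identical(a$values, b$values)
  expect_equal(a$cell_size, b$cell_size)
}
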