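dens <- yunnan_density_table()
areas <- yunnan_area_table()

test_that("class density is the four-pool sum", {
  expect_equal(class_density(dens, "cropland"), 27.89 + 62 + 47.52 + 1)   # 138.41
  expect_equal(class_density(dens, "forest_land"), 48.18 + 131.7 + 49.24 + 29) # 258.12
  z <- carbon_density_table("bare", 0, 0, 0, 0)
  expect_equal(class_density(z, "bare"), 0)
  expect_error(class_density(dens, "swamp"), "unknown class")
})

test_that("stock bookkeeping reproduces the published per-class stocks", {
  # all 30 published cells (five epochs x six classes), 10^6 t at 2 dp
  published <- rbind(
    cropland          = c(960.16, 955.04, 936.87, 930.77, 928.80),
    forest_land       = c(5649.76, 5637.88, 5684.45, 5675.26, 5674.07),
    grassland         = c(1625.59, 1635.96, 1604.35, 1594.44, 1593.40),
    water_area        = c(19.94, 20.12, 23.02, 27.32, 27.28),
    construction_land = c(13.22, 15.01, 27.92, 33.36, 35.29),
    unused_land       = c(15.57, 15.57, 11.55, 11.49, 11.39))
  for (j in seq_along(areas)) {
    rep <- stock_by_class(areas[[j]], dens)
    expect_equal(round(rep$table$stock_Mt, 2), unname(published[, j]),
                 info = names(areas)[j])
    expect_equal(rep$total_Mt, sum(rep$table$stock_Mt))
    expect_equal(sum(rep$table$contribution_pct), 100, tolerance = 0.02 / 100)
  }
})

test_that("epoch totals and the period mean match the study", {
  reports <- lapply(areas, stock_by_class, dens = dens)
  totals <- round(sapply(reports, function(r) r$total_Mt), 2)
  expect_equal(unname(totals), c(8284.23, 8279.59, 8288.16, 8272.62, 8270.24))
  expect_equal(round(mean_total(reports), 2), 8278.97)
  expect_equal(mean_total(reports[1]), reports[[1]]$total_Mt)
  expect_error(mean_total(list()), "at least one")
})

test_that("stock change decomposition matches the published 1990-2020 deltas", {
  r90 <- stock_by_class(areas[["1990"]], dens)
  r20 <- stock_by_class(areas[["2020"]], dens)
  chg <- stock_change(r90, r20)
  d <- setNames(chg$table$delta_Mt, chg$table$class)
  expect_equal(round(d[["cropland"]], 2), -31.36)
  expect_equal(round(d[["grassland"]], 2), -32.18)
  expect_equal(round(d[["unused_land"]], 2), -4.18)
  expect_equal(round(d[["forest_land"]], 2), 24.31)
  expect_equal(round(d[["water_area"]], 2), 7.34)
  expect_equal(round(d[["construction_land"]], 2), 22.08)

  sh <- setNames(chg$table$share_of_decrease_pct, chg$table$class)
  expect_equal(round(sh[["cropland"]], 2), 46.31)
  expect_equal(round(sh[["grassland"]], 2), 47.52)
  expect_equal(round(sh[["unused_land"]], 2), 6.17)
  expect_equal(chg$total_delta_Mt,
               chg$gross_increase_Mt - chg$gross_decrease_Mt)

  # no change -> zero deltas, shares reported as 0
  same <- stock_change(r90, r90)
  expect_true(all(same$table$delta_Mt == 0))
  expect_true(all(same$table$share_of_decrease_pct == 0))
  expect_equal(same$gross_decrease_Mt, 0)
})

test_that("contribution shares match the published 1990 and 2020 values", {
  r90 <- stock_by_class(areas[["1990"]], dens)
  r20 <- stock_by_class(areas[["2020"]], dens)
  c90 <- setNames(r90$table$contribution_pct, r90$table$class)
  c20 <- setNames(r20$table$contribution_pct, r20$table$class)
  expect_equal(round(c90[["forest_land"]], 1), 68.2)
  expect_equal(round(c20[["forest_land"]], 2), 68.61)
  expect_equal(round(c90[["cropland"]], 2), 11.59)
  expect_equal(round(c20[["cropland"]], 2), 11.23)
  expect_equal(round(c90[["grassland"]], 2), 19.62)
  expect_equal(round(c20[["grassland"]], 2), 19.27)
})

test_that("per-cell stock maps aggregate to the table bookkeeping", {
  # constant forest grid: each 1-km cell holds 258.12 t/hm2 * 100 hm2
  g <- mk_grid(matrix(2, 2, 2))
  sm <- stock_map(g, dens)
  expect_true(all(sm == 25812))

  # random grid: map total equals stock_by_class total (t vs 10^6 t)
  for (seed in 1:3) {
    gr <- random_grid(15, 15, seed = seed, nodata_frac = 0.15, cell = 0.5)
    total_map <- sum(stock_map(gr, dens), na.rm = TRUE)
    total_tab <- stock_by_class(class_areas(gr), dens)$total_Mt * 1e6
    expect_equal(total_map, total_tab, tolerance = 1e-6)
  }

  gn <- mk_grid(matrix(yunnan_scheme()$nodata, 3, 3))
  smn <- stock_map(gn, dens)
  expect_true(all(is.na(smn)))
  expect_equal(sum(smn, na.rm = TRUE), 0)
})

test_that("stock and total increase monotonically with class area", {
  a <- areas[["1990"]]
  r <- stock_by_class(a, dens)
  a2 <- a; a2$area_km2[3] <- a2$area_km2[3] + 10
  attr(a2, "epoch") <- "1990"
  r2 <- stock_by_class(a2, dens)
  expect_gt(r2$table$stock_Mt[3], r$table$stock_Mt[3])
  expect_gt(r2$total_Mt, r$total_Mt)
})

test_that("climate adjustment hook scales pools by proxy ratios", {
  clim <- climate_context(ref_temp = 7.56, ref_precip = 673.9,
                          study_temp = 14.5, study_precip = 1180.3)
  # identity / constant relations leave the table unchanged
  expect_equal(adjust_density_table(dens, clim), dens)
  const <- list(biomass = function(t, p) 42, soil = function(t, p) 42)
  expect_equal(adjust_density_table(dens, clim, const), dens)

  # linear precipitation proxy scales corrected pools by 1180.3 / 673.9
  lin <- list(biomass = function(t, p) p, soil = function(t, p) p)
  adj <- adjust_density_table(dens, clim, lin)
  ratio <- 1180.3 / 673.9
  expect_equal(adj$above, dens$above * ratio)
  expect_equal(adj$soil, dens$soil * ratio)

  bad <- list(biomass = function(t, p) 0, soil = function(t, p) 1)
  expect_error(adjust_density_table(dens, clim, bad), "zero")
})
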