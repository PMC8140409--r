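test_that("grid_spec enforces regularity and conventions", {
  expect_error(grid_spec(lat = c(40, 40.5, 41.2), lon = c(0, 0.5)), "irregular")
  expect_error(grid_spec(lat = c(95, 96), lon = 0:1), "outside")
  g <- grid_spec(lat = c(40, 40.5), lon = c(359, 359.5))   # 0..360 rotated
  expect_true(all(g$lon < 180))
})

test_that("concentration NetCDF round-trips bit-identically", {
  b <- small_bundle()
  path <- withr::local_tempfile(fileext = ".nc")
  write_concentration(b$conc_present, path)
  back <- read_concentration(path)
  expect_identical(back$values, b$conc_present$values)
  expect_equal(back$grid$lat, b$conc_present$grid$lat, tolerance = 1e-12)
  expect_equal(back$grid$lon, b$conc_present$grid$lon, tolerance = 1e-12)
  expect_identical(back$period_label, "1991-2010")
})

test_that("reader rejects wrong units", {
  path <- withr::local_tempfile(fileext = ".nc")
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", c(40, 41))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", c(0, 1))
  v <- ncdf4::ncvar_def("pm25", "ppb", list(dlat, dlon), prec = "double")
  nc <- ncdf4::nc_create(path, v)
  ncdf4::ncvar_put(nc, v, matrix(1, 2, 2))
  ncdf4::nc_close(nc)
  expect_error(read_concentration(path), "units")
})

test_that("population CSV round-trips", {
  b <- small_bundle()
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(b$pop, path)
  back <- read_population(path)
  expect_equal(back$counts, b$pop$counts, tolerance = 1e-12)
  expect_identical(back$year, b$pop$year)
})

test_that("cell areas follow the spherical closed form", {
  # 0.11 deg cell at the equator
  g <- grid_spec(lat = c(-0.055, 0.055), lon = c(0, 0.11))
  a <- cell_areas(g)
  expect_equal(a$area[1, 1], 149.6081, tolerance = 1e-4)
  # symmetry about the equator
  expect_equal(a$area[1, ], a$area[2, ], tolerance = 1e-12)
  # strict decrease away from the equator at fixed resolution
  g2 <- grid_spec(lat = seq(0.5, 80.5, by = 1), lon = c(0, 1))
  rows <- cell_areas(g2)$area[, 1]
  expect_true(all(diff(rows) < 0))
  # global closure: sum of areas = 4 pi R^2
  gg <- grid_spec(lat = seq(-89.5, 89.5, by = 1), lon = seq(-179.5, 179.5, by = 1))
  expect_equal(sum(cell_areas(gg)$area), 4 * pi * 6371^2, tolerance = 1e-6)
})

test_that("regridding is conservative", {
  # identity on the same grid
  b <- small_bundle()
  expect_identical(regrid_population(b$pop, b$pop$grid), b$pop)
  # exact nesting: 4 source cells in 1 target cell, counts 1..4 -> 10
  src <- grid_spec(lat = c(44.75, 45.25), lon = c(9.75, 10.25))
  counts <- array(0, dim = c(2, 2, 12), dimnames = list(NULL, NULL, AGE_BANDS))
  counts[, , "60-64"] <- matrix(1:4, 2, 2)
  tgt <- grid_spec(lat = c(44, 45), lon = c(9, 10))   # res 1; cell (45,10) covers src
  out <- regrid_population(pop_grid(src, counts), tgt)
  expect_equal(unname(out$counts[2, 2, "60-64"]), 10, tolerance = 1e-12)
  expect_equal(sum(out$counts), 10, tolerance = 1e-12)
  # random fine-to-coarse aggregation conserves totals per age group
  set.seed(7)
  fine <- grid_spec(lat = seq(40.025, 41.975, by = 0.05),
                    lon = seq(0.025, 3.975, by = 0.05))
  arr <- array(stats::runif(length(fine$lat) * length(fine$lon) * 12),
               dim = c(length(fine$lat), length(fine$lon), 12),
               dimnames = list(NULL, NULL, AGE_BANDS))
  popf <- pop_grid(fine, arr)
  coarse <- grid_spec(lat = seq(39.955, 42.165, by = 0.11),
                      lon = seq(-0.055, 4.125, by = 0.11))
  out2 <- regrid_population(popf, coarse)
  for (bnd in AGE_BANDS)
    expect_equal(sum(out2$counts[, , bnd]), sum(arr[, , bnd]), tolerance = 1e-6)
  # disjoint domains rejected
  far <- grid_spec(lat = seq(70.25, 71.75, by = 0.5), lon = seq(60.25, 61.75, by = 0.5))
  expect_error(regrid_population(popf, far), "disjoint")
})

test_that("typed table reader validates schemas", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("region,endpoint,age_group,y0", "Western,IHD,60-64,0.004"), path)
  df <- read_table(path, "baseline_rates")
  expect_identical(df$region, "Western")
  expect_identical(df$y0, 0.004)
  # missing required column
  writeLines(c("region,endpoint,age_group", "Western,IHD,60-64"), path)
  expect_error(read_table(path, "baseline_rates"), "missing required column")
  # unknown column rejected
  writeLines(c("region,endpoint,age_group,y0,extra", "Western,IHD,60-64,0.004,1"), path)
  expect_error(read_table(path, "baseline_rates"), "unknown column")
  # negative rate rejected
  writeLines(c("region,endpoint,age_group,y0", "Western,IHD,60-64,-0.004"), path)
  expect_error(read_table(path, "baseline_rates"), "\\[0, 1\\]")
  # projection_ratios round trip
  rt <- data.frame(country = c("XA", "XB"), age_group = "60-64", ratio = c(1.3, 0.9))
  write_table(rt, path, "projection_ratios")
  expect_equal(read_table(path, "projection_ratios"), rt)
})
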