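test_that("generators are reproducible from the seed and sensitive to it", {
  s <- small_spec(3L)
  c1 <- synth_concentration(s)
  c2 <- synth_concentration(s)
  expect_identical(c1$values, c2$values)
  b1 <- synth_population(s)
  b2 <- synth_population(s)
  expect_identical(b1$pop$counts, b2$pop$counts)
  c3 <- synth_concentration(small_spec(4L))
  expect_false(identical(c1$values, c3$values))
  # bookkeeping identities hold under any seed
  expect_equal(total_population(b1$pop), s$pop_total, tolerance = 1e-6)
  expect_equal(total_population(synth_population(small_spec(4L))$pop),
               s$pop_total, tolerance = 1e-6)
})

test_that("concentration field has background plus hotspot structure", {
  # zero hotspots, zero spread -> constant field at the median
  s0 <- synth_spec(lat_range = c(40, 45), lon_range = c(0, 5), resolution = 0.5,
                   n_hotspots = 0, background_sigma = 0, background_median = 8,
                   pop_total = 1e6, pop_total_future = 1e6)
  c0 <- synth_concentration(s0)
  expect_true(all(abs(c0$values - 8) < 1e-12))
  # defaults: at least one urban cell above the 25 ug m-3 annual limit,
  # domain mean at background level
  cd <- synth_concentration(synth_spec())
  expect_gt(max(cd$values), 25)
  expect_gt(mean(cd$values), 5)
  expect_lt(mean(cd$values), 20)
  expect_true(all(cd$values >= 0))
})

test_that("future perturbation applies the south/north dipole and clamps at zero", {
  s <- synth_spec()   # full default domain so both dipole plateaus are reached
  pres <- synth_concentration(s)
  fut <- synth_future_concentration(pres, s)
  # a cell far south of the split gains ~ +2, far north loses ~ -0.3
  i_s <- which.min(abs(pres$grid$lat - 36)); i_n <- which.min(abs(pres$grid$lat - 59.5))
  delta <- fut$values - pres$values
  expect_equal(delta[i_s, 1], 2, tolerance = 0.01)
  expect_equal(delta[i_n, 1], -0.3, tolerance = 0.01)
  # zero dipole -> identity
  s0 <- synth_spec(); s0$south_increment <- 0; s0$north_decrement <- 0
  expect_equal(synth_future_concentration(pres, s0)$values, pres$values,
               tolerance = 1e-12)
  # clamped at zero even for violent decrements
  s2 <- small_spec(); s2$north_decrement <- 1e4; s2$south_increment <- 0
  expect_true(all(synth_future_concentration(pres, s2)$values >= 0))
})

test_that("synthetic population matches its pyramid and projection targets", {
  b <- small_bundle()
  pyr <- age_pyramid(b$pop)
  expect_equal(unname(pyr[names(b$spec$pyramid_present)]),
               unname(b$spec$pyramid_present), tolerance = 1e-9)
  # the 80+ share roughly doubles under the default projection
  fut <- apply_projection(b$pop, b$ratios, b$mask)
  expect_gt(age_pyramid(fut)["80plus"] / pyr["80plus"], 1.8)
  expect_equal(total_population(fut), b$spec$pop_total_future, tolerance = 1e-6)
  # every emitted artifact passes its validators
  expect_s3_class(b$pop, "pop_grid")
  expect_s3_class(b$mask, "country_mask")
  expect_true(all(stats::na.omit(as.vector(b$mask$codes)) %in% b$scheme$country))
  # no population on sentinel (sea) cells
  land_pop <- apply(b$pop$counts, c(1, 2), sum)
  expect_true(all(land_pop[is.na(b$mask$codes)] == 0))
})

test_that("synthetic baseline rates are complete, age-monotone and region-ordered", {
  rates <- synth_baseline_rates(small_spec())
  expect_identical(nrow(rates), 3L * 7L * 12L)
  for (rg in REGIONS) for (ep in c(ENDPOINTS, OTHER_NCD)) {
    y <- rates$y0[rates$region == rg & rates$endpoint == ep]
    y <- y[match(AGE_BANDS, rates$age_group[rates$region == rg & rates$endpoint == ep])]
    expect_true(all(diff(y) > 0))
  }
  for (ep in SPECIFIC_CAUSES) for (b in c("25-29", "80plus")) {
    w <- lookup_y0(rates, "Western", ep, b)
    expect_gte(lookup_y0(rates, "Central", ep, b), w)
    expect_gte(lookup_y0(rates, "Eastern", ep, b),
               lookup_y0(rates, "Central", ep, b))
  }
})

test_that("known-truth variants carry the advertised expected values", {
  kt0 <- known_truth_case("counterfactual")
  expect_true(all(kt0$expected$central == 0))
  sc <- known_truth_case("single_cell")
  expect_equal(sc$expected$central, c(200, 200), tolerance = 1e-12)
  res <- run_hia(sc$conc, sc$pop, sc$rates, sc$params, sc$mask, sc$scheme)
  tot <- res$summary[res$summary$region == "EUROPE" & res$summary$age_group == "ALL" &
                       res$summary$endpoint == "NCD_LRI", ]
  expect_equal(tot$central, 200, tolerance = 1e-12)
  expect_equal(tot$low, 200, tolerance = 1e-12)  # se = 0 collapses the CI
})
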