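test_that("cell mortality implements y0 * (RR-1)/RR * Pop", {
  expect_identical(cell_mortality(0.01, rr_value(1), 1e5)$central, 0)
  expect_identical(cell_mortality(0.01, rr_value(1.25), 0)$central, 0)
  expect_equal(cell_mortality(0.01, rr_value(1.25), 1e5)$central, 200, tolerance = 1e-12)
  expect_error(cell_mortality(0.01, rr_value(1.25), -5), "negative population")
  expect_error(cell_mortality(1.5, rr_value(1.25), 5), "y0")
})

test_that("endpoint field at the counterfactual concentration is all zero", {
  kt <- known_truth_case("counterfactual")
  for (ep in ENDPOINTS) {
    f <- compute_endpoint(kt$conc, kt$pop, kt$rates, kt$params, kt$mask, ep, kt$scheme)
    expect_true(all(f$deaths == 0))
  }
})

test_that("a single-cell domain reduces to cell_mortality", {
  sc <- known_truth_case("single_cell")
  f <- compute_endpoint(sc$conc, sc$pop, sc$rates, sc$params, sc$mask, "NCD_LRI", sc$scheme)
  p <- as.list(sc$params[sc$params$endpoint == "NCD_LRI", ])
  manual <- cell_mortality(0.01, gemm_rr(12.4, p), 1e5)
  expect_equal(f$deaths[1, 1, "60-64", "central"], manual$central, tolerance = 1e-12)
  expect_equal(sum(f$deaths[, , , "central"]), manual$central, tolerance = 1e-12)
  # the sea cell contributes nothing even though it has a concentration
  expect_equal(sum(f$deaths[2, 1, , ]), 0)
})

test_that("pipeline reproduces the hand-computed oracle to 1e-12 relative", {
  kt <- known_truth_case("three_region")
  res <- run_hia(kt$conc, kt$pop, kt$rates, kt$params, kt$mask, kt$scheme)
  got <- res$summary[res$summary$age_group == "ALL", ]
  m <- merge(got, kt$expected, by = c("region", "endpoint"),
             suffixes = c("", ".exp"))
  expect_identical(nrow(m), nrow(kt$expected))
  for (cn in c("central", "low", "high")) {
    rel <- abs(m[[cn]] - m[[paste0(cn, ".exp")]]) /
      pmax(1e-300, abs(m[[paste0(cn, ".exp")]]))
    expect_lt(max(rel), 1e-12)
  }
  # the Central-region cell sits exactly at the counterfactual: zero deaths
  expect_true(all(m$central[m$region == "Central"] == 0))
})

test_that("other-NCD subtraction floors at zero and is otherwise exact", {
  kt <- known_truth_case("three_region")
  all_cause <- compute_endpoint(kt$conc, kt$pop, kt$rates, kt$params, kt$mask,
                                "NCD_LRI", kt$scheme)
  five <- lapply(SPECIFIC_CAUSES, function(ep)
    compute_endpoint(kt$conc, kt$pop, kt$rates, kt$params, kt$mask, ep, kt$scheme))
  # five causes all zero -> other equals the envelope
  zero5 <- lapply(five, function(f) { f$deaths[] <- 0; f })
  expect_equal(derive_other_ncd(all_cause, zero5)$deaths, all_cause$deaths)
  # five causes exactly the envelope -> zero field
  parts <- lapply(seq_along(five), function(i) {
    f <- five[[i]]; f$deaths <- all_cause$deaths / 5; f })
  expect_true(all(abs(derive_other_ncd(all_cause, parts)$deaths) < 1e-9))
  # adversarial: causes exceed the envelope by epsilon -> floored, logged
  over <- lapply(seq_along(five), function(i) {
    f <- five[[i]]; f$deaths <- all_cause$deaths / 5 * (1 + 1e-9); f })
  expect_message(out <- derive_other_ncd(all_cause, over), "floored")
  expect_true(all(out$deaths == 0))
  expect_gt(attr(out, "floored"), 0)
  expect_error(derive_other_ncd(all_cause, five[1:4]), "five_causes")
})

test_that("aggregation reproduces the printed regional arithmetic and conserves cells", {
  # printed regional all-cause totals sum to the printed Europe total
  ref <- europe_reference()
  all_cause <- ref[ref$endpoint == "NCD_LRI", ]
  expect_identical(sum(all_cause$central[all_cause$region %in% REGIONS]),
                   all_cause$central[all_cause$region == "EUROPE"])
  # random synthetic field: cell sum == regional sum == Europe total
  b <- small_bundle()
  f <- compute_endpoint(b$conc_present, b$pop, b$rates, gemm_params_tab(),
                        b$mask, "IHD", b$scheme)
  s <- aggregate_mortality(f, b$mask, b$scheme)
  europe <- s$central[s$region == "EUROPE" & s$age_group == "ALL"]
  expect_equal(europe, sum(f$deaths[, , , "central"]), tolerance = 1e-9)
  expect_equal(europe, sum(s$central[s$region %in% REGIONS & s$age_group == "ALL"]),
               tolerance = 1e-9)
  # one-region domain: EUROPE row equals that region's row
  sc <- known_truth_case("single_cell")
  f1 <- compute_endpoint(sc$conc, sc$pop, sc$rates, sc$params, sc$mask,
                         "NCD_LRI", sc$scheme)
  s1 <- aggregate_mortality(f1, sc$mask, sc$scheme)
  expect_equal(s1$central[s1$region == "EUROPE" & s1$age_group == "ALL"],
               s1$central[s1$region == "Western" & s1$age_group == "ALL"],
               tolerance = 1e-15)
})

test_that("per-km2 maps invert against cell areas", {
  sc <- known_truth_case("single_cell")
  f <- compute_endpoint(sc$conc, sc$pop, sc$rates, sc$params, sc$mask,
                        "NCD_LRI", sc$scheme)
  areas <- cell_areas(f$grid)
  dens <- per_area(f, areas)
  # 300 deaths in a 150 km2 cell -> 2 deaths/km2 (constructed directly)
  f2 <- f
  f2$deaths[] <- 0
  f2$deaths[1, 1, "60-64", ] <- 300
  a2 <- areas; a2$area[] <- 150
  expect_equal(unname(per_area(f2, a2)$density[1, 1, "central"]), 2, tolerance = 1e-12)
  # all-zero field maps to zero density
  f2$deaths[] <- 0
  expect_true(all(per_area(f2, areas)$density == 0))
  # density times area recovers the original total
  back <- sum(dens$density[, , "central"] * areas$area)
  expect_equal(back, sum(f$deaths[, , , "central"]), tolerance = 1e-9)
})

test_that("endpoint shares reproduce the printed percentages", {
  s <- reference_as_summary()
  sh <- mortality_shares(s)
  expect_identical(sh$share_pct[sh$endpoint == "IHD"], 48)
  expect_identical(sh$share_pct[sh$endpoint == "OTHER_NCD"], 29)
  expect_identical(sh$share_pct[sh$endpoint == "COPD"], 3)
  # cardiovascular (IHD + CEV) share of the total
  cardio <- sum(sh$share[sh$endpoint %in% c("IHD", "CEV")])
  expect_identical(pm25hia:::round_half_up(cardio), 58)
  # single nonzero endpoint -> 100%
  one <- data.frame(region = "EUROPE", endpoint = c("NCD_LRI", "IHD"),
                    age_group = "ALL", central = c(10, 10), low = c(10, 10),
                    high = c(10, 10))
  expect_identical(mortality_shares(one)$share_pct, 100)
})

test_that("mortality scales linearly in population and monotonically in concentration", {
  kt <- known_truth_case("three_region")
  f1 <- compute_endpoint(kt$conc, kt$pop, kt$rates, kt$params, kt$mask, "IHD", kt$scheme)
  pop2 <- pop_grid(kt$pop$grid, kt$pop$counts * 2, year = kt$pop$year)
  f2 <- compute_endpoint(kt$conc, pop2, kt$rates, kt$params, kt$mask, "IHD", kt$scheme)
  expect_equal(f2$deaths, f1$deaths * 2, tolerance = 1e-15)
  up <- conc_field(kt$conc$grid, kt$conc$values + 5, period_label = "up")
  f3 <- compute_endpoint(up, kt$pop, kt$rates, kt$params, kt$mask, "IHD", kt$scheme)
  expect_true(all(f3$deaths >= f1$deaths))
})
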