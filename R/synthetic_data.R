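#' Specification for the synthetic input generator
#'
#' Collects every knob of the synthetic pipeline inputs. Defaults emulate
#' the structure of the study conditions: a spatially smooth lognormal
#' PM2.5 background with urban hotspot plumes exceeding 25 ug m-3; a
#' clustered population of 808 million with an age pyramid whose 80+ share
#' is 4% in the present and rises to 9% (total 806 million) in the future;
#' a future concentration perturbation that adds about +2 ug m-3 south of
#' the latitude split and removes about 0.3 ug m-3 north of it; and
#' baseline mortality rates that rise with age and from Western through
#' Central to Eastern Europe.
#'
#' @param seed Integer master seed; every sub-generator derives its own
#'   stream from it.
#' @param lat_range,lon_range,resolution Domain extent and cell size,
#'   degrees.
#' @param background_median,background_sigma Lognormal background median
#'   (ug m-3) and log-scale spread.
#' @param n_hotspots,hotspot_amplitude,hotspot_radius Number of urban
#'   plumes, their peak enhancement range (ug m-3) and Gaussian radius
#'   range (degrees).
#' @param pop_total,pop_total_future Continental totals (persons).
#' @param n_clusters,cluster_radius Settlement clusters and their radius
#'   range (degrees).
#' @param hotspot_coloc_frac Fraction of settlement clusters co-located
#'   with concentration hotspots.
#' @param pyramid_present,pyramid_future Named shares (sum 1) over
#'   `under25` plus the twelve adult bands.
#' @param south_increment,north_decrement,lat_split,split_width Future
#'   dipole: enhancement south of the split, reduction north of it
#'   (ug m-3), split latitude and logistic smoothing width (degrees).
#' @param sea_margin Cells of sentinel (sea) ring around the domain.
#' @param rate_base Named per-endpoint baseline rates at the youngest band
#'   (deaths/person/yr, Western region).
#' @param rate_age_factor Multiplicative increase per 5-year band.
#' @param rate_region_mult Named multipliers for Western/Central/Eastern.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(seed = 42L,
                       lat_range = c(35, 60), lon_range = c(-10, 30),
                       resolution = 0.5,
                       background_median = 8, background_sigma = 0.25,
                       n_hotspots = 6,
                       hotspot_amplitude = c(15, 25), hotspot_radius = c(0.3, 0.7),
                       pop_total = 808e6, pop_total_future = 806e6,
                       n_clusters = 40, cluster_radius = c(0.3, 1.0),
                       hotspot_coloc_frac = 0.5,
                       pyramid_present = NULL, pyramid_future = NULL,
                       south_increment = 2, north_decrement = 0.3,
                       lat_split = 47, split_width = 1,
                       sea_margin = 1,
                       rate_base = c(IHD = 2e-4, CEV = 1.2e-4, COPD = 5e-5,
                                     LC = 8e-5, LRI = 4e-5),
                       rate_age_factor = 1.35,
                       rate_region_mult = c(Western = 1, Central = 1.25, Eastern = 1.6)) {
  if (is.null(pyramid_present))
    pyramid_present <- c(under25 = 0.31,
                         `25-29` = 0.065, `30-34` = 0.068, `35-39` = 0.070,
                         `40-44` = 0.072, `45-49` = 0.071, `50-54` = 0.068,
                         `55-59` = 0.062, `60-64` = 0.055, `65-69` = 0.048,
                         `70-74` = 0.040, `75-79` = 0.031, `80plus` = 0.040)
  if (is.null(pyramid_future))
    pyramid_future <- c(under25 = 0.27,
                        `25-29` = 0.055, `30-34` = 0.057, `35-39` = 0.058,
                        `40-44` = 0.060, `45-49` = 0.062, `50-54` = 0.063,
                        `55-59` = 0.063, `60-64` = 0.062, `65-69` = 0.060,
                        `70-74` = 0.056, `75-79` = 0.044, `80plus` = 0.090)
  spec <- mget(names(formals()))
  spec$pyramid_present <- pyramid_present
  spec$pyramid_future <- pyramid_future
  for (p in list(pyramid_present, pyramid_future)) {
    if (abs(sum(p) - 1) > 1e-9) stop_stage("validate", "pyramid shares must sum to 1")
    if (!setequal(names(p), c(AGE_BAND_U25, AGE_BANDS)))
      stop_stage("validate", "pyramid must cover under25 plus the 12 adult bands")
  }
  stopifnot(resolution > 0, background_median > 0, background_sigma >= 0,
            pop_total > 0, rate_age_factor > 0, all(rate_base > 0))
  structure(spec, class = "synth_spec")
}

# derived, seeded RNG stream: runs `expr` under seed + offset, restoring
# the caller's RNG state afterwards
with_stream <- function(spec, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed + offset)
  force(expr)
}

synth_grid <- function(spec) {
  half <- spec$resolution / 2
  grid_spec(lat = seq(spec$lat_range[1] + half, spec$lat_range[2] - half, by = spec$resolution),
            lon = seq(spec$lon_range[1] + half, spec$lon_range[2] - half, by = spec$resolution))
}

# smooth standard-normal-ish surface: coarse white noise, bilinearly
# interpolated to the working grid
smooth_surface <- function(grid, scale_deg = 5) {
  clat <- seq(min(grid$lat) - scale_deg, max(grid$lat) + scale_deg, by = scale_deg)
  clon <- seq(min(grid$lon) - scale_deg, max(grid$lon) + scale_deg, by = scale_deg)
  z <- matrix(stats::rnorm(length(clat) * length(clon)), length(clat), length(clon))
  # interpolate along lat for each coarse lon, then along lon
  half <- matrix(0, length(grid$lat), length(clon))
  for (j in seq_along(clon))
    half[, j] <- stats::approx(clat, z[, j], xout = grid$lat, rule = 2)$y
  out <- matrix(0, length(grid$lat), length(grid$lon))
  for (i in seq_along(grid$lat))
    out[i, ] <- stats::approx(clon, half[i, ], xout = grid$lon, rule = 2)$y
  out
}

gaussian_plumes <- function(grid, centers_lat, centers_lon, amp, radius) {
  out <- matrix(0, length(grid$lat), length(grid$lon))
  lon_row <- matrix(grid$lon, length(grid$lat), length(grid$lon), byrow = TRUE)
  lat_col <- matrix(grid$lat, length(grid$lat), length(grid$lon))
  for (h in seq_along(amp)) {
    d2 <- (lat_col - centers_lat[h])^2 + (lon_row - centers_lon[h])^2
    out <- out + amp[h] * exp(-d2 / (2 * radius[h]^2))
  }
  out
}

#' Synthesise a present-day concentration field
#'
#' Spatially smooth lognormal background plus Gaussian urban hotspot
#' plumes. With the default spec the field maximum exceeds the 25 ug m-3
#' annual-mean limit value in at least one hotspot while the domain mean
#' remains at rural-European background levels.
#'
#' @param spec A [synth_spec()].
#' @return A [conc_field()] labelled `"1991-2010"`.
#' @export
synth_concentration <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  grid <- synth_grid(spec)
  with_stream(spec, 1L, {
    bg <- spec$background_median * exp(spec$background_sigma * smooth_surface(grid))
    hs <- synth_hotspots(spec, grid)
    vals <- bg + gaussian_plumes(grid, hs$lat, hs$lon, hs$amp, hs$radius)
    conc_field(grid, vals, period_label = "1991-2010")
  })
}

# hotspot locations are a derived stream of their own so that the
# population generator can co-locate settlements with them
synth_hotspots <- function(spec, grid = synth_grid(spec)) {
  with_stream(spec, 7L, {
    n <- spec$n_hotspots
    pad <- 2
    data.frame(
      lat = stats::runif(n, min(grid$lat) + pad, max(grid$lat) - pad),
      lon = stats::runif(n, min(grid$lon) + pad, max(grid$lon) - pad),
      amp = stats::runif(n, spec$hotspot_amplitude[1], spec$hotspot_amplitude[2]),
      radius = stats::runif(n, spec$hotspot_radius[1], spec$hotspot_radius[2]))
  })
}

#' Perturb a present field into the future scenario
#'
#' Applies the south-increase / north-decrease dipole of the future climate
#' projection: cells well south of the latitude split gain
#' `south_increment` ug m-3, cells well north lose `north_decrement`, with
#' a logistic transition of width `split_width` across the split. Values
#' are clamped at zero.
#'
#' @param present A [conc_field()].
#' @param spec A [synth_spec()].
#' @return A [conc_field()] labelled `"2031-2050"`.
#' @export
synth_future_concentration <- function(present, spec) {
  stopifnot(inherits(present, "conc_field"), inherits(spec, "synth_spec"))
  g <- present$grid
  north_frac <- 1 / (1 + exp(-(g$lat - spec$lat_split) / spec$split_width))
  delta_row <- spec$south_increment * (1 - north_frac) - spec$north_decrement * north_frac
  delta <- matrix(delta_row, length(g$lat), length(g$lon))
  conc_field(g, pmax(present$values + delta, 0), period_label = "2031-2050")
}

# toy country layout: land cells (outside the sea margin) split into three
# longitude thirds (Western | Central | Eastern), each third split at the
# domain's mid-latitude into two synthetic countries
synth_mask <- function(spec, grid = synth_grid(spec)) {
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  codes <- matrix(NA_character_, nlat, nlon)
  m <- spec$sea_margin
  lat_in <- seq_len(nlat) > m & seq_len(nlat) <= nlat - m
  lon_in <- seq_len(nlon) > m & seq_len(nlon) <= nlon - m
  lon_third <- cut(grid$lon, breaks = stats::quantile(grid$lon, c(0, 1/3, 2/3, 1)),
                   labels = c("W", "C", "E"), include.lowest = TRUE)
  lat_half <- ifelse(grid$lat <= stats::median(grid$lat), "A", "B")
  for (i in which(lat_in)) for (j in which(lon_in))
    codes[i, j] <- paste0("X", lon_third[j], lat_half[i])
  country_mask(grid, codes)
}

synth_scheme <- function() {
  region_scheme(data.frame(
    country = c("XWA", "XWB", "XCA", "XCB", "XEA", "XEB"),
    region = rep(REGIONS, each = 2)))
}

#' Synthesise population, projection ratios and country mask
#'
#' Builds a clustered settlement surface (a configurable fraction of
#' clusters co-located with the concentration hotspots), distributes the
#' continental total over land cells, and splits each cell by the present
#' age-pyramid shares, so the generated pyramid matches the spec exactly.
#' Projection ratios are constructed per (synthetic) country and band so
#' that applying them reproduces the future pyramid and total; with the
#' defaults the 80+ share rises from 4% to 9% of total population while
#' the total barely changes.
#'
#' @param spec A [synth_spec()].
#' @return List with `pop` ([pop_grid()], year 2010), `ratios`
#'   (`projection_ratios` data.frame), `mask` ([country_mask()]) and
#'   `scheme` ([region_scheme()]).
#' @export
synth_population <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  grid <- synth_grid(spec)
  mask <- synth_mask(spec, grid)
  land <- !is.na(mask$codes)
  hs <- synth_hotspots(spec, grid)
  dens <- with_stream(spec, 2L, {
    n <- spec$n_clusters
    n_co <- min(round(spec$hotspot_coloc_frac * n), nrow(hs))
    pick <- if (n_co > 0) sample(nrow(hs), n_co, replace = n_co > nrow(hs)) else integer()
    pad <- 2
    clat <- c(hs$lat[pick], stats::runif(n - n_co, min(grid$lat) + pad, max(grid$lat) - pad))
    clon <- c(hs$lon[pick], stats::runif(n - n_co, min(grid$lon) + pad, max(grid$lon) - pad))
    amp <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    rad <- stats::runif(n, spec$cluster_radius[1], spec$cluster_radius[2])
    gaussian_plumes(grid, clat, clon, amp, rad)
  })
  dens[!land] <- 0
  dens[land] <- dens[land] + 0.05 * mean(dens[land])   # diffuse rural floor
  dens <- dens * (spec$pop_total / sum(dens))
  bands <- names(spec$pyramid_present)
  counts <- array(0, dim = c(dim(dens), length(bands)),
                  dimnames = list(NULL, NULL, bands))
  for (k in seq_along(bands)) counts[, , k] <- dens * spec$pyramid_present[k]
  pop <- pop_grid(grid, counts, year = 2010L)
  # national 2050/2010 multipliers reproducing the future pyramid and total
  scheme <- synth_scheme()
  ratio_band <- (spec$pyramid_future[bands] * spec$pop_total_future) /
    (spec$pyramid_present[bands] * spec$pop_total)
  ratios <- expand.grid(country = scheme$country, age_group = bands,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ratios$ratio <- ratio_band[ratios$age_group]
  list(pop = pop, ratios = ratios[c("country", "age_group", "ratio")],
       mask = mask, scheme = scheme)
}

#' Synthesise a baseline mortality rate table
#'
#' Complete over 3 regions x 7 endpoints (five specific causes, the
#' `NCD_LRI` all-cause envelope, and `OTHER_NCD` defined so the envelope
#' equals twice the sum of the specific causes) x 12 adult bands. Rates
#' increase geometrically with age and from Western through Central to
#' Eastern Europe.
#'
#' @param spec A [synth_spec()].
#' @return A validated `baseline_rates` data.frame.
#' @export
synth_baseline_rates <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  rows <- list()
  age_mult <- spec$rate_age_factor^(seq_along(AGE_BANDS) - 1)
  for (rg in REGIONS) {
    rm <- spec$rate_region_mult[[rg]]
    for (k in seq_along(AGE_BANDS)) {
      singles <- spec$rate_base * age_mult[k] * rm
      all_cause <- 2 * sum(singles)
      y0 <- c(singles, NCD_LRI = all_cause, OTHER_NCD = all_cause - sum(singles))
      for (ep in names(y0))
        rows[[length(rows) + 1]] <- data.frame(
          region = rg, endpoint = ep, age_group = AGE_BANDS[k], y0 = unname(y0[ep]))
    }
  }
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  if (any(rates$y0 > 1)) stop_stage("validate", "synthetic rate exceeds 1/person/yr")
  validate_baseline_rates(rates, endpoints = c(ENDPOINTS, OTHER_NCD))
}

#' Generate a complete, consistent input bundle
#'
#' Runs all sub-generators under derived streams of the master seed and
#' returns every input the pipeline needs for a present and a future run.
#'
#' @param spec A [synth_spec()].
#' @return List with `spec`, `conc_present`, `conc_future`, `pop`,
#'   `ratios`, `mask`, `scheme`, `rates`.
#' @export
synth_bundle <- function(spec = synth_spec()) {
  conc <- synth_concentration(spec)
  popset <- synth_population(spec)
  list(spec = spec,
       conc_present = conc,
       conc_future = synth_future_concentration(conc, spec),
       pop = popset$pop, ratios = popset$ratios,
       mask = popset$mask, scheme = popset$scheme,
       rates = synth_baseline_rates(spec))
}

# ---- known-truth oracle case -------------------------------------------

# scalar GEMM evaluation used ONLY to build expected values for the
# known-truth bundle; deliberately written as plain arithmetic, not via
# gemm_rr(), so the pipeline is checked against an independent path
scalar_gemm <- function(conc, theta, alpha, mu, nu, zcf) {
  z <- max(0, conc - zcf)
  exp(theta * log(1 + z / alpha) * (1 / (1 + exp(-(z - mu) / nu))))
}

#' Hand-computable end-to-end oracle case
#'
#' Tiny input bundles whose expected regional summaries are computed by an
#' independent scalar evaluation of the attributable-mortality identity
#' (plain `exp`/`log` arithmetic, no pipeline code), for end-to-end
#' verification of the engine.
#'
#' * `"three_region"`: 1 x 3 grid, one synthetic country per region,
#'   constant concentration per region (one cell exactly at the
#'   counterfactual), population in two age bands, packaged GEMM
#'   parameters, simple round-number baseline rates.
#' * `"counterfactual"`: same domain with every cell at the counterfactual
#'   concentration; all expected totals are zero.
#' * `"single_cell"`: one cell, population 100,000 in one band, all-cause
#'   baseline rate 0.01 and a parameter table tuned so RR = 1.25 exactly,
#'   giving an expected all-cause total of 0.01 * 0.2 * 100000 = 200.
#'
#' @param variant One of `"three_region"`, `"counterfactual"`,
#'   `"single_cell"`.
#' @return List with the inputs (`conc`, `pop`, `mask`, `scheme`, `rates`,
#'   `params`) and `expected`, a data.frame of all-age totals (`region`,
#'   `endpoint`, `central`, `low`, `high`) including `EUROPE` rows.
#' @export
known_truth_case <- function(variant = c("three_region", "counterfactual", "single_cell")) {
  variant <- match.arg(variant)
  if (variant == "single_cell") return(known_truth_single_cell())
  grid <- grid_spec(lat = 45, lon = c(0, 10, 20))
  cvals <- if (variant == "counterfactual") c(2.4, 2.4, 2.4) else c(12.4, 2.4, 30)
  conc <- conc_field(grid, matrix(cvals, 1, 3), period_label = "oracle")
  mask <- country_mask(grid, matrix(c("XWA", "XCA", "XEA"), 1, 3))
  scheme <- region_scheme(data.frame(country = c("XWA", "XCA", "XEA"), region = REGIONS))
  pops <- c(`60-64` = 1e5, `80plus` = 5e4)
  counts <- array(0, dim = c(1, 3, 12), dimnames = list(NULL, NULL, AGE_BANDS))
  for (b in names(pops)) counts[, , b] <- pops[b]
  pop <- pop_grid(grid, counts, year = 2010L)
  reg_mult <- c(Western = 1, Central = 1.2, Eastern = 1.5)
  y0_single <- c(`60-64` = 0.002, `80plus` = 0.008)
  y0_all <- c(`60-64` = 0.02, `80plus` = 0.08)
  rows <- list()
  for (rg in REGIONS) for (b in AGE_BANDS) for (ep in ENDPOINTS) {
    y0 <- if (!b %in% names(pops)) 0
          else if (ep == "NCD_LRI") y0_all[[b]] * reg_mult[[rg]]
          else y0_single[[b]] * reg_mult[[rg]]
    rows[[length(rows) + 1]] <- data.frame(region = rg, endpoint = ep,
                                           age_group = b, y0 = y0)
  }
  rates <- do.call(rbind, rows)
  params <- load_rr_params("GEMM")
  # --- independent scalar expectation ------------------------------------
  cell_region <- REGIONS
  exp_rows <- list()
  for (ep in c(ENDPOINTS, OTHER_NCD)) {
    per_region <- matrix(0, 3, 3, dimnames = list(REGIONS, c("central", "low", "high")))
    for (ci in 1:3) {
      rg <- cell_region[ci]
      for (b in names(pops)) {
        if (ep == OTHER_NCD) {
          # envelope minus the five causes, scalar arithmetic throughout
          get_dm <- function(e, which) {
            pr <- params[params$endpoint == e &
                           params$age_group %in% c(b, "ALL_AGES"), ]
            pr <- if (b %in% pr$age_group) pr[pr$age_group == b, ] else pr
            th <- switch(which, central = pr$theta,
                         low = pr$theta - 1.96 * pr$theta_se,
                         high = pr$theta + 1.96 * pr$theta_se)
            rr <- scalar_gemm(cvals[ci], th, pr$alpha, pr$mu, pr$nu, pr$zcf)
            y0 <- (if (e == "NCD_LRI") y0_all[[b]] else y0_single[[b]]) * reg_mult[[rg]]
            y0 * (rr - 1) / rr * pops[[b]]
          }
          v <- vapply(c("central", "low", "high"), function(w)
            max(0, get_dm("NCD_LRI", w) -
                  sum(vapply(SPECIFIC_CAUSES, get_dm, 0, which = w))), 0)
          # same layer-ordering convention as the pipeline's derived field
          v <- c(central = unname(v["central"]), low = min(v), high = max(v))
          for (w in c("central", "low", "high"))
            per_region[rg, w] <- per_region[rg, w] + v[[w]]
        } else {
          pr <- params[params$endpoint == ep &
                         params$age_group %in% c(b, "ALL_AGES"), ]
          pr <- if (b %in% pr$age_group) pr[pr$age_group == b, ] else pr
          y0 <- (if (ep == "NCD_LRI") y0_all[[b]] else y0_single[[b]]) * reg_mult[[rg]]
          for (w in c("central", "low", "high")) {
            th <- switch(w, central = pr$theta,
                         low = pr$theta - 1.96 * pr$theta_se,
                         high = pr$theta + 1.96 * pr$theta_se)
            rr <- scalar_gemm(cvals[ci], th, pr$alpha, pr$mu, pr$nu, pr$zcf)
            per_region[rg, w] <- per_region[rg, w] + y0 * (rr - 1) / rr * pops[[b]]
          }
        }
      }
    }
    for (rg in REGIONS)
      exp_rows[[length(exp_rows) + 1]] <- data.frame(
        region = rg, endpoint = ep, central = per_region[rg, "central"],
        low = per_region[rg, "low"], high = per_region[rg, "high"])
    exp_rows[[length(exp_rows) + 1]] <- data.frame(
      region = "EUROPE", endpoint = ep, central = sum(per_region[, "central"]),
      low = sum(per_region[, "low"]), high = sum(per_region[, "high"]))
  }
  expected <- do.call(rbind, exp_rows)
  rownames(expected) <- NULL
  list(conc = conc, pop = pop, mask = mask, scheme = scheme, rates = rates,
       params = params, expected = expected)
}

known_truth_single_cell <- function() {
  grid <- grid_spec(lat = c(44.5, 45.5), lon = 10)   # 2 cells; second is sea
  conc <- conc_field(grid, matrix(c(12.4, 12.4), 2, 1), period_label = "oracle")
  mask <- country_mask(grid, matrix(c("XWA", NA), 2, 1))
  scheme <- region_scheme(data.frame(country = "XWA", region = "Western"))
  counts <- array(0, dim = c(2, 1, 12), dimnames = list(NULL, NULL, AGE_BANDS))
  counts[1, 1, "60-64"] <- 1e5
  pop <- pop_grid(grid, counts, year = 2010L)
  # theta tuned so that RR(12.4) = 1.25 exactly under the NCD+LRI shape
  z <- 12.4 - 2.4
  shape <- log(1 + z / 1.6) * (1 / (1 + exp(-(z - 15.5) / 36.8)))
  theta <- log(1.25) / shape
  params <- do.call(rbind, lapply(ENDPOINTS, function(ep) data.frame(
    family = "GEMM", endpoint = ep, age_group = "ALL_AGES",
    theta = theta, theta_se = 0, alpha = 1.6, mu = 15.5, nu = 36.8, zcf = 2.4)))
  params <- rbind(params, do.call(rbind, lapply(c("IHD", "CEV"), function(ep)
    do.call(rbind, lapply(AGE_BANDS, function(b) data.frame(
      family = "GEMM", endpoint = ep, age_group = b,
      theta = theta, theta_se = 0, alpha = 1.6, mu = 15.5, nu = 36.8, zcf = 2.4))))))
  class(params) <- c("rr_params", "data.frame")
  rates <- expand.grid(region = REGIONS, endpoint = ENDPOINTS, age_group = AGE_BANDS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rates$y0 <- ifelse(rates$endpoint == "NCD_LRI" & rates$age_group == "60-64", 0.01, 0)
  expected <- data.frame(
    region = c("Western", "EUROPE"), endpoint = "NCD_LRI",
    central = 0.01 * 0.2 * 1e5, low = 0.01 * 0.2 * 1e5, high = 0.01 * 0.2 * 1e5)
  list(conc = conc, pop = pop, mask = mask, scheme = scheme, rates = rates,
       params = params, expected = expected)
}
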