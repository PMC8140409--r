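#' Gridded attributable-mortality field
#'
#' Attributable deaths per year per cell x age band, with central / low /
#' high layers (95% confidence bounds), for one endpoint.
#'
#' @param grid A [grid_spec()].
#' @param endpoint Endpoint code.
#' @param deaths Numeric array `nlat x nlon x 12 x 3` with dimnames
#'   `(NULL, NULL, AGE_BANDS, c("central","low","high"))`.
#' @return Object of class `mortality_field`.
#' @export
mortality_field <- function(grid, endpoint, deaths) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!identical(dim(deaths)[3:4], c(length(AGE_BANDS), 3L)))
    stop_stage("validate", "deaths array must be nlat x nlon x 12 bands x 3 layers")
  if (any(!is.finite(deaths))) stop_stage("validate", "non-finite deaths")
  dimnames(deaths) <- list(NULL, NULL, AGE_BANDS, c("central", "low", "high"))
  structure(list(grid = grid, endpoint = endpoint, deaths = deaths),
            class = "mortality_field")
}

#' @export
print.mortality_field <- function(x, ...) {
  cat(sprintf("<mortality_field> %s: total %.1f (%.1f-%.1f) deaths/yr\n",
              x$endpoint, sum(x$deaths[, , , "central"]),
              sum(x$deaths[, , , "low"]), sum(x$deaths[, , , "high"])))
  invisible(x)
}

#' Attributable deaths in one cell
#'
#' The core attributable-mortality identity
#' \deqn{\Delta M = y_0 \cdot \frac{RR - 1}{RR} \cdot Pop}
#' applied componentwise to the central estimate and the two confidence
#' bounds of the risk ratio.
#'
#' @param y0 Baseline mortality rate, deaths per person per year, in `[0,1]`.
#' @param rr An [rr_value()].
#' @param pop Exposed persons, `>= 0`.
#' @return List with `central`, `low`, `high` attributable deaths per year.
#' @examples
#' cell_mortality(0.01, rr_value(1.25), 1e5)$central  # 200
#' @export
cell_mortality <- function(y0, rr, pop) {
  if (any(y0 < 0 | y0 > 1)) stop_stage("validate", "y0 must lie in [0, 1]")
  if (any(pop < 0)) stop_stage("validate", "negative population")
  af <- attributable_fraction(rr)
  list(central = y0 * af$central * pop,
       low = y0 * af$low * pop,
       high = y0 * af$high * pop)
}

# region label per cell (NA for sentinel cells), as nlat x nlon matrix
region_matrix <- function(mask, scheme) {
  codes <- mask$codes
  known <- !is.na(codes)
  reg <- matrix(NA_character_, nrow(codes), ncol(codes))
  reg[known] <- assign_region(codes[known], scheme)
  reg
}

#' Compute the attributable-mortality field for one endpoint
#'
#' Applies the attributable-mortality identity in every grid cell and adult
#' age band: the cell's region comes from the country mask and region
#' scheme, the baseline rate from the region x endpoint x band table, and
#' the risk ratio from the band-specific (or age-constant) exposure-response
#' parameters evaluated at the cell's concentration. Cells with a sentinel
#' country code contribute zero deaths.
#'
#' @param conc A [conc_field()].
#' @param pop A [pop_grid()] on the same grid.
#' @param rates Baseline-rate table (see [validate_baseline_rates()]).
#' @param params Parameter table from [load_rr_params()].
#' @param mask A [country_mask()] on the same grid.
#' @param endpoint One of [ENDPOINTS].
#' @param scheme A [region_scheme()].
#' @return A [mortality_field()].
#' @export
compute_endpoint <- function(conc, pop, rates, params, mask, endpoint,
                             scheme = default_region_scheme()) {
  stopifnot(inherits(conc, "conc_field"), inherits(pop, "pop_grid"),
            inherits(mask, "country_mask"))
  assert_same_grid("engine", conc$grid, pop$grid, mask$grid)
  if (!endpoint %in% ENDPOINTS) stop_stage("validate", "unknown endpoint ", endpoint)
  nlat <- length(conc$grid$lat); nlon <- length(conc$grid$lon)
  reg <- region_matrix(mask, scheme)
  live <- !is.na(reg) & !is.na(conc$values)
  cvec <- conc$values[live]
  deaths <- array(0, dim = c(nlat, nlon, length(AGE_BANDS), 3))
  y0_tab <- rates[rates$endpoint == endpoint, ]
  for (k in seq_along(AGE_BANDS)) {
    band <- AGE_BANDS[k]
    p <- select_rr_params(params, endpoint, band)
    rr <- eval_rr(cvec, p)
    y0r <- vapply(REGIONS, function(r) lookup_y0(y0_tab, r, endpoint, band), 0)
    y0 <- y0r[match(reg[live], REGIONS)]
    popk <- pop$counts[, , band][live]
    dm <- cell_mortality(y0, rr, popk)
    lay <- array(0, dim = c(nlat, nlon, 3))
    tmp <- matrix(0, nlat, nlon)
    tmp[live] <- dm$central; lay[, , 1] <- tmp
    tmp[live] <- dm$low;     lay[, , 2] <- tmp
    tmp[live] <- dm$high;    lay[, , 3] <- tmp
    deaths[, , k, ] <- lay
  }
  mortality_field(conc$grid, endpoint, deaths)
}

#' Derive the "other NCD" field by subtraction
#'
#' Other non-communicable-disease mortality is the all-cause (`NCD_LRI`)
#' envelope minus the five specific causes, floored at zero cellwise. Floor
#' events (cells where the specific causes exceed the envelope, e.g. from
#' rounding or inconsistent inputs) are counted and reported via a message
#' and the `"floored"` attribute.
#'
#' @param all_cause `NCD_LRI` [mortality_field()].
#' @param five_causes List of the five specific-cause fields (IHD, CEV,
#'   COPD, LC, LRI in any order).
#' @return A [mortality_field()] for `OTHER_NCD`.
#' @export
derive_other_ncd <- function(all_cause, five_causes) {
  stopifnot(inherits(all_cause, "mortality_field"), all_cause$endpoint == "NCD_LRI")
  eps <- vapply(five_causes, function(f) f$endpoint, "")
  if (!setequal(eps, SPECIFIC_CAUSES))
    stop_stage("validate", "five_causes must be exactly ", paste(SPECIFIC_CAUSES, collapse = ", "))
  for (f in five_causes) assert_same_grid("engine", all_cause$grid, f$grid)
  other <- all_cause$deaths
  for (f in five_causes) other <- other - f$deaths
  n_floor <- sum(other < 0)
  if (n_floor > 0) {
    message(sprintf("derive_other_ncd: floored %d negative cell-layer value(s) at 0", n_floor))
    other[other < 0] <- 0
  }
  # layerwise subtraction shifts every endpoint's slope in the same
  # direction, which can invert the bounds of the difference; restore the
  # cellwise ordering low <= central <= high
  lo <- pmin(other[, , , 1], other[, , , 2], other[, , , 3])
  hi <- pmax(other[, , , 1], other[, , , 2], other[, , , 3])
  other[, , , 2] <- lo
  other[, , , 3] <- hi
  out <- mortality_field(all_cause$grid, OTHER_NCD, other)
  attr(out, "floored") <- n_floor
  out
}

#' Aggregate a mortality field to regional and continental totals
#'
#' Sums attributable deaths per region x age band, adds per-region all-age
#' rows and a `EUROPE` row set (sum of the three regions). Confidence
#' bounds are summed linearly.
#'
#' @param field A [mortality_field()].
#' @param mask A [country_mask()] on the same grid.
#' @param scheme A [region_scheme()].
#' @return A `data.frame` (class `regional_summary`) with columns `region`,
#'   `endpoint`, `age_group`, `central`, `low`, `high`; `age_group == "ALL"`
#'   rows are band sums and `region == "EUROPE"` rows are region sums.
#' @export
aggregate_mortality <- function(field, mask, scheme = default_region_scheme()) {
  stopifnot(inherits(field, "mortality_field"), inherits(mask, "country_mask"))
  assert_same_grid("engine", field$grid, mask$grid)
  reg <- region_matrix(mask, scheme)
  rows <- list()
  tot <- array(0, dim = c(length(REGIONS), length(AGE_BANDS), 3))
  for (r in seq_along(REGIONS)) {
    sel <- !is.na(reg) & reg == REGIONS[r]
    for (k in seq_along(AGE_BANDS)) for (l in 1:3)
      tot[r, k, l] <- sum(field$deaths[, , k, l][sel])
  }
  for (r in seq_along(REGIONS)) {
    for (k in seq_along(AGE_BANDS))
      rows[[length(rows) + 1]] <- data.frame(
        region = REGIONS[r], endpoint = field$endpoint, age_group = AGE_BANDS[k],
        central = tot[r, k, 1], low = tot[r, k, 2], high = tot[r, k, 3])
    rows[[length(rows) + 1]] <- data.frame(
      region = REGIONS[r], endpoint = field$endpoint, age_group = "ALL",
      central = sum(tot[r, , 1]), low = sum(tot[r, , 2]), high = sum(tot[r, , 3]))
  }
  for (k in seq_along(AGE_BANDS))
    rows[[length(rows) + 1]] <- data.frame(
      region = "EUROPE", endpoint = field$endpoint, age_group = AGE_BANDS[k],
      central = sum(tot[, k, 1]), low = sum(tot[, k, 2]), high = sum(tot[, k, 3]))
  rows[[length(rows) + 1]] <- data.frame(
    region = "EUROPE", endpoint = field$endpoint, age_group = "ALL",
    central = sum(tot[, , 1]), low = sum(tot[, , 2]), high = sum(tot[, , 3]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("regional_summary", "data.frame")
  out
}

#' Deaths per square kilometre
#'
#' Cellwise division of attributable deaths (summed over bands, per layer)
#' by spherical cell area, for mortality-density maps.
#'
#' @param field A [mortality_field()].
#' @param areas An `area_field` from [cell_areas()] on the same grid.
#' @return List with `grid` and `nlat x nlon x 3` array `density`
#'   (deaths km-2 yr-1; layers central/low/high).
#' @export
per_area <- function(field, areas) {
  stopifnot(inherits(field, "mortality_field"), inherits(areas, "area_field"))
  assert_same_grid("engine", field$grid, areas$grid)
  if (any(areas$area <= 0)) stop_stage("validate", "non-positive cell area")
  dens <- array(0, dim = c(dim(areas$area), 3),
                dimnames = list(NULL, NULL, c("central", "low", "high")))
  for (l in 1:3)
    dens[, , l] <- apply(field$deaths[, , , l, drop = FALSE], c(1, 2), sum) / areas$area
  list(grid = field$grid, endpoint = field$endpoint, density = dens)
}

#' Endpoint shares of all-cause mortality
#'
#' Percentage contribution of each cause to the all-cause (`NCD_LRI`)
#' total over a summary table's `EUROPE` / all-age rows, reported unrounded
#' and rounded half-away-from-zero to integer percent.
#'
#' @param summary A combined `regional_summary` covering `NCD_LRI` and the
#'   causes of interest (typically the five specific causes plus
#'   `OTHER_NCD`).
#' @param region Row set to use (default `"EUROPE"`).
#' @return data.frame with `endpoint`, `share` (unrounded percent) and
#'   `share_pct` (integer percent).
#' @export
mortality_shares <- function(summary, region = "EUROPE") {
  rows <- summary[summary$region == region & summary$age_group == "ALL", ]
  all_cause <- rows$central[rows$endpoint == "NCD_LRI"]
  if (length(all_cause) != 1 || all_cause <= 0)
    stop_stage("validate", "summary must contain a positive all-cause (NCD_LRI) total")
  causes <- rows[rows$endpoint != "NCD_LRI", ]
  data.frame(endpoint = causes$endpoint,
             share = 100 * causes$central / all_cause,
             share_pct = round_half_up(100 * causes$central / all_cause))
}

#' Run the full multi-endpoint assessment
#'
#' Computes the all-cause `NCD_LRI` field and the five specific causes,
#' derives `OTHER_NCD` by subtraction, and aggregates everything to a
#' Table-2-style regional summary.
#'
#' @inheritParams compute_endpoint
#' @return List with `fields` (named list of seven [mortality_field()]s)
#'   and `summary` (row-bound `regional_summary` over all endpoints).
#' @export
run_hia <- function(conc, pop, rates, params, mask, scheme = default_region_scheme()) {
  fields <- list()
  for (ep in ENDPOINTS)
    fields[[ep]] <- compute_endpoint(conc, pop, rates, params, mask, ep, scheme)
  fields[[OTHER_NCD]] <- derive_other_ncd(fields$NCD_LRI, fields[SPECIFIC_CAUSES])
  summaries <- lapply(fields, aggregate_mortality, mask = mask, scheme = scheme)
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  class(summary) <- c("regional_summary", "data.frame")
  list(fields = fields, summary = summary)
}
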