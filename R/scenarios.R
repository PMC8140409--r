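#' Run one scenario from a configuration
#'
#' A scenario configuration names the input files of one assessment run:
#' concentration NetCDF, population CSV, optional projection-ratio CSV
#' (applied when present, turning a 2010 census grid into the 2050
#' projection), baseline-rate CSV, country-mask CSV (long `lat, lon,
#' country`), region-scheme CSV and risk-function family. Baseline rates
#' and risk-function parameters are shared across scenarios by
#' construction: the same files are referenced from both configurations.
#'
#' @param config Named list (or path to a YAML file with the same keys):
#'   `label`, `concentration`, `population`, `rates`, `mask`, `scheme`
#'   (optional; packaged default when absent), `projection_ratios`
#'   (optional), `family` (`"GEMM"` default), `rr_params` (optional path).
#' @return List with `label`, `fields`, `summary` (see [run_hia()]) and
#'   `inputs` (resolved file paths with MD5 checksums).
#' @export
run_scenario <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  need <- c("concentration", "population", "rates", "mask")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop_stage("config", "missing key(s): ", paste(miss, collapse = ", "))
  paths <- config[intersect(names(config),
                            c("concentration", "population", "rates", "mask",
                              "scheme", "projection_ratios", "rr_params"))]
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      stop_stage("config", nm, " file not found: ", paths[[nm]])

  conc <- read_concentration(config$concentration)
  pop <- read_population(config$population)
  mask <- read_mask(config$mask, conc$grid)
  scheme <- if (!is.null(config$scheme))
    region_scheme(read_table(config$scheme, "country_regions")) else default_region_scheme()
  rates <- validate_baseline_rates(read_table(config$rates, "baseline_rates"))
  family <- toupper(config$family %||% "GEMM")
  params <- load_rr_params(family, path = config$rr_params)
  if (!same_grid(pop$grid, conc$grid)) pop <- regrid_population(pop, conc$grid)
  if (!is.null(config$projection_ratios)) {
    ratios <- read_table(config$projection_ratios, "projection_ratios")
    pop <- apply_projection(pop, ratios, mask)
  }
  res <- run_hia(conc, pop, rates, params, mask, scheme)
  checks <- vapply(unlist(paths), function(p) unname(tools::md5sum(p)), "")
  list(label = config$label %||% "scenario", fields = res$fields,
       summary = res$summary, inputs = data.frame(file = unlist(paths), md5 = checks))
}

#' Read a country mask from long CSV
#'
#' Format `lat, lon, country` with `country` empty or `NA` for sea cells;
#' must tile the given grid exactly.
#'
#' @param path CSV path.
#' @param grid Expected [grid_spec()].
#' @return A [country_mask()].
#' @export
read_mask <- function(path, grid) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(country = "character"))
  if (!all(c("lat", "lon", "country") %in% names(df)))
    stop_stage("schema", "mask CSV must have columns lat, lon, country")
  codes <- matrix(NA_character_, length(grid$lat), length(grid$lon))
  i <- match(df$lat, grid$lat); j <- match(df$lon, grid$lon)
  if (any(is.na(i)) || any(is.na(j)))
    stop_stage("grid", "mask coordinates do not match the working grid")
  cc <- df$country; cc[cc == ""] <- NA_character_
  codes[cbind(i, j)] <- cc
  country_mask(grid, codes)
}

#' @rdname read_mask
#' @param mask A [country_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  df <- expand.grid(lat = mask$grid$lat, lon = mask$grid$lon,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$country <- as.vector(mask$codes)
  df$country[is.na(df$country)] <- ""
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Percent change between two summaries
#'
#' Rowwise `100 * (future - present) / present` on the central estimates of
#' two matching summary tables, reported unrounded and integer-rounded
#' (half-away-from-zero: 72.57% prints as +73%). Rows with a zero present
#' value are flagged `undefined` rather than raising an error.
#'
#' @param present,future `regional_summary` tables with identical row
#'   structure.
#' @return data.frame with the key columns, `present`, `future`, `pct`
#'   (unrounded), `pct_int` and logical `undefined`.
#' @export
percent_change <- function(present, future) {
  key <- c("region", "endpoint", "age_group")
  if (!identical(present[key], future[key]))
    stop_stage("validate", "summary tables have different row structure")
  pct <- ifelse(present$central == 0, NA_real_,
                100 * (future$central - present$central) / present$central)
  out <- cbind(present[key],
               data.frame(present = present$central, future = future$central,
                          pct = pct, pct_int = round_half_up(pct),
                          undefined = present$central == 0))
  out
}

#' Percent excess relative to this study's estimate
#'
#' Comparison of an estimate with an external reference value, expressed as
#' a share of the estimate itself: `100 * (estimate - reference) /
#' estimate`. This is the convention used when stating how much larger the
#' study's total is than earlier literature values.
#'
#' @param estimate This study's value.
#' @param reference External reference value.
#' @return List with `pct` (unrounded) and `pct_int`.
#' @export
percent_excess_vs_reference <- function(estimate, reference) {
  if (any(estimate == 0)) stop_stage("validate", "zero estimate")
  pct <- 100 * (estimate - reference) / estimate
  list(pct = pct, pct_int = round_half_up(pct))
}

#' Rowwise difference of two summaries
#'
#' `future - present` for central, low and high columns; the row structure
#' must match exactly.
#'
#' @inheritParams percent_change
#' @return A `regional_summary` of differences.
#' @export
delta_summary <- function(present, future) {
  key <- c("region", "endpoint", "age_group")
  if (!identical(present[key], future[key]))
    stop_stage("validate", "summary tables have different row structure")
  out <- present
  for (cn in c("central", "low", "high")) out[[cn]] <- future[[cn]] - present[[cn]]
  out
}

#' Decompose a future-minus-present change into drivers
#'
#' Uses the present scenario as the common reference and evaluates the
#' pipeline under the four input combinations:
#' * climate-only = dM(future conc, present pop) - dM(present, present)
#' * population-only = dM(present conc, future pop) - dM(present, present)
#' * interaction = total change - climate-only - population-only
#'
#' The three components sum to the total change exactly (rowwise identity on
#' every summary row).
#'
#' @param present_conc,future_conc [conc_field()]s on one grid.
#' @param present_pop,future_pop [pop_grid()]s on the same grid.
#' @param rates,params,mask,scheme Shared inputs as in [run_hia()].
#' @return List of `regional_summary` tables: `total`, `climate_only`,
#'   `population_only`, `interaction`, plus the four corner summaries in
#'   `corners`.
#' @export
decompose_change <- function(present_conc, future_conc, present_pop, future_pop,
                             rates, params, mask, scheme = default_region_scheme()) {
  assert_same_grid("scenario", present_conc$grid, future_conc$grid,
                   present_pop$grid, future_pop$grid)
  s_pp <- run_hia(present_conc, present_pop, rates, params, mask, scheme)$summary
  s_fp <- run_hia(future_conc, present_pop, rates, params, mask, scheme)$summary
  s_pf <- run_hia(present_conc, future_pop, rates, params, mask, scheme)$summary
  s_ff <- run_hia(future_conc, future_pop, rates, params, mask, scheme)$summary
  total <- delta_summary(s_pp, s_ff)
  climate <- delta_summary(s_pp, s_fp)
  population <- delta_summary(s_pp, s_pf)
  interaction <- total
  for (cn in c("central", "low", "high"))
    interaction[[cn]] <- total[[cn]] - climate[[cn]] - population[[cn]]
  list(total = total, climate_only = climate, population_only = population,
       interaction = interaction,
       corners = list(present = s_pp, conc_future = s_fp,
                      pop_future = s_pf, future = s_ff))
}
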