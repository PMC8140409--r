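#' Gridded concentration field
#'
#' Container for an annual-mean PM2.5 concentration field on a regular grid.
#' Values are micrograms per cubic metre; missing cells are `NA`, never
#' silently zero.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric `nlat x nlon` matrix (rows = latitudes ascending).
#' @param period_label Free-text averaging-period label, e.g. `"1991-2010"`.
#' @return An object of class `conc_field`.
#' @export
conc_field <- function(grid, values, period_label = "") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(grid$lat), length(grid$lon))))
    stop_stage("grid", "values matrix does not match grid dimensions")
  if (any(is.nan(values)) || any(is.infinite(values)))
    stop_stage("validate", "concentration values must be finite or NA")
  if (any(values < 0, na.rm = TRUE))
    stop_stage("validate", "negative concentration values")
  structure(list(grid = grid, values = values, period_label = as.character(period_label)),
            class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  cat(sprintf("<conc_field> '%s': %d x %d cells, mean %.2f, max %.2f ug m-3\n",
              x$period_label, nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Country-code mask
#'
#' One country code per cell (character), `NA` for sea / out-of-domain cells.
#'
#' @param grid A [grid_spec()].
#' @param codes Character `nlat x nlon` matrix of country codes.
#' @return An object of class `country_mask`.
#' @export
country_mask <- function(grid, codes) {
  stopifnot(inherits(grid, "grid_spec"))
  codes <- as.matrix(codes)
  storage.mode(codes) <- "character"
  if (!all(dim(codes) == c(length(grid$lat), length(grid$lon))))
    stop_stage("grid", "mask matrix does not match grid dimensions")
  structure(list(grid = grid, codes = codes), class = "country_mask")
}

CONC_UNITS <- "ug m-3"

#' Write a concentration field to CF-style NetCDF
#'
#' Dimensions `(lat, lon)` with coordinate units `degrees_north` /
#' `degrees_east`; the data variable carries units `"ug m-3"` and the
#' averaging period is stored as global attribute `period_label`.
#'
#' @param field A [conc_field()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_concentration <- function(field, path) {
  stopifnot(inherits(field, "conc_field"))
  if (any(is.infinite(field$values)) || any(is.nan(field$values)))
    stop_stage("validate", "non-finite concentration values")
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", field$grid$lat)
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", field$grid$lon)
  var <- ncdf4::ncvar_def("pm25", CONC_UNITS, list(dim_lat, dim_lon),
                          missval = -9999, prec = "double",
                          longname = "annual mean PM2.5 concentration")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var, field$values)
  ncdf4::ncatt_put(nc, 0, "period_label", field$period_label)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  invisible(path)
}

#' Read a concentration field from NetCDF
#'
#' Expects one 2-D data variable with a units attribute `"ug m-3"` and 1-D
#' coordinate variables in `degrees_north` / `degrees_east`. The grid is
#' inferred from the coordinates; longitudes on `[0, 360)` are rotated to
#' `[-180, 180)`.
#'
#' @param path NetCDF file path.
#' @return A [conc_field()].
#' @export
read_concentration <- function(path) {
  if (!file.exists(path)) stop_stage("io", "file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  v2d <- Filter(function(v) v$ndims == 2, nc$var)
  if (length(v2d) != 1)
    stop_stage("format", "expected exactly one 2-D variable, found ", length(v2d))
  var <- v2d[[1]]
  if (!identical(var$units, CONC_UNITS))
    stop_stage("format", sprintf("variable units '%s', expected '%s'", var$units, CONC_UNITS))
  dn <- vapply(var$dim, function(d) d$name, "")
  lat <- ncdf4::ncvar_get(nc, "lat")
  lon <- ncdf4::ncvar_get(nc, "lon")
  lat_units <- ncdf4::ncatt_get(nc, "lat", "units")$value
  lon_units <- ncdf4::ncatt_get(nc, "lon", "units")$value
  if (!identical(lat_units, "degrees_north") || !identical(lon_units, "degrees_east"))
    stop_stage("format", "coordinate units must be degrees_north / degrees_east")
  vals <- ncdf4::ncvar_get(nc, var$name, collapse_degen = FALSE)
  if (identical(dn, c("lon", "lat"))) vals <- t(vals)
  else if (!identical(dn, c("lat", "lon")))
    stop_stage("format", "variable dimensions must be (lat, lon)")
  pl <- ncdf4::ncatt_get(nc, 0, "period_label")
  grid <- grid_spec(lat, lon)
  conc_field(grid, vals, period_label = if (pl$hasatt) pl$value else "")
}

#' Write / read an age-structured population grid as long CSV
#'
#' Long format `lat, lon, age_group, count`, one row per (cell, band) with a
#' nonzero or zero count; every cell x band combination present. The
#' reference year is stored in a `# year:` comment header line.
#'
#' @param pop A [pop_grid()].
#' @param path CSV file path.
#' @return `path` (writer) or a [pop_grid()] (reader).
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "pop_grid"))
  bands <- dimnames(pop$counts)[[3]]
  df <- expand.grid(lat = pop$grid$lat, lon = pop$grid$lon,
                    age_group = bands, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$count <- as.vector(pop$counts)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# year: %d", pop$year), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  if (!file.exists(path)) stop_stage("io", "file not found: ", path)
  hdr <- readLines(path, n = 1)
  year <- if (grepl("^# year:", hdr)) as.integer(sub("^# year:\\s*", "", hdr)) else NA_integer_
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("lat", "lon", "age_group", "count")
  if (!all(need %in% names(df))) stop_stage("schema", "population CSV must have columns ", paste(need, collapse = ", "))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  bands <- unique(df$age_group)
  bands <- c(intersect(AGE_BAND_U25, bands), intersect(AGE_BANDS, bands))
  if (!all(df$age_group %in% bands)) stop_stage("schema", "unknown age_group labels in population CSV")
  grid <- grid_spec(lat, lon)
  counts <- array(0, dim = c(length(lat), length(lon), length(bands)),
                  dimnames = list(NULL, NULL, bands))
  i <- match(df$lat, lat); j <- match(df$lon, lon); k <- match(df$age_group, bands)
  counts[cbind(i, j, k)] <- df$count
  pop_grid(grid, counts, year = year)
}

TABLE_SCHEMAS <- list(
  baseline_rates    = c("region", "endpoint", "age_group", "y0"),
  projection_ratios = c("country", "age_group", "ratio"),
  country_regions   = c("country", "region"),
  rr_params         = c("family", "endpoint", "age_group", "theta", "theta_se",
                        "alpha", "mu", "nu", "zcf")
)

#' Read a typed input table
#'
#' Reads one of the pipeline's CSV tables and validates it against its named
#' schema. Lines starting with `#` are comments. Unknown columns are
#' rejected; rates and ratios must be non-negative.
#'
#' @param path CSV file path.
#' @param schema One of `"baseline_rates"`, `"projection_ratios"`,
#'   `"country_regions"`, `"rr_params"`.
#' @return A `data.frame` with exactly the schema's columns.
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(TABLE_SCHEMAS))
  if (!file.exists(path)) stop_stage("io", "file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- TABLE_SCHEMAS[[schema]]
  miss <- setdiff(cols, names(df))
  if (length(miss)) stop_stage("schema", schema, ": missing required column(s) ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), cols)
  if (length(extra)) stop_stage("schema", schema, ": unknown column(s) ", paste(extra, collapse = ", "))
  df <- df[cols]
  num <- intersect(c("y0", "ratio", "theta", "theta_se", "alpha", "mu", "nu", "zcf"), cols)
  for (cn in num) {
    df[[cn]] <- as.numeric(df[[cn]])
    if (any(!is.finite(df[[cn]]))) stop_stage("validate", schema, ": non-finite values in ", cn)
  }
  if (schema == "baseline_rates" && any(df$y0 < 0 | df$y0 > 1))
    stop_stage("validate", "baseline rates must lie in [0, 1] (per-person annual)")
  if (schema == "projection_ratios" && any(df$ratio < 0))
    stop_stage("validate", "projection ratios must be non-negative")
  if (schema == "rr_params" && any(df$theta_se < 0))
    stop_stage("validate", "theta_se must be non-negative")
  df
}

#' @rdname read_table
#' @param df Table to write (validated against the schema first).
#' @param comment Optional character vector of header comment lines (without
#'   the leading `#`).
#' @export
write_table <- function(df, path, schema, comment = NULL) {
  schema <- match.arg(schema, names(TABLE_SCHEMAS))
  cols <- TABLE_SCHEMAS[[schema]]
  stopifnot(all(cols %in% names(df)))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df[cols], con, row.names = FALSE)
  invisible(path)
}

# 1-d conservative overlap matrix between source and target cell edges.
# weights: fraction of source cell i falling in target cell j, measured in
# `coord` space (degrees for lon, sin(lat) for lat so fractions are exact
# area fractions on the sphere).
overlap_weights <- function(src_centers, src_res, tgt_centers, tgt_res, sin_space = FALSE) {
  tr <- function(x) if (sin_space) sin(pmin(90, pmax(-90, x)) * pi / 180) else x
  s_lo <- tr(src_centers - src_res / 2); s_hi <- tr(src_centers + src_res / 2)
  t_lo <- tr(tgt_centers - tgt_res / 2); t_hi <- tr(tgt_centers + tgt_res / 2)
  W <- matrix(0, length(src_centers), length(tgt_centers))
  for (j in seq_along(tgt_centers)) {
    ov <- pmax(0, pmin(s_hi, t_hi[j]) - pmax(s_lo, t_lo[j]))
    W[, j] <- ov / (s_hi - s_lo)
  }
  W
}

#' Conservatively regrid an age-structured population
#'
#' Area-weighted conservative aggregation of population counts from a source
#' grid to a target grid: each source cell's count is split across target
#' cells in proportion to the spherical-area fraction of the overlap.
#' Population is an extensive quantity, so totals per age group are preserved
#' (to within 1e-6 relative) whenever the target domain covers the source.
#'
#' @param pop A [pop_grid()] on the source grid.
#' @param target A [grid_spec()] for the working grid.
#' @return A [pop_grid()] on `target`.
#' @export
regrid_population <- function(pop, target) {
  stopifnot(inherits(pop, "pop_grid"), inherits(target, "grid_spec"))
  src <- pop$grid
  if (same_grid(src, target)) return(pop)
  W_lat <- overlap_weights(src$lat, src$res, target$lat, target$res, sin_space = TRUE)
  W_lon <- overlap_weights(src$lon, src$res, target$lon, target$res, sin_space = FALSE)
  if (sum(W_lat) == 0 || sum(W_lon) == 0)
    stop_stage("domain", "source and target domains are disjoint")
  bands <- dimnames(pop$counts)[[3]]
  out <- array(0, dim = c(length(target$lat), length(target$lon), length(bands)),
               dimnames = list(NULL, NULL, bands))
  for (k in seq_along(bands))
    out[, , k] <- t(W_lat) %*% pop$counts[, , k] %*% W_lon
  pop_grid(target, out, year = pop$year)
}
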