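#' Age-structured population grid
#'
#' Population counts per cell per 5-year age band on a regular grid. The
#' twelve adult bands ([AGE_BANDS]) are mandatory; an `"under25"` band may be
#' carried for pyramid display but is excluded from mortality computation.
#' Sexes are merged on ingest; the container holds combined counts only.
#'
#' @param grid A [grid_spec()].
#' @param counts Numeric array `nlat x nlon x nband` with band dimnames.
#' @param year Reference year of the counts (2010 for the present census
#'   grid, 2050 after projection).
#' @return An object of class `pop_grid`.
#' @export
pop_grid <- function(grid, counts, year = 2010L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(dim(counts)) != 3)
    stop_stage("validate", "counts must be a 3-d array (lat, lon, age band)")
  bands <- dimnames(counts)[[3]]
  if (is.null(bands)) stop_stage("validate", "counts array must carry age-band dimnames")
  extra <- setdiff(bands, c(AGE_BANDS, AGE_BAND_U25))
  if (length(extra)) stop_stage("validate", "unknown age band(s): ", paste(extra, collapse = ", "))
  if (!all(AGE_BANDS %in% bands))
    stop_stage("validate", "all 12 adult age bands are required")
  if (!all(dim(counts)[1:2] == c(length(grid$lat), length(grid$lon))))
    stop_stage("grid", "counts array does not match grid dimensions")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop_stage("validate", "population counts must be finite and >= 0")
  structure(list(grid = grid, counts = counts, year = as.integer(year)),
            class = "pop_grid")
}

#' @export
print.pop_grid <- function(x, ...) {
  cat(sprintf("<pop_grid> year %d: %d x %d cells, %d bands, total %.3g persons\n",
              x$year, dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              sum(x$counts)))
  invisible(x)
}

#' Total population
#'
#' Sum of counts over all cells and bands (adult bands plus the under-25
#' band if carried).
#'
#' @param pop A [pop_grid()].
#' @param bands Optional subset of band labels to total over.
#' @return Persons (scalar).
#' @export
total_population <- function(pop, bands = NULL) {
  stopifnot(inherits(pop, "pop_grid"))
  if (is.null(bands)) return(sum(pop$counts))
  bands <- intersect(bands, dimnames(pop$counts)[[3]])
  sum(pop$counts[, , bands, drop = FALSE])
}

#' Population pyramid shares
#'
#' Share of total population in each carried age band; shares sum to 1.
#'
#' @param pop A [pop_grid()].
#' @return Named numeric vector of shares per band.
#' @export
age_pyramid <- function(pop) {
  stopifnot(inherits(pop, "pop_grid"))
  tot <- sum(pop$counts)
  if (tot <= 0) stop_stage("validate", "zero total population has no pyramid")
  by_band <- apply(pop$counts, 3, sum)
  by_band / tot
}

#' Apply national population projection ratios
#'
#' Multiplies each cell's count in age band `a` by the country-level ratio
#' `ratio(country(cell), a)` (2050/2010 multipliers derived from national
#' projections). The spatial pattern within a country is unchanged up to
#' that scalar: no sub-national redistribution is modeled. Cells with
#' population but a sentinel (NA) country code are a coverage error.
#'
#' @param pop A [pop_grid()] with `year == 2010`.
#' @param ratios `projection_ratios` data.frame (`country`, `age_group`,
#'   `ratio`), complete over the mask's countries and the carried bands
#'   (an `under25` ratio defaults to 1 if absent).
#' @param mask A [country_mask()] on the same grid.
#' @return A [pop_grid()] with `year == 2050`.
#' @export
apply_projection <- function(pop, ratios, mask) {
  stopifnot(inherits(pop, "pop_grid"), inherits(mask, "country_mask"))
  assert_same_grid("demography", pop$grid, mask$grid)
  if (pop$year != 2010L)
    stop_stage("demography", "projection ratios are 2050/2010 multipliers; population year must be 2010")
  bands <- dimnames(pop$counts)[[3]]
  countries <- sort(unique(mask$codes[!is.na(mask$codes)]))
  orphan <- is.na(mask$codes) & apply(pop$counts, c(1, 2), sum) > 0
  if (any(orphan))
    stop_stage("coverage", sum(orphan), " cell(s) carry population but no country code")
  out <- pop$counts
  for (k in seq_along(bands)) {
    b <- bands[k]
    r <- ratios[ratios$age_group == b, , drop = FALSE]
    if (nrow(r) == 0) {
      if (b == AGE_BAND_U25) next   # under-25 band defaults to ratio 1
      stop_stage("coverage", "no projection ratios for age band ", b)
    }
    idx <- match(countries, r$country)
    if (any(is.na(idx)))
      stop_stage("coverage", "no ratio for country(ies) ",
                 paste(countries[is.na(idx)], collapse = ", "), " in band ", b)
    rv <- r$ratio[idx][match(mask$codes, countries)]  # per-cell ratio (NA on sea)
    rv[is.na(rv)] <- 1
    out[, , k] <- out[, , k] * matrix(rv, nrow = dim(out)[1])
  }
  pop_grid(pop$grid, out, year = 2050L)
}
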