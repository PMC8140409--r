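#' Region scheme: country-to-region mapping
#'
#' Europe is divided into three regions with distinct baseline mortality
#' rates, reflecting differences in public-health systems, economy and
#' climate. A scheme is a two-column data.frame (`country`, `region`) whose
#' countries are unique and whose regions are among `Western`, `Central`,
#' `Eastern`.
#'
#' @param mapping data.frame with columns `country` and `region`.
#' @return Validated scheme (class `region_scheme`).
#' @export
region_scheme <- function(mapping) {
  stopifnot(is.data.frame(mapping), all(c("country", "region") %in% names(mapping)))
  mapping <- mapping[c("country", "region")]
  if (anyDuplicated(mapping$country))
    stop_stage("validate", "country assigned to more than one region: ",
               paste(unique(mapping$country[duplicated(mapping$country)]), collapse = ", "))
  bad <- !mapping$region %in% REGIONS
  if (any(bad)) stop_stage("validate", "unknown region(s): ", paste(unique(mapping$region[bad]), collapse = ", "))
  class(mapping) <- c("region_scheme", "data.frame")
  mapping
}

#' Default three-region European scheme
#'
#' Western Europe: Portugal, Spain, France, Italy, United Kingdom, Ireland.
#' Central Europe: Denmark, Finland, Norway, Sweden, Austria, Belgium,
#' Germany, Luxembourg, the Netherlands, Switzerland. Eastern Europe:
#' Turkey, Belarus, Bulgaria, Czech Republic, Hungary, Poland, Moldova,
#' Romania, Russian Federation, Slovakia, Ukraine, Estonia, Latvia,
#' Lithuania, Albania, Bosnia and Herzegovina, Croatia, Greece, Montenegro,
#' North Macedonia, Serbia, Slovenia. Countries are ISO-3166 alpha-2 codes.
#' User-supplied schemes can be read with
#' `region_scheme(read_table(path, "country_regions"))`.
#'
#' @return A [region_scheme()].
#' @export
default_region_scheme <- function() {
  path <- system.file("extdata", "country_regions.csv", package = "pm25hia", mustWork = TRUE)
  region_scheme(read_table(path, "country_regions"))
}

#' Assign a country to its region
#'
#' @param country Country code(s).
#' @param scheme A [region_scheme()]; defaults to the packaged three-region
#'   European scheme.
#' @return Region label(s).
#' @export
assign_region <- function(country, scheme = default_region_scheme()) {
  idx <- match(country, scheme$country)
  if (any(is.na(idx) & !is.na(country)))
    stop_stage("coverage", "country code(s) not in region scheme: ",
               paste(unique(country[is.na(idx) & !is.na(country)]), collapse = ", "))
  scheme$region[idx]
}

#' Validate a baseline mortality rate table
#'
#' Baseline rates `y0` are per-person annual death probabilities (deaths
#' per person per year, not per 100,000) per region x endpoint x age band;
#' the same table serves present and future runs (baseline mortality is held
#' constant across scenarios). The table must be complete over the three
#' regions, the requested endpoints and the twelve adult bands, and the
#' all-cause `NCD_LRI` rate must be at least the largest single-cause rate
#' for every (region, band).
#'
#' @param rates `baseline_rates` data.frame (`region`, `endpoint`,
#'   `age_group`, `y0`).
#' @param endpoints Endpoints that must be covered.
#' @return The table, classed `baseline_rates`.
#' @export
validate_baseline_rates <- function(rates, endpoints = ENDPOINTS) {
  stopifnot(is.data.frame(rates))
  key <- paste(rates$region, rates$endpoint, rates$age_group)
  if (anyDuplicated(key)) stop_stage("validate", "duplicated baseline-rate row(s)")
  if (any(rates$y0 < 0 | rates$y0 > 1))
    stop_stage("validate", "baseline rates must lie in [0, 1]")
  want <- expand.grid(region = REGIONS, endpoint = endpoints, age_group = AGE_BANDS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  miss <- !paste(want$region, want$endpoint, want$age_group) %in% key
  if (any(miss))
    stop_stage("coverage", sum(miss), " missing baseline-rate triple(s), e.g. ",
               paste(want$region[miss][1], want$endpoint[miss][1], want$age_group[miss][1]))
  if ("NCD_LRI" %in% endpoints) {
    for (rg in REGIONS) for (b in AGE_BANDS) {
      sub <- rates[rates$region == rg & rates$age_group == b, ]
      all_cause <- sub$y0[sub$endpoint == "NCD_LRI"]
      singles <- sub$y0[sub$endpoint %in% SPECIFIC_CAUSES]
      if (length(singles) && length(all_cause) && all_cause < max(singles) - 1e-15)
        stop_stage("validate", sprintf(
          "all-cause y0 below a single-cause y0 for (%s, %s)", rg, b))
    }
  }
  class(rates) <- c("baseline_rates", "data.frame")
  rates
}

#' Look up a baseline mortality rate
#'
#' Pure table lookup: the exact stored `y0` for a (region, endpoint, age
#' band) triple. Repeated calls are identical; present and future scenarios
#' use the same table.
#'
#' @param rates Table from [validate_baseline_rates()] (or raw data.frame).
#' @param region,endpoint,age Triple to look up.
#' @return Scalar rate, deaths per person per year.
#' @export
lookup_y0 <- function(rates, region, endpoint, age) {
  hit <- rates$y0[rates$region == region & rates$endpoint == endpoint &
                    rates$age_group == age]
  if (length(hit) != 1)
    stop_stage("coverage", sprintf("no baseline rate for (%s, %s, %s)", region, endpoint, age))
  hit
}

#' Broadcast coarse age-band rates to 5-year bands
#'
#' Ingest helper: a rate published for a coarse band (e.g. `"25-44"` or
#' `"65plus"`) is copied to each constituent 5-year band. Broadcasts are
#' reported with a message so provenance stays visible in logs.
#'
#' @param rates data.frame (`region`, `endpoint`, `age_group`, `y0`) where
#'   `age_group` may be a coarse label `"lo-hi"` or `"NNplus"`.
#' @return data.frame on the 5-year bands.
#' @export
broadcast_coarse_rates <- function(rates) {
  band_lo <- as.integer(sub("-.*|plus", "", AGE_BANDS))
  out <- list()
  for (i in seq_len(nrow(rates))) {
    ag <- rates$age_group[i]
    if (ag %in% AGE_BANDS) { out[[length(out) + 1]] <- rates[i, ]; next }
    if (grepl("^\\d+plus$", ag)) {
      lo <- as.integer(sub("plus", "", ag)); hi <- Inf
    } else if (grepl("^\\d+-\\d+$", ag)) {
      lo <- as.integer(sub("-.*", "", ag)); hi <- as.integer(sub(".*-", "", ag))
    } else stop_stage("schema", "unrecognised age_group label: ", ag)
    hit <- AGE_BANDS[band_lo >= lo & band_lo <= hi]
    if (!length(hit)) stop_stage("schema", "coarse band ", ag, " covers no 5-year band")
    message(sprintf("broadcasting %s/%s/%s to %d bands",
                    rates$region[i], rates$endpoint[i], ag, length(hit)))
    rep_rows <- rates[rep(i, length(hit)), ]
    rep_rows$age_group <- hit
    out[[length(out) + 1]] <- rep_rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
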