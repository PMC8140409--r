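# shared fixtures: kept tiny so the whole suite stays fast

# small synthetic study spec (consistent present/future totals)
small_spec <- function(seed = 11L) {
  synth_spec(seed = seed, lat_range = c(40, 50), lon_range = c(0, 10),
             resolution = 0.5, n_hotspots = 3, n_clusters = 12,
             pop_total = 1e7, pop_total_future = 1e7 * 806 / 808)
}

small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synth_bundle(small_spec())
    cache
  }
})

gemm_params_tab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_rr_params("GEMM")
    cache
  }
})

# one-row GEMM parameter list (all-cause envelope, all ages)
ncd_all_age <- function() {
  p <- gemm_params_tab()
  as.list(p[p$endpoint == "NCD_LRI" & p$age_group == "ALL_AGES", ])
}

ier_demo_params <- function(alpha = 10, gamma = 0.05, delta = 1, zcf = 2.4) {
  list(family = "IER", endpoint = "IHD", age_group = "ALL_AGES",
       theta = 0, theta_se = 0, alpha = alpha, mu = gamma, nu = delta, zcf = zcf)
}

# uniform single-band population grid on an arbitrary grid
uniform_pop <- function(grid, count = 1000, band = "60-64", year = 2010L) {
  counts <- array(0, dim = c(length(grid$lat), length(grid$lon), 12),
                  dimnames = list(NULL, NULL, AGE_BANDS))
  counts[, , band] <- count
  pop_grid(grid, counts, year = year)
}

# printed Europe totals fixture (thousands)
europe_reference <- function() {
  utils::read.csv(system.file("extdata", "europe_reference_totals.csv",
                              package = "pm25hia", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}

europe_age_reference <- function() {
  utils::read.csv(system.file("extdata", "europe_age_totals.csv",
                              package = "pm25hia", mustWork = TRUE),
                  comment.char = "#", stringsAsFactors = FALSE)
}

# reference table recast as a regional_summary (ALL-age rows only)
reference_as_summary <- function() {
  df <- europe_reference()
  df$age_group <- "ALL"
  class(df) <- c("regional_summary", "data.frame")
  df
}
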