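#' Risk-ratio value with 95% confidence bounds
#'
#' @param central,low,high Numeric vectors (recycled to common length).
#' @return An object of class `rr_value`: list of three aligned numeric
#'   vectors with `low <= central <= high`.
#' @export
rr_value <- function(central, low = central, high = central) {
  n <- max(length(central), length(low), length(high))
  central <- rep_len(central, n); low <- rep_len(low, n); high <- rep_len(high, n)
  if (any(!is.finite(central) | !is.finite(low) | !is.finite(high)))
    stop_stage("validate", "non-finite risk ratio")
  if (any(low < 0)) stop_stage("validate", "negative risk ratio")
  if (any(low > central + 1e-12) || any(central > high + 1e-12))
    stop_stage("validate", "risk-ratio bounds must satisfy low <= central <= high")
  structure(list(central = central, low = low, high = high), class = "rr_value")
}

#' @export
print.rr_value <- function(x, ...) {
  n <- length(x$central)
  cat(sprintf("<rr_value> n=%d, central %.4f (%.4f-%.4f)%s\n", n,
              x$central[1], x$low[1], x$high[1], if (n > 1) " ..." else ""))
  invisible(x)
}

check_rr_params <- function(params, family) {
  need <- c("family", "endpoint", "age_group", "theta", "theta_se", "alpha", "mu", "nu", "zcf")
  if (!all(need %in% names(params)))
    stop_stage("validate", "rr parameter row must carry fields ", paste(need, collapse = ", "))
  if (!identical(as.character(params$family), family))
    stop_stage("validate", sprintf("parameter family '%s', expected '%s'", params$family, family))
  if (params$alpha <= 0 || params$nu <= 0 || params$zcf < 0 || params$theta_se < 0)
    stop_stage("validate", "rr shape parameters out of range (alpha>0, nu>0, zcf>=0, se>=0)")
  invisible(TRUE)
}

#' GEMM risk ratio
#'
#' Global Exposure Mortality Model hazard-ratio function
#' \deqn{RR(z) = \exp\{\theta \, \log(1 + z/\alpha)\, \omega(z)\}, \quad
#'       \omega(z) = \frac{1}{1 + e^{-(z-\mu)/\nu}}, \quad
#'       z = \max(0, C - z_{cf})}
#' with counterfactual concentration \eqn{z_{cf}} (default 2.4 ug m-3 in the
#' shipped parameter table, the lowest observed cohort concentration in the
#' GEMM cohorts). The 95% bounds replace \eqn{\theta} by
#' \eqn{\theta \mp 1.96\,SE(\theta)}; no uncertainty is propagated through
#' the shape parameters. At or below the counterfactual all three components
#' are exactly 1.
#'
#' @param concentration Numeric vector of annual-mean PM2.5, ug m-3.
#' @param params One parameter row (list or 1-row data.frame) with fields
#'   `family="GEMM"`, `theta`, `theta_se`, `alpha`, `mu`, `nu`, `zcf`.
#' @param reject_protective If `TRUE` (default) a central risk ratio below 1
#'   (only possible for `theta < 0`) is an error.
#' @return An [rr_value()] aligned with `concentration`.
#' @examples
#' p <- list(family = "GEMM", endpoint = "NCD_LRI", age_group = "ALL_AGES",
#'           theta = 0.1430, theta_se = 0.01807, alpha = 1.6, mu = 15.5,
#'           nu = 36.8, zcf = 2.4)
#' gemm_rr(12.4, p)$central  # ~1.140
#' @export
gemm_rr <- function(concentration, params, reject_protective = TRUE) {
  check_rr_params(params, "GEMM")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop_stage("validate", "concentration must be finite and >= 0")
  z <- pmax(0, concentration - params$zcf)
  shape <- log1p(z / params$alpha) / (1 + exp(-(z - params$mu) / params$nu))
  th <- params$theta
  ci <- 1.96 * params$theta_se
  central <- exp(th * shape)
  low <- exp((th - ci) * shape)
  high <- exp((th + ci) * shape)
  if (reject_protective && any(central < 1 - 1e-15))
    stop_stage("validate", "central GEMM risk ratio below 1 (theta < 0?)")
  rr_value(central, pmin(low, central), pmax(high, central))
}

#' IER risk ratio
#'
#' Integrated Exposure-Response function of the Global Burden of Disease,
#' \deqn{RR(z) = 1 + \alpha\,(1 - e^{-\gamma z^{\delta}}), \quad
#'       z = \max(0, C - z_{cf}).}
#' IER rows reuse the `rr_params` shape columns: `alpha` holds
#' \eqn{\alpha}, `mu` holds \eqn{\gamma} and `nu` holds \eqn{\delta}. The
#' parameter table carries no slope standard error for this family, so the
#' confidence bounds replicate the central estimate unless `theta_se > 0`
#' (in which case \eqn{\alpha} is scaled by \eqn{1 \mp 1.96\,SE/\alpha} --
#' not used by the shipped tables).
#'
#' @inheritParams gemm_rr
#' @return An [rr_value()].
#' @export
ier_rr <- function(concentration, params, reject_protective = TRUE) {
  check_rr_params(params, "IER")
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop_stage("validate", "concentration must be finite and >= 0")
  alpha <- params$alpha; gamma <- params$mu; delta <- params$nu
  if (gamma < 0 || delta <= 0) stop_stage("validate", "IER gamma must be >= 0, delta > 0")
  z <- pmax(0, concentration - params$zcf)
  central <- 1 + alpha * (1 - exp(-gamma * z^delta))
  if (params$theta_se > 0) {
    f <- 1.96 * params$theta_se
    low <- 1 + pmax(0, alpha - f) * (1 - exp(-gamma * z^delta))
    high <- 1 + (alpha + f) * (1 - exp(-gamma * z^delta))
  } else {
    low <- central; high <- central
  }
  if (reject_protective && any(central < 1 - 1e-15))
    stop_stage("validate", "central IER risk ratio below 1")
  rr_value(central, low, high)
}

#' Evaluate a risk ratio for either family
#' @inheritParams gemm_rr
#' @keywords internal
eval_rr <- function(concentration, params, reject_protective = TRUE) {
  switch(as.character(params$family),
         GEMM = gemm_rr(concentration, params, reject_protective),
         IER = ier_rr(concentration, params, reject_protective),
         stop_stage("validate", "unknown risk-function family: ", params$family))
}

#' Attributable fraction
#'
#' \eqn{AF = (RR - 1)/RR}, the share of baseline deaths attributable to
#' exposure above the counterfactual; applied componentwise to the central
#' estimate and both confidence bounds. For `RR >= 1`, `AF` lies in `[0, 1)`
#' and is strictly increasing in `RR`.
#'
#' @param rr An [rr_value()] (or plain numeric vector).
#' @param allow_protective If `FALSE` (default) components below 1 are an
#'   error; if `TRUE` they yield negative fractions.
#' @return Same shape as `rr`: list with `central`, `low`, `high` (or a
#'   numeric vector for numeric input).
#' @export
attributable_fraction <- function(rr, allow_protective = FALSE) {
  af1 <- function(x) {
    if (any(x == 0)) stop_stage("validate", "risk ratio of 0 has no attributable fraction")
    if (!allow_protective && any(x < 1 - 1e-12))
      stop_stage("validate", "risk ratio below 1; set allow_protective = TRUE to permit")
    (x - 1) / x
  }
  if (is.numeric(rr)) return(af1(rr))
  stopifnot(inherits(rr, "rr_value"))
  list(central = af1(rr$central), low = af1(rr$low), high = af1(rr$high))
}

#' Load a risk-function parameter table
#'
#' Reads an `rr_params` CSV (the packaged GEMM table by default), filters to
#' one family and enforces coverage: every endpoint must carry either an
#' `ALL_AGES` row or a complete set of the twelve 5-year bands; `IHD` and
#' `CEV` must be age-resolved (their risk ratios decline with the logarithm
#' of age), while `COPD`, `LC` and `LRI` may be age-constant. Duplicate
#' (family, endpoint, age_group) rows are rejected.
#'
#' @param family `"GEMM"` or `"IER"`.
#' @param path CSV path; `NULL` loads the packaged `gemm_params.csv`.
#' @return A `data.frame` of parameter rows (class `rr_params`).
#' @export
load_rr_params <- function(family = c("GEMM", "IER"), path = NULL) {
  family <- match.arg(family)
  if (is.null(path))
    path <- system.file("extdata", "gemm_params.csv", package = "pm25hia", mustWork = TRUE)
  df <- read_table(path, "rr_params")
  df <- df[df$family == family, , drop = FALSE]
  if (nrow(df) == 0) stop_stage("coverage", "no rows for family ", family)
  key <- paste(df$family, df$endpoint, df$age_group)
  if (anyDuplicated(key))
    stop_stage("validate", "duplicated (family, endpoint, age_group) row(s): ",
               paste(unique(key[duplicated(key)]), collapse = "; "))
  bad <- !df$endpoint %in% ENDPOINTS
  if (any(bad)) stop_stage("validate", "unknown endpoint(s): ", paste(unique(df$endpoint[bad]), collapse = ", "))
  bad_age <- !df$age_group %in% c(AGE_BANDS, ALL_AGES)
  if (any(bad_age)) stop_stage("validate", "unknown age_group label(s): ",
                               paste(unique(df$age_group[bad_age]), collapse = ", "))
  if (any(df$alpha <= 0) || any(df$nu <= 0) || any(df$zcf < 0))
    stop_stage("validate", "shape parameters out of range")
  for (ep in intersect(ENDPOINTS, unique(df$endpoint))) {
    ages <- df$age_group[df$endpoint == ep]
    full <- all(AGE_BANDS %in% ages)
    if (!(ALL_AGES %in% ages) && !full)
      stop_stage("coverage", ep, ": needs an ALL_AGES row or all 12 age bands")
    if (ep %in% c("IHD", "CEV") && !full)
      stop_stage("coverage", ep, ": age-specific rows required for all 12 bands")
  }
  miss <- setdiff(ENDPOINTS, unique(df$endpoint))
  if (length(miss))
    stop_stage("coverage", "endpoint(s) not covered: ", paste(miss, collapse = ", "))
  class(df) <- c("rr_params", "data.frame")
  df
}

#' Select the parameter row for one endpoint and age band
#'
#' Prefers the band-specific row; falls back to `ALL_AGES` where the table
#' is age-constant for that endpoint.
#'
#' @param params Table from [load_rr_params()].
#' @param endpoint Endpoint code.
#' @param age_group One of [AGE_BANDS].
#' @return A one-row list of parameters.
#' @export
select_rr_params <- function(params, endpoint, age_group) {
  rows <- params[params$endpoint == endpoint, , drop = FALSE]
  if (nrow(rows) == 0) stop_stage("coverage", "no parameters for endpoint ", endpoint)
  hit <- rows[rows$age_group == age_group, , drop = FALSE]
  if (nrow(hit) == 0) hit <- rows[rows$age_group == ALL_AGES, , drop = FALSE]
  if (nrow(hit) != 1) stop_stage("coverage", "no parameter row for ", endpoint, " / ", age_group)
  as.list(hit[1, ])
}
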