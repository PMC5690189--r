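#' Relative seriality model parameters
#'
#' Parameters of the Poisson-statistics relative seriality dose-response
#' model: `d50` is the uniform whole-organ dose giving 50% complication
#' probability, `gamma` the maximum normalized slope of the sigmoid response,
#' and `s` the relative seriality (large `s`: serial, chain-like organ;
#' `s` near 0: parallel organ). `s = 0` is rejected: the organ-level formula
#' is undefined there.
#'
#' @param d50 Dose in Gy at 50% complication probability, `> 0`.
#' @param gamma Dimensionless maximum normalized dose-response gradient, `> 0`.
#' @param s Dimensionless relative seriality, `> 0`.
#' @param endpoint Endpoint label carried as metadata.
#' @param horizon_years Risk horizon carried as metadata (the model has no
#'   time variable; the horizon is fixed by the parameter fit).
#' @return An object of class `seriality_params`.
#' @export
seriality_params <- function(d50, gamma, s = 1,
                             endpoint = "cardiac_mortality",
                             horizon_years = 15) {
  if (!is_number(d50) || d50 <= 0) stopf("d50 must be > 0")
  if (!is_number(gamma) || gamma <= 0) stopf("gamma must be > 0")
  if (!is_number(s) || s <= 0) stopf("s must be > 0 (s = 0 is undefined)")
  structure(list(d50 = d50, gamma = gamma, s = s, endpoint = endpoint,
                 horizon_years = horizon_years),
            class = "seriality_params")
}

#' Default cardiac-mortality parameter set (whole heart)
#'
#' Published fit for excess cardiac mortality at 15 years after irradiation:
#' `d50 = 70.3` Gy, `gamma = 0.96`, `s = 1`.
#' @return A `seriality_params` object.
#' @export
cardiac_seriality_params <- function() {
  seriality_params(d50 = 70.3, gamma = 0.96, s = 1)
}

#' Schneider modified linear-quadratic cancer-induction parameters
#'
#' Parameters of the mechanistic cancer-induction model behind the organ
#' equivalent dose (OED) concept: `rf` is the repopulation/repair fraction,
#' `alpha` the repairable-damage coefficient of the linear-quadratic model
#' (per Gy), and `mu` the low-dose linear-no-threshold slope of cancer
#' induction (cases per 10,000 persons per year per Gy). The effective
#' coefficient `alpha_prime` defaults to `alpha`; callers with a quadratic
#' component may supply `beta` and `dose_per_fraction`, in which case
#' `alpha_prime = alpha + beta * dose_per_fraction`.
#'
#' @param rf Repopulation/repair fraction, strictly between 0 and 1 (`rf = 1`
#'   makes the model singular).
#' @param alpha Repairable-damage coefficient in 1/Gy, `> 0`.
#' @param mu LNT slope, cases per 10,000 person-years per Gy, `> 0`.
#' @param alpha_prime Effective coefficient in 1/Gy; default `alpha`.
#' @param beta,dose_per_fraction Optional quadratic coefficient (1/Gy^2) and
#'   dose per fraction (Gy); when both are given they override `alpha_prime`.
#' @param endpoint Endpoint label carried as metadata.
#' @param horizon_years Risk horizon metadata (30 years by convention here).
#' @return An object of class `schneider_params`.
#' @export
schneider_params <- function(rf, alpha, mu, alpha_prime = NULL,
                             beta = NULL, dose_per_fraction = NULL,
                             endpoint = "cancer_induction",
                             horizon_years = 30) {
  if (!is_number(rf) || rf <= 0 || rf >= 1)
    stopf("rf must be strictly between 0 and 1")
  if (!is_number(alpha) || alpha <= 0) stopf("alpha must be > 0")
  if (!is_number(mu) || mu <= 0) stopf("mu must be > 0")
  if (!is.null(beta) && !is.null(dose_per_fraction)) {
    if (!is_number(beta) || beta < 0) stopf("beta must be >= 0")
    if (!is_number(dose_per_fraction) || dose_per_fraction <= 0)
      stopf("dose_per_fraction must be > 0")
    alpha_prime <- alpha + beta * dose_per_fraction
  }
  if (is.null(alpha_prime)) alpha_prime <- alpha
  if (!is_number(alpha_prime) || alpha_prime <= 0) stopf("alpha_prime must be > 0")
  structure(list(rf = rf, alpha = alpha, mu = mu, alpha_prime = alpha_prime,
                 endpoint = endpoint, horizon_years = horizon_years),
            class = "schneider_params")
}

#' Default cancer-induction parameter sets (lung, breast)
#'
#' Published fits: lung `rf = 0.84`, `alpha = 0.061`/Gy, `mu = 2.7`;
#' breast `rf = 0.62`, `alpha = 0.067`/Gy, `mu = 4.8` (cases per 10,000
#' person-years per Gy). `alpha_prime = alpha` in both.
#'
#' @param organ `"lung"` or `"breast"`.
#' @return A `schneider_params` object.
#' @export
default_schneider_params <- function(organ = c("lung", "breast")) {
  organ <- match.arg(organ)
  switch(organ,
    lung   = schneider_params(rf = 0.84, alpha = 0.061, mu = 2.7,
                              endpoint = "lung_cancer"),
    breast = schneider_params(rf = 0.62, alpha = 0.067, mu = 4.8,
                              endpoint = "breast_cancer"))
}

#' Read model parameter sets from a key-value config file
#'
#' The config uses Debian-control (DCF) blocks separated by blank lines, one
#' block per parameter set. Seriality blocks carry `model: seriality` with
#' fields `organ, endpoint, d50, gamma, s`; cancer-induction blocks carry
#' `model: schneider` with fields `organ, endpoint, rf, alpha, mu` and
#' optional `beta`, `dose_per_fraction`. The file shipped at
#' `system.file("extdata", "model_params.dcf", package = "dvhrisk")` holds
#' the package defaults.
#'
#' @param path Path to the config file; default: the shipped defaults.
#' @return A named list of parameter objects keyed `organ.endpoint`.
#' @export
read_model_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "model_params.dcf", package = "dvhrisk")
  if (!file.exists(path)) stopf("parameter config not found: %s", path)
  m <- read.dcf(path)
  out <- list()
  for (i in seq_len(nrow(m))) {
    row <- as.list(m[i, ])
    row <- row[!is.na(row)]
    num <- function(key) if (key %in% names(row)) as.double(row[[key]]) else NULL
    model <- row[["model"]]
    p <- switch(model,
      seriality = seriality_params(
        d50 = num("d50"), gamma = num("gamma"),
        s = if (is.null(num("s"))) 1 else num("s"),
        endpoint = row[["endpoint"]],
        horizon_years = if (is.null(num("horizon_years"))) 15 else num("horizon_years")),
      schneider = schneider_params(
        rf = num("rf"), alpha = num("alpha"), mu = num("mu"),
        beta = num("beta"), dose_per_fraction = num("dose_per_fraction"),
        endpoint = row[["endpoint"]],
        horizon_years = if (is.null(num("horizon_years"))) 30 else num("horizon_years")),
      stopf("unknown model '%s' in %s (block %d)", model, path, i))
    out[[paste(row[["organ"]], row[["endpoint"]], sep = ".")]] <- p
  }
  out
}

#' @export
print.seriality_params <- function(x, ...) {
  cat(sprintf("<seriality_params> %s: d50=%g Gy, gamma=%g, s=%g (horizon %g y)\n",
              x$endpoint, x$d50, x$gamma, x$s, x$horizon_years))
  invisible(x)
}

#' @export
print.schneider_params <- function(x, ...) {
  cat(sprintf("<schneider_params> %s: rf=%g, alpha=%g/Gy, alpha'=%g/Gy, mu=%g /1e4 py/Gy (horizon %g y)\n",
              x$endpoint, x$rf, x$alpha, x$alpha_prime, x$mu, x$horizon_years))
  invisible(x)
}
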