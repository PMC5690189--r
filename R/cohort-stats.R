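#' Per-patient, per-modality late-toxicity risk table
#'
#' Runs both response models over a cohort of plans: cardiac mortality via
#' the relative seriality model on the heart DVH (15-year horizon), and
#' lung/breast cancer induction via the Schneider model on the lung and
#' combined-breast DVHs (30-year horizon). Breast risk is computed only for
#' female patients; male patients simply have no breast rows.
#'
#' @param plans A `dvh_cohort` or list of [patient_plan()] objects; every
#'   plan must carry heart and lung DVHs, plus a breast DVH for female
#'   patients.
#' @param seriality Cardiac parameter set; default [cardiac_seriality_params()].
#' @param lung,breast Cancer-induction parameter sets; defaults
#'   [default_schneider_params()].
#' @return A data.frame of class `cohort_risk_table` with columns
#'   `patient_id, sex, modality, endpoint, value, horizon_years`; cardiac
#'   values are probabilities in `[0, 1]`, cancer values EAR in cases per
#'   10,000 person-years.
#' @export
compute_cohort_risks <- function(plans,
                                 seriality = cardiac_seriality_params(),
                                 lung = default_schneider_params("lung"),
                                 breast = default_schneider_params("breast")) {
  rows <- list()
  for (plan in plans) {
    pid <- plan$patient$patient_id
    sex <- plan$patient$sex
    mod <- plan$modality
    for (organ in c("heart", "lung")) {
      if (is.null(plan$dvhs[[organ]]))
        stopf("patient %s (%s): missing required %s DVH", pid, mod, organ)
    }
    if (sex == "F" && is.null(plan$dvhs[["breast"]]))
      stopf("patient %s (%s): female patient without breast DVH", pid, mod)
    add <- function(endpoint, value, horizon) {
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = pid, sex = sex, modality = mod, endpoint = endpoint,
        value = value, horizon_years = horizon, stringsAsFactors = FALSE)
    }
    add("cardiac_mortality", ntcp(plan$dvhs$heart, seriality),
        seriality$horizon_years)
    add("lung_cancer", ear(plan$dvhs$lung, lung), lung$horizon_years)
    if (sex == "F")
      add("breast_cancer", ear(plan$dvhs$breast, breast), breast$horizon_years)
  }
  out <- do.call(rbind, rows)
  dup <- duplicated(out[c("patient_id", "modality", "endpoint")])
  if (any(dup))
    stopf("duplicate (patient, modality, endpoint) row: %s/%s/%s",
          out$patient_id[dup][1], out$modality[dup][1], out$endpoint[dup][1])
  class(out) <- c("cohort_risk_table", class(out))
  out
}

#' Modality risk ratio for one endpoint
#'
#' Per-patient ratio `value(modality) / value(reference)` and its cohort
#' summary. The cohort "average risk ratio" is the arithmetic mean of the
#' per-patient ratios (the quantity paired naturally with a paired test on
#' patients); the ratio of cohort means is also returned for transparency.
#' Patients with a zero reference value are excluded from the ratios and
#' counted.
#'
#' @param table A `cohort_risk_table`.
#' @param endpoint Endpoint label.
#' @param modality Comparison modality.
#' @param reference Reference modality (conventionally `"3DCRT"`).
#' @return A list of class `risk_ratio`: `per_patient` (data.frame
#'   `patient_id, ratio`), `mean_ratio`, `ratio_of_means`, `n_excluded`.
#' @export
risk_ratio <- function(table, endpoint, modality, reference = "3DCRT") {
  a <- table[table$endpoint == endpoint & table$modality == modality, ]
  b <- table[table$endpoint == endpoint & table$modality == reference, ]
  ids <- intersect(a$patient_id, b$patient_id)
  if (length(ids) == 0L)
    stopf("no patients with both %s and %s values for endpoint %s",
          modality, reference, endpoint)
  va <- a$value[match(ids, a$patient_id)]
  vb <- b$value[match(ids, b$patient_id)]
  keep <- vb > 0
  structure(list(
    endpoint = endpoint, modality = modality, reference = reference,
    per_patient = data.frame(patient_id = ids[keep],
                             ratio = va[keep] / vb[keep],
                             stringsAsFactors = FALSE),
    mean_ratio = mean(va[keep] / vb[keep]),
    ratio_of_means = mean(va) / mean(vb),
    n_excluded = sum(!keep)),
    class = "risk_ratio")
}

#' @export
print.risk_ratio <- function(x, ...) {
  cat(sprintf("<risk_ratio> %s %s/%s: mean of ratios %.3g (ratio of means %.3g, n=%d, excluded %d)\n",
              x$endpoint, x$modality, x$reference, x$mean_ratio,
              x$ratio_of_means, nrow(x$per_patient), x$n_excluded))
  invisible(x)
}

#' Classical paired t-test
#'
#' Two-sided paired t-test on the differences `a - b`: `t = mean(d) /
#' (sd(d)/sqrt(n))` with `n - 1` degrees of freedom. When every difference
#' is exactly zero the statistic is undefined; by convention the result is
#' flagged degenerate with `p = 1` ("no difference").
#'
#' @param a,b Paired per-patient values of equal length `>= 2`.
#' @return A list of class `paired_t`: `t`, `df`, `p_value`, `mean_diff`,
#'   `degenerate`.
#' @examples
#' paired_t_test(c(1, 2, 3), c(1, 3, 5))  # t = -sqrt(3), p ~= 0.225
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stopf("a and b must be paired (equal length)")
  n <- length(a)
  if (n < 2L) stopf("paired t-test needs at least 2 pairs")
  d <- a - b
  if (all(d == 0))
    return(structure(list(t = NA_real_, df = n - 1L, p_value = 1,
                          mean_diff = 0, degenerate = TRUE),
                     class = "paired_t"))
  se <- stats::sd(d) / sqrt(n)
  t_stat <- mean(d) / se
  structure(list(t = t_stat, df = n - 1L,
                 p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
                 mean_diff = mean(d), degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate)
    cat("<paired_t> degenerate: all differences zero, p = 1\n")
  else
    cat(sprintf("<paired_t> t = %.4g, df = %d, p = %.4g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Cohort modality comparison: ratios and paired tests
#'
#' Convenience wrapper producing, for each endpoint and each non-reference
#' modality, the [risk_ratio()] summary and the [paired_t_test()] of the
#' per-patient risks against the reference modality.
#'
#' @param table A `cohort_risk_table`.
#' @param reference Reference modality.
#' @return A data.frame with one row per (endpoint, modality): columns
#'   `endpoint, modality, reference, n, mean_ratio, ratio_of_means,
#'   n_excluded, t, df, p_value, degenerate`.
#' @export
compare_modalities <- function(table, reference = "3DCRT") {
  endpoints <- unique(table$endpoint)
  modalities <- setdiff(unique(table$modality), reference)
  rows <- list()
  for (ep in endpoints) {
    for (mod in modalities) {
      rr <- risk_ratio(table, ep, mod, reference)
      a <- table[table$endpoint == ep & table$modality == mod, ]
      b <- table[table$endpoint == ep & table$modality == reference, ]
      ids <- intersect(a$patient_id, b$patient_id)
      tt <- if (length(ids) >= 2L)
        paired_t_test(a$value[match(ids, a$patient_id)],
                      b$value[match(ids, b$patient_id)])
      else  # a single patient supports a ratio but no test
        list(t = NA_real_, df = NA_integer_, p_value = NA_real_,
             degenerate = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        endpoint = ep, modality = mod, reference = reference,
        n = length(ids), mean_ratio = rr$mean_ratio,
        ratio_of_means = rr$ratio_of_means, n_excluded = rr$n_excluded,
        t = if (tt$degenerate) NA_real_ else tt$t, df = tt$df,
        p_value = tt$p_value, degenerate = tt$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity of risk estimates to a relative absolute-dose error
#'
#' Recomputes every risk with all DVH doses scaled by `1 - delta` and
#' `1 + delta` and summarizes the worst-case change per endpoint: maximum
#' absolute change in percentage points for cardiac mortality, maximum
#' relative change for the cancer EARs (which are near-linear in dose in the
#' low-dose regime, so small relative dose errors propagate roughly
#' one-to-one).
#'
#' @param plans A `dvh_cohort`.
#' @param delta Relative dose error, `0 <= delta < 1`.
#' @param ... Parameter sets forwarded to [compute_cohort_risks()].
#' @return A list of class `dose_sensitivity`: `delta`, `summary` (data.frame
#'   `endpoint, measure, max_change`), and the three risk tables (`base`,
#'   `low`, `high`).
#' @export
dose_uncertainty_sensitivity <- function(plans, delta, ...) {
  if (!is_number(delta) || delta < 0 || delta >= 1)
    stopf("delta must be in [0, 1)")
  scale_plans <- function(f) {
    out <- lapply(plans, function(plan) {
      plan$dvhs <- lapply(plan$dvhs, scale_dose, factor = f)
      plan
    })
    class(out) <- class(plans)
    out
  }
  base <- compute_cohort_risks(plans, ...)
  low <- if (delta > 0) compute_cohort_risks(scale_plans(1 - delta), ...) else base
  high <- if (delta > 0) compute_cohort_risks(scale_plans(1 + delta), ...) else base
  rows <- list()
  for (ep in unique(base$endpoint)) {
    i <- base$endpoint == ep
    v0 <- base$value[i]; v1 <- low$value[i]; v2 <- high$value[i]
    if (ep == "cardiac_mortality") {
      change <- max(abs(v1 - v0), abs(v2 - v0)) * 100
      measure <- "max_abs_change_pp"
    } else {
      rel <- c(abs(v1 - v0), abs(v2 - v0)) / ifelse(v0 > 0, v0, NA_real_)
      change <- max(rel, na.rm = TRUE)
      measure <- "max_rel_change"
    }
    rows[[length(rows) + 1L]] <- data.frame(endpoint = ep, measure = measure,
                                            max_change = change,
                                            stringsAsFactors = FALSE)
  }
  structure(list(delta = delta, summary = do.call(rbind, rows),
                 base = base, low = low, high = high),
            class = "dose_sensitivity")
}

#' Sensitivity of risk estimates to a uniform secondary-neutron dose bath
#'
#' Adds a uniform whole-organ dose-equivalent of
#' `bath_msv_per_gy / 1000 * prescription` Gy to every organ DVH of the
#' proton (IMPT) plans — modelling the neutron bath of scanned proton
#' delivery, with any RBE weighting (up to a conservative cap of 20) already
#' folded into the caller's mSv/Gy figure — and reports the change in every
#' IMPT risk.
#'
#' @param plans A `dvh_cohort`.
#' @param bath_msv_per_gy Neutron dose-equivalent per treatment Gy, in
#'   mSv/Gy, `>= 0`; default 0 (no bath).
#' @param rbe_cap Upper bound accepted for the implied weighting; values of
#'   `bath_msv_per_gy` above `100 * rbe_cap` are rejected as unphysical.
#' @param ... Parameter sets forwarded to [compute_cohort_risks()].
#' @return A list of class `neutron_sensitivity`: `bath_msv_per_gy`,
#'   `deltas` (data.frame `patient_id, endpoint, base, perturbed, delta` for
#'   IMPT rows), and `summary` (max absolute delta per endpoint; cardiac in
#'   probability, cancers in EAR units).
#' @export
neutron_bath_sensitivity <- function(plans, bath_msv_per_gy = 0, rbe_cap = 20,
                                     ...) {
  if (!is_number(bath_msv_per_gy) || bath_msv_per_gy < 0)
    stopf("bath_msv_per_gy must be >= 0")
  if (bath_msv_per_gy > 100 * rbe_cap)
    stopf("bath_msv_per_gy = %g exceeds the physical range (cap %g)",
          bath_msv_per_gy, 100 * rbe_cap)
  perturb <- function(plan) {
    if (plan$modality != "IMPT") return(plan)
    bath_gy <- bath_msv_per_gy / 1000 * plan$patient$prescription_gy
    if (bath_gy > 0) plan$dvhs <- lapply(plan$dvhs, shift_dose, delta_gy = bath_gy)
    plan
  }
  base <- compute_cohort_risks(plans, ...)
  pert_plans <- lapply(plans, perturb)
  class(pert_plans) <- class(plans)
  pert <- compute_cohort_risks(pert_plans, ...)
  i <- base$modality == "IMPT"
  deltas <- data.frame(patient_id = base$patient_id[i],
                       endpoint = base$endpoint[i], base = base$value[i],
                       perturbed = pert$value[i],
                       delta = pert$value[i] - base$value[i],
                       stringsAsFactors = FALSE)
  summ <- stats::aggregate(abs(deltas$delta),
                           by = list(endpoint = deltas$endpoint), FUN = max)
  names(summ)[2] <- "max_abs_delta"
  structure(list(bath_msv_per_gy = bath_msv_per_gy, deltas = deltas,
                 summary = summ),
            class = "neutron_sensitivity")
}
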