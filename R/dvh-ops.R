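#' Convert a cumulative DVH to differential form
#'
#' Takes first differences of the "volume receiving at least dose" curve:
#' the bin `[d_k, d_{k+1})` receives `frac_ge(d_k) - frac_ge(d_{k+1})`.
#' The final tabulated fraction must be ~0, i.e. the export covers the full
#' dose range of the organ, otherwise volume would be lost.
#'
#' @param c_dvh A `cumulative_dvh` with at least two points.
#' @return A `differential_dvh` on the grid of tabulated doses.
#' @export
cumulative_to_differential <- function(c_dvh) {
  validate_cumulative_dvh(c_dvh)
  n <- length(c_dvh$dose_gy)
  if (n < 2L)
    stopf("cumulative DVH (%s): need at least 2 points to form bins", c_dvh$organ)
  last <- c_dvh$frac_ge[n]
  if (last > .VOL_TOL)
    stopf("cumulative DVH (%s): last fraction is %.3g, not 0; the curve must extend past the maximum organ dose",
          c_dvh$organ, last)
  differential_dvh(
    lo = c_dvh$dose_gy[-n], hi = c_dvh$dose_gy[-1],
    frac_volume = -diff(c_dvh$frac_ge),
    organ = c_dvh$organ, dose_kind = c_dvh$dose_kind)
}

#' Convert a differential DVH to cumulative form
#'
#' The fraction at dose `x` is the total fractional volume of bins with
#' `lo >= x`; points are tabulated at every bin edge, starting at `(0, 1)`
#' and ending at zero at the top edge.
#'
#' @param d A `differential_dvh`.
#' @return A `cumulative_dvh`.
#' @export
differential_to_cumulative <- function(d) {
  validate_differential_dvh(d)
  n <- length(d$lo)
  tail_sum <- rev(cumsum(rev(d$frac_volume)))    # fraction receiving >= lo[i]
  dose <- c(d$lo, d$hi[n])
  frac <- c(tail_sum, 0)
  if (dose[1] > 0) {
    dose <- c(0, dose)
    frac <- c(1, frac)
  } else {
    frac[1] <- 1   # guard rounding: whole organ receives >= 0 Gy
  }
  cumulative_dvh(dose, pmin(pmax(frac, 0), 1),
                 organ = d$organ, dose_kind = d$dose_kind)
}

#' Rebin a differential DVH onto a uniform grid
#'
#' The target grid has the requested `width` and is aligned so that the first
#' source edge falls on a grid line where possible. Each source bin's volume
#' is apportioned to target bins proportionally to dose overlap, so total
#' volume is conserved exactly and the mean dose moves by at most half a
#' target width.
#'
#' @param d A `differential_dvh`.
#' @param width Target bin width in Gy, `> 0`.
#' @return A `differential_dvh` on the uniform grid.
#' @export
rebin <- function(d, width) {
  validate_differential_dvh(d)
  if (!is_number(width) || width <= 0) stopf("width must be a positive number")
  start <- floor(min(d$lo) / width + 1e-9) * width
  k_max <- ceiling((max(d$hi) - start) / width - 1e-9)
  edges <- start + width * seq.int(0, max(k_max, 1L))
  m <- length(edges) - 1L
  out <- numeric(m)
  for (i in seq_along(d$lo)) {
    lo_i <- d$lo[i]; hi_i <- d$hi[i]; v <- d$frac_volume[i]
    if (v == 0) next
    j0 <- max(1L, min(m, floor((lo_i - start) / width + 1e-9) + 1L))
    j1 <- max(1L, min(m, ceiling((hi_i - start) / width - 1e-9)))
    ov <- pmin(hi_i, edges[(j0 + 1L):(j1 + 1L)]) - pmax(lo_i, edges[j0:j1])
    out[j0:j1] <- out[j0:j1] + v * ov / (hi_i - lo_i)
  }
  differential_dvh(edges[-length(edges)], edges[-1], out,
                   organ = d$organ, dose_kind = d$dose_kind)
}

#' Fraction of organ volume receiving at least a threshold dose
#'
#' The classical Vx planning metric (e.g. V5Gy, V20Gy), computed from the
#' differential DVH as the total fractional volume of bins whose midpoint
#' dose is at or above the threshold.
#'
#' @param d A `differential_dvh`.
#' @param threshold Dose threshold in Gy, `>= 0`.
#' @return Fraction of volume in `[0, 1]`.
#' @export
vx <- function(d, threshold) {
  validate_differential_dvh(d)
  if (!is_number(threshold) || threshold < 0) stopf("threshold must be >= 0")
  sum(d$frac_volume[bin_midpoints(d) >= threshold])
}

#' Mean organ dose of a differential DVH
#'
#' Volume-weighted mean of bin midpoint doses.
#' @param d A `differential_dvh`.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(d) {
  validate_differential_dvh(d)
  sum(bin_midpoints(d) * d$frac_volume)
}

#' Scale all doses of a DVH by a multiplicative factor
#'
#' Multiplies every bin edge by `factor` and leaves volumes untouched. Used
#' for RBE weighting of proton plans (factor 1.1) and for absolute-dose
#' sensitivity analyses (factors `1 +/- delta`).
#'
#' @param d A `differential_dvh`.
#' @param factor Positive scale factor.
#' @param dose_kind Optional new `dose_kind` label; set to
#'   `"rbe_weighted_gy"` when the factor is an RBE weighting.
#' @return A `differential_dvh` with scaled dose axis.
#' @export
scale_dose <- function(d, factor, dose_kind = NULL) {
  validate_differential_dvh(d)
  if (!is_number(factor) || factor <= 0) stopf("factor must be > 0")
  d$lo <- d$lo * factor
  d$hi <- d$hi * factor
  if (!is.null(dose_kind)) {
    d$dose_kind <- match.arg(dose_kind, c("physical_gy", "rbe_weighted_gy"))
  }
  validate_differential_dvh(d)
}

#' Shift all doses of a DVH by a uniform additive dose
#'
#' Adds `delta_gy` to every bin edge, modelling a uniform whole-organ dose
#' bath (e.g. a secondary-neutron dose-equivalent contribution) on top of
#' the planned distribution.
#'
#' @param d A `differential_dvh`.
#' @param delta_gy Additive dose in Gy, `>= 0`.
#' @return A `differential_dvh` with shifted dose axis.
#' @export
shift_dose <- function(d, delta_gy) {
  validate_differential_dvh(d)
  if (!is_number(delta_gy) || delta_gy < 0) stopf("delta_gy must be >= 0")
  d$lo <- d$lo + delta_gy
  d$hi <- d$hi + delta_gy
  validate_differential_dvh(d)
}

#' Equieffective dose in 2-Gy fractions (EQD2) transform of a DVH
#'
#' Optional fractionation correction: each bin midpoint dose `D` delivered in
#' `n_fractions` equal fractions is converted to
#' `D * (D/n + ab) / (2 + ab)` with `ab` the organ's alpha/beta ratio in Gy.
#' Off by default throughout the package: the response models are applied to
#' the planned (physical or RBE-weighted) DVH unless the caller explicitly
#' transforms it.
#'
#' @param d A `differential_dvh`.
#' @param alpha_beta Organ alpha/beta ratio in Gy, `> 0`.
#' @param n_fractions Number of equal fractions, `>= 1`.
#' @return A `differential_dvh` on the EQD2 dose axis.
#' @export
eqd2_dvh <- function(d, alpha_beta, n_fractions) {
  validate_differential_dvh(d)
  if (!is_number(alpha_beta) || alpha_beta <= 0) stopf("alpha_beta must be > 0")
  if (!is_number(n_fractions) || n_fractions < 1) stopf("n_fractions must be >= 1")
  f <- function(x) x * (x / n_fractions + alpha_beta) / (2 + alpha_beta)
  # transform edges; monotone increasing for x >= 0 so bin order is preserved
  d$lo <- f(d$lo)
  d$hi <- f(d$hi)
  validate_differential_dvh(d)
}
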