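#' Differential dose-volume histogram
#'
#' A differential DVH describes how an organ's volume is distributed over
#' absorbed dose: contiguous half-open dose bins `[lo, hi)` each carrying the
#' fraction of organ volume irradiated to a dose inside the bin. The fractions
#' sum to one, i.e. the whole organ is accounted for; unirradiated tissue is
#' carried as an explicit zero-dose bin so that downstream response models see
#' the full organ.
#'
#' The bin "dose" used by all response models is the midpoint `(lo + hi) / 2`,
#' an unbiased convention for narrow bins (0.1 Gy by default in this package).
#'
#' @param lo,hi Numeric vectors of bin edges in Gy; bins must be sorted,
#'   non-overlapping and contiguous (`hi[i] == lo[i + 1]`).
#' @param frac_volume Fraction of organ volume per bin, in `[0, 1]`, summing
#'   to 1 within `1e-6`.
#' @param organ Organ label: `"heart"`, `"lung"`, `"breast"` or `"other"`.
#'   Lungs are treated as a single paired organ and breasts as one combined
#'   structure; per-side DVHs should be volume-weighted and summed on input.
#' @param dose_kind `"physical_gy"` or `"rbe_weighted_gy"`. Metadata only:
#'   models are applied to the numeric dose as given (proton doses are
#'   conventionally RBE-weighted by 1.1).
#' @return An object of class `differential_dvh`.
#' @examples
#' d <- differential_dvh(lo = c(0, 10), hi = c(10, 20),
#'                       frac_volume = c(0.6, 0.4), organ = "lung")
#' mean_dose(d)
#' @seealso [cumulative_dvh()], [cumulative_to_differential()], [rebin()]
#' @export
differential_dvh <- function(lo, hi, frac_volume,
                             organ = c("other", "heart", "lung", "breast"),
                             dose_kind = c("physical_gy", "rbe_weighted_gy")) {
  organ <- match.arg(organ)
  dose_kind <- match.arg(dose_kind)
  if (length(lo) != length(hi) || length(lo) != length(frac_volume))
    stopf("lo, hi and frac_volume must have equal length")
  if (length(lo) == 0L) stopf("a differential DVH needs at least one bin")
  d <- structure(
    list(organ = organ, lo = as.double(lo), hi = as.double(hi),
         frac_volume = as.double(frac_volume), dose_kind = dose_kind),
    class = "differential_dvh")
  validate_differential_dvh(d)
}

#' @rdname differential_dvh
#' @param d A `differential_dvh` object to validate.
#' @export
validate_differential_dvh <- function(d) {
  with(d, {
    if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(!is.finite(frac_volume)))
      stopf("DVH (%s): non-finite bin values", organ)
    if (any(lo < 0)) stopf("DVH (%s): bin lower edges must be >= 0", organ)
    if (any(hi <= lo)) stopf("DVH (%s): each bin needs hi > lo (bin %d)",
                             organ, which(hi <= lo)[1])
    if (is.unsorted(lo, strictly = TRUE))
      stopf("DVH (%s): bins must be sorted by lo", organ)
    if (length(lo) > 1L) {
      gap <- abs(hi[-length(hi)] - lo[-1])
      bad <- which(gap > 1e-9 * pmax(1, hi[-length(hi)]))
      if (length(bad))
        stopf("DVH (%s): bins must be contiguous (gap after bin %d)", organ, bad[1])
    }
    if (any(frac_volume < -.VOL_TOL) || any(frac_volume > 1 + .VOL_TOL))
      stopf("DVH (%s): frac_volume outside [0, 1]", organ)
    if (abs(sum(frac_volume) - 1) > .VOL_TOL)
      stopf("DVH (%s): frac_volume sums to %.8f, not 1 (carry unirradiated volume in a zero-dose bin)",
            organ, sum(frac_volume))
  })
  d
}

#' Cumulative dose-volume histogram
#'
#' The interchange form used by most planning-system exports: at each dose the
#' fraction of organ volume receiving at least that dose. Doses must be
#' strictly increasing, fractions non-increasing, and the curve starts at
#' `(0, 1)` (a leading point at dose 0 with fraction 1 is prepended if
#' absent).
#'
#' @param dose_gy Strictly increasing doses in Gy.
#' @param frac_ge Fraction of volume receiving at least each dose;
#'   non-increasing, in `[0, 1]`.
#' @inheritParams differential_dvh
#' @return An object of class `cumulative_dvh`.
#' @seealso [differential_to_cumulative()], [cumulative_to_differential()]
#' @export
cumulative_dvh <- function(dose_gy, frac_ge,
                           organ = c("other", "heart", "lung", "breast"),
                           dose_kind = c("physical_gy", "rbe_weighted_gy")) {
  organ <- match.arg(organ)
  dose_kind <- match.arg(dose_kind)
  if (length(dose_gy) != length(frac_ge)) stopf("dose_gy and frac_ge lengths differ")
  if (length(dose_gy) == 0L) stopf("a cumulative DVH needs at least one point")
  if (dose_gy[1] > 0) {
    dose_gy <- c(0, dose_gy)
    frac_ge <- c(1, frac_ge)
  }
  c_dvh <- structure(
    list(organ = organ, dose_gy = as.double(dose_gy),
         frac_ge = as.double(frac_ge), dose_kind = dose_kind),
    class = "cumulative_dvh")
  validate_cumulative_dvh(c_dvh)
}

#' @rdname cumulative_dvh
#' @param c_dvh A `cumulative_dvh` object to validate.
#' @export
validate_cumulative_dvh <- function(c_dvh) {
  with(c_dvh, {
    if (any(!is.finite(dose_gy)) || any(!is.finite(frac_ge)))
      stopf("cumulative DVH (%s): non-finite values", organ)
    if (is.unsorted(dose_gy, strictly = TRUE))
      stopf("cumulative DVH (%s): doses must be strictly increasing", organ)
    bad <- which(diff(frac_ge) > .VOL_TOL)
    if (length(bad))
      stopf("cumulative DVH (%s): fractions must be non-increasing (point %d)",
            organ, bad[1] + 1L)
    if (abs(dose_gy[1]) > 1e-12 || abs(frac_ge[1] - 1) > .VOL_TOL)
      stopf("cumulative DVH (%s): first point must be (0, 1)", organ)
    if (frac_ge[length(frac_ge)] < -.VOL_TOL)
      stopf("cumulative DVH (%s): fractions must be >= 0", organ)
  })
  c_dvh
}

#' Bin midpoint doses of a differential DVH
#'
#' The dose assigned to each subvolume by the response models.
#' @param d A `differential_dvh`.
#' @return Numeric vector of midpoints in Gy.
#' @export
bin_midpoints <- function(d) (d$lo + d$hi) / 2

#' @export
print.differential_dvh <- function(x, ...) {
  cat(sprintf("<differential_dvh> organ=%s  bins=%d  dose=[%.3g, %.3g] Gy  mean=%.3g Gy  (%s)\n",
              x$organ, length(x$lo), min(x$lo), max(x$hi), mean_dose(x), x$dose_kind))
  invisible(x)
}

#' @export
print.cumulative_dvh <- function(x, ...) {
  cat(sprintf("<cumulative_dvh> organ=%s  points=%d  dose=[%.3g, %.3g] Gy  (%s)\n",
              x$organ, length(x$dose_gy), min(x$dose_gy), max(x$dose_gy), x$dose_kind))
  invisible(x)
}
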