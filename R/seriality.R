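#' Subvolume dose-response of the relative seriality model
#'
#' Poisson-statistics sigmoid for the complication probability of a tissue
#' subvolume uniformly irradiated to dose `D`:
#' \deqn{P(D) = 2^{-\exp\left(e\,\gamma\,(1 - D/D_{50})\right)}}
#' with `e` Euler's number. `P(D50) = 0.5` exactly and `gamma` is the maximum
#' normalized slope of the curve.
#'
#' @param dose Dose(s) in Gy, `>= 0`; vectorized.
#' @param p A [seriality_params()] object.
#' @return Probability in `[0, 1]`, strictly increasing in dose.
#' @examples
#' subvolume_response(70.3, cardiac_seriality_params())  # 0.5
#' @export
subvolume_response <- function(dose, p) {
  stopifnot(inherits(p, "seriality_params"))
  if (any(!is.finite(dose)) || any(dose < 0)) stopf("dose must be finite and >= 0")
  2^(-exp(exp(1) * p$gamma * (1 - dose / p$d50)))
}

#' Organ complication probability from a differential DVH
#'
#' The relative seriality model combines subvolume responses over the whole
#' organ. With subvolume probabilities `P(D_i)`, fractional volumes
#' `dv_i` and relative seriality `s`:
#' \deqn{P = \left[1 - \prod_{i=1}^{M} \left(1 - P(D_i)^s\right)^{dv_i}\right]^{1/s}}
#' For a uniform dose the formula reduces to [subvolume_response()] for any
#' `s`. Bin doses are the bin midpoints. The product is evaluated in log
#' space as `exp(sum dv_i * log(1 - P_i^s))` with `expm1`/`log1p` guards so
#' subvolume probabilities near 0 or 1 lose no precision.
#'
#' @param d A `differential_dvh` (conventionally the whole heart).
#' @param p A [seriality_params()] object.
#' @return Complication probability in `[0, 1]`. Reported as "excess risk"
#'   directly: the model's baseline risk is zero.
#' @examples
#' d <- differential_dvh(70.25, 70.35, 1, organ = "heart")
#' ntcp(d, cardiac_seriality_params())  # 0.5
#' @export
ntcp <- function(d, p) {
  validate_differential_dvh(d)
  seriality_combine(bin_midpoints(d), d$frac_volume, p)
}

#' Brute-force voxelwise evaluation of the relative seriality model
#'
#' Evaluates the organ response directly on a list of voxel doses with equal
#' voxel volumes (`dv_i = 1/N`), without any binning. Intended as an
#' independent cross-check for [ntcp()] on binned DVHs.
#'
#' @param doses Non-empty vector of voxel doses in Gy.
#' @param p A [seriality_params()] object.
#' @return Complication probability in `[0, 1]`.
#' @export
ntcp_voxelwise <- function(doses, p) {
  if (length(doses) == 0L) stopf("doses must be non-empty")
  seriality_combine(doses, rep(1 / length(doses), length(doses)), p)
}

# log(1 - e^x) for x <= 0 without cancellation at either end: the usual
# log1mexp branch at x = -log 2.
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# Core of the organ-level formula shared by ntcp() and ntcp_voxelwise().
seriality_combine <- function(doses, dv, p) {
  P <- subvolume_response(doses, p)
  s <- p$s
  # log(1 - P^s) via log1mexp(s log P); P > 0 always holds for finite dose,
  # and P^s -> 1 maps to -Inf (organ response 1).
  ssum <- sum(dv * log1mexp(s * log(P)))
  if (!is.finite(ssum)) return(1)
  # organ response = (1 - e^ssum)^(1/s), again through log1mexp
  out <- exp(log1mexp(ssum) / s)
  min(max(out, 0), 1)
}
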