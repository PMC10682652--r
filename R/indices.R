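#' Valvuloarterial impedance (Zva)
#'
#' Global left-ventricular afterload estimate combining the valvular and
#' arterial components: `(SBP + mean aortic gradient) / SVi`.
#'
#' @param sbp Systolic blood pressure, mmHg.
#' @param mean_gradient Mean transvalvular aortic gradient, mmHg.
#' @param svi Stroke volume index, ml/m^2 (must be positive).
#' @return Zva in mmHg.m^2/ml.
#' @examples
#' zva(130, 49, 43)
#' @export
zva <- function(sbp, mean_gradient, svi) {
  if (any(svi <= 0, na.rm = TRUE)) stop_vp("SVi must be positive")
  (sbp + mean_gradient) / svi
}

#' Total arterial distensibility surrogate (SVi/PP)
#'
#' @param svi Stroke volume index, ml/m^2.
#' @param pp Pulse pressure, mmHg (must be positive).
#' @return SVi/PP in ml/mmHg (per m^2).
#' @export
arterial_distensibility <- function(svi, pp) {
  if (any(pp <= 0, na.rm = TRUE)) stop_vp("pulse pressure must be positive")
  svi / pp
}

#' Proportional pre/post variation
#'
#' `(post - pre)/pre`, the relative change of a parameter from baseline to
#' after the intervention; undefined for a zero baseline.
#'
#' @param pre,post Baseline and follow-up values (vectorized).
#' @return Dimensionless proportional change.
#' @examples
#' proportional_variation(48, 10.6)   # mean-gradient drop after TAVI
#' @export
proportional_variation <- function(pre, post) {
  if (any(pre == 0, na.rm = TRUE)) stop_vp("proportional variation undefined for a zero baseline")
  (post - pre) / pre
}
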