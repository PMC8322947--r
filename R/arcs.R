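#' Mechanoneural (controller) arc parameters
#'
#' The mechanoneural (MN) arc maps arterial pressure sensed at the
#' baroreceptors to sympathetic outflow, read out as plasma norepinephrine
#' (PNE). Near the operating point the arc is a straight line on the
#' PNE--AP plane with slope \eqn{-1/G_{MN}} against the PNE axis, i.e.
#' \deqn{PNE = \max(floor,\; G_{MN} (AP_{MN,0} - AP)).}
#' Above the pressure set point \eqn{AP_{MN,0}} the sympathetic limb is
#' silent and PNE rests at `pne_floor`.
#'
#' @param g_mn MN-arc gain, pg·ml^-1·mmHg^-1; must be >= 0. Stored positive;
#'   the line's slope on the PNE-vs-AP plane is `-g_mn`.
#' @param ap_mn0 AP-axis intercept of the arc, mmHg. Approximates the
#'   set-point pressure of the reflex.
#' @param pne_floor Minimal PNE when the reflex is silent, pg·ml^-1
#'   (default 0). A nonzero value models a non-neural residual.
#' @return An object of class `mn_arc`.
#' @seealso [nm_arc()], [mn_arc_response()], [solve_operating_point()]
#' @examples
#' mn <- mn_arc(g_mn = 8.92, ap_mn0 = 103)
#' mn_arc_response(92.3, mn)
#' @export
mn_arc <- function(g_mn, ap_mn0, pne_floor = 0) {
  stopifnot_scalar_finite(g_mn, "g_mn")
  stopifnot_scalar_finite(ap_mn0, "ap_mn0")
  stopifnot_scalar_finite(pne_floor, "pne_floor")
  if (g_mn < 0) abort_baroloop("`g_mn` must be >= 0", "invalid_argument")
  if (pne_floor < 0) abort_baroloop("`pne_floor` must be >= 0", "invalid_argument")
  structure(
    list(g_mn = g_mn, ap_mn0 = ap_mn0, pne_floor = pne_floor),
    class = "mn_arc"
  )
}

#' Neuromechanical (plant) arc parameters
#'
#' The neuromechanical (NM) arc maps sympathetic outflow (PNE) to the
#' arterial pressure the cardiovascular system generates, at a given tilt
#' angle \eqn{\varphi}:
#' \deqn{AP = G_{NM}(\varphi)\, PNE + AP_{NM,0}(\varphi).}
#' Head-up tilt lowers both the gain and the intercept, so a separate
#' `nm_arc` describes the plant at each angle.
#'
#' @param g_nm NM-arc gain, mmHg·ml·pg^-1; must be >= 0.
#' @param ap_nm0 Pressure generated at null PNE, mmHg.
#' @param angle_deg Optional annotation: the tilt angle this
#'   parameterization belongs to, degrees (head-down negative).
#' @return An object of class `nm_arc`.
#' @seealso [mn_arc()], [nm_arc_response()], [nm_params_at_angle()]
#' @examples
#' nm <- nm_arc(g_nm = 0.61, ap_nm0 = 34.1, angle_deg = 0)
#' nm_arc_response(95.4, nm)
#' @export
nm_arc <- function(g_nm, ap_nm0, angle_deg = NA_real_) {
  stopifnot_scalar_finite(g_nm, "g_nm")
  stopifnot_scalar_finite(ap_nm0, "ap_nm0")
  if (g_nm < 0) abort_baroloop("`g_nm` must be >= 0", "invalid_argument")
  new_nm_arc(g_nm, ap_nm0, angle_deg)
}

# Internal constructor that skips the sign check: estimation may produce a
# negative fitted gain, which is reported with a quality flag, not rejected.
new_nm_arc <- function(g_nm, ap_nm0, angle_deg = NA_real_, flags = character()) {
  structure(
    list(g_nm = g_nm, ap_nm0 = ap_nm0, angle_deg = as.numeric(angle_deg),
         flags = flags),
    class = "nm_arc"
  )
}

#' @export
print.mn_arc <- function(x, ...) {
  cat(sprintf(
    "MN arc: PNE = max(%g, %g * (%g - AP))  [gain pg/ml/mmHg, set point mmHg]\n",
    x$pne_floor, x$g_mn, x$ap_mn0
  ))
  invisible(x)
}

#' @export
print.nm_arc <- function(x, ...) {
  ang <- if (is.na(x$angle_deg)) "" else sprintf(" at %g deg", x$angle_deg)
  cat(sprintf("NM arc%s: AP = %g * PNE + %g  [gain mmHg*ml/pg, offset mmHg]\n",
              ang, x$g_nm, x$ap_nm0))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Sympathetic response of the mechanoneural arc
#'
#' Evaluates PNE commanded by the MN arc at one or more arterial
#' pressures: the rectified line
#' `max(pne_floor, g_mn * (ap_mn0 - ap))`, continuous and non-increasing
#' in `ap`. Above the set point the response clamps at the floor.
#'
#' @param ap Arterial pressure, mmHg (vectorized; must be finite).
#' @param mn An [mn_arc()] object.
#' @return PNE, pg·ml^-1, same length as `ap`.
#' @export
mn_arc_response <- function(ap, mn) {
  if (!inherits(mn, "mn_arc")) abort_baroloop("`mn` must be an mn_arc", "invalid_argument")
  if (!is.numeric(ap) || length(ap) == 0L || any(!is.finite(ap))) {
    abort_baroloop("`ap` must be finite numeric", "invalid_argument")
  }
  pmax(mn$pne_floor, mn$g_mn * (mn$ap_mn0 - ap))
}

#' Pressure response of the neuromechanical arc
#'
#' Evaluates arterial pressure generated by the cardiovascular system at
#' one or more PNE levels: `g_nm * pne + ap_nm0`, non-decreasing in `pne`.
#'
#' @param pne Plasma norepinephrine, pg·ml^-1 (vectorized; must be >= 0).
#' @param nm An [nm_arc()] object.
#' @return Arterial pressure, mmHg, same length as `pne`.
#' @export
nm_arc_response <- function(pne, nm) {
  if (!inherits(nm, "nm_arc")) abort_baroloop("`nm` must be an nm_arc", "invalid_argument")
  if (!is.numeric(pne) || length(pne) == 0L || any(!is.finite(pne)) || any(pne < 0)) {
    abort_baroloop("`pne` must be finite numeric >= 0", "invalid_argument")
  }
  nm$g_nm * pne + nm$ap_nm0
}

#' Open-loop gain of the baroreflex
#'
#' The open-loop gain is the product of the two arc gains,
#' \eqn{G_L = G_{MN} \cdot G_{NM}}. It is the homeostatic index of the
#' reflex: a pressure disturbance is attenuated to \eqn{1/(1+G_L)} by the
#' closed loop.
#'
#' @param mn An [mn_arc()] object.
#' @param nm An [nm_arc()] object.
#' @return Dimensionless gain, >= 0.
#' @seealso [attenuation_factor()], [gain_from_attenuation()]
#' @export
open_loop_gain <- function(mn, nm) {
  if (!inherits(mn, "mn_arc") || !inherits(nm, "nm_arc")) {
    abort_baroloop("`mn`/`nm` must be mn_arc / nm_arc objects", "invalid_argument")
  }
  mn$g_mn * nm$g_nm
}

#' Disturbance attenuation of a closed feedback loop
#'
#' A loop with open-loop gain `g_l` attenuates an external pressure
#' disturbance to the fraction `1 / (1 + g_l)` of its open-loop effect.
#'
#' @param g_l Open-loop gain, dimensionless, >= 0 (vectorized).
#' @return Attenuation fraction in (0, 1].
#' @export
attenuation_factor <- function(g_l) {
  if (!is.numeric(g_l) || length(g_l) == 0L || any(!is.finite(g_l)) || any(g_l < 0)) {
    abort_baroloop("`g_l` must be finite numeric >= 0", "invalid_argument")
  }
  1 / (1 + g_l)
}

#' Loop gain implied by an observed attenuation ratio
#'
#' Inverts [attenuation_factor()]: `g_l = 1/ratio - 1`. Used to recover
#' the open-loop gain from the ratio of closed-loop to open-loop pressure
#' responses to the same disturbance.
#'
#' @param ratio Attenuation ratio in (0, 1] (vectorized).
#' @return Implied open-loop gain, >= 0.
#' @export
gain_from_attenuation <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) == 0L || any(!is.finite(ratio)) ||
      any(ratio <= 0) || any(ratio > 1)) {
    abort_baroloop("`ratio` must be in (0, 1]", "invalid_argument")
  }
  1 / ratio - 1
}
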