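#' Closed-loop operating point of the baroreflex
#'
#' Under closed-loop conditions the system settles where the two arc
#' curves intersect on the PNE--AP plane. For linear arcs the
#' unconstrained intersection is
#' \deqn{AP^* = \frac{G_L\,AP_{MN,0} + AP_{NM,0}}{1 + G_L}, \qquad
#'       PNE^* = G_{MN}(AP_{MN,0} - AP^*),}
#' with \eqn{G_L = G_{MN} G_{NM}}. When that intersection would command
#' PNE below the sympathetic floor (e.g. the plant-generated pressure
#' already exceeds the set point), the loop cannot command negative
#' norepinephrine: the operating point is placed on the NM line at the
#' floor and flagged as a boundary solution.
#'
#' @param mn An [mn_arc()] object.
#' @param nm An [nm_arc()] object.
#' @return An `operating_point`: list with `ap` (mmHg), `pne` (pg·ml^-1)
#'   and `boundary` (TRUE when the solution sits at the PNE floor).
#' @examples
#' mn <- mn_arc(8.92, 103)
#' solve_operating_point(mn, nm_arc(0.61, 34.1))
#' @export
solve_operating_point <- function(mn, nm) {
  if (!inherits(mn, "mn_arc") || !inherits(nm, "nm_arc")) {
    abort_baroloop("`mn`/`nm` must be mn_arc / nm_arc objects", "invalid_argument")
  }
  g_l <- mn$g_mn * nm$g_nm
  if (!is.finite(g_l)) abort_baroloop("loop gain must be finite", "invalid_argument")
  if (mn$g_mn == 0 && nm$g_nm == 0) {
    # degenerate open loop in both arcs: plant output at the floor
    return(new_operating_point(nm_arc_response(mn$pne_floor, nm),
                               mn$pne_floor, boundary = TRUE))
  }
  ap_star <- (g_l * mn$ap_mn0 + nm$ap_nm0) / (1 + g_l)
  pne_star <- mn$g_mn * (mn$ap_mn0 - ap_star)
  if (pne_star < mn$pne_floor) {
    return(new_operating_point(nm_arc_response(mn$pne_floor, nm),
                               mn$pne_floor, boundary = TRUE))
  }
  new_operating_point(ap_star, pne_star, boundary = FALSE)
}

new_operating_point <- function(ap, pne, boundary) {
  structure(list(ap = ap, pne = pne, boundary = boundary),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point: AP = %.4f mmHg, PNE = %.4f pg/ml%s\n",
              x$ap, x$pne, if (x$boundary) "  (boundary: PNE at floor)" else ""))
  invisible(x)
}

#' Numeric operating-point solver for monotone arc curves
#'
#' Bracketing (bisection) solver for the closed-loop fixed point of
#' arbitrary monotone arcs, e.g. the sigmoidal characteristics seen when
#' a wide pressure range is explored. It finds the root of the residual
#' `r(ap) = nm_curve(mn_curve(ap)) - ap` over `ap_bracket`. For linear
#' arcs it agrees with the closed form of [solve_operating_point()] and
#' serves as its independent cross-check.
#'
#' Monotonicity of the supplied curves (non-increasing `mn_curve`,
#' non-decreasing `nm_curve`) is the caller's responsibility; it is what
#' guarantees a unique fixed point within the bracket.
#'
#' @param mn_curve Function AP (mmHg) -> PNE (pg·ml^-1), non-increasing.
#' @param nm_curve Function PNE (pg·ml^-1) -> AP (mmHg), non-decreasing.
#' @param ap_bracket Length-2 interval, mmHg, over which the residual
#'   changes sign.
#' @param tol Residual tolerance, mmHg (default 1e-9).
#' @return An `operating_point` (boundary is FALSE: the numeric solver
#'   reports the fixed point and does not classify floor solutions).
#' @examples
#' mn_curve <- function(ap) 300 / (1 + exp(0.1 * (ap - 90)))
#' nm <- nm_arc(0.36, 33.4)
#' solve_operating_point_numeric(mn_curve, function(p) nm_arc_response(p, nm),
#'                               c(0, 200))
#' @export
solve_operating_point_numeric <- function(mn_curve, nm_curve,
                                          ap_bracket = c(0, 300),
                                          tol = 1e-9) {
  if (!is.function(mn_curve) || !is.function(nm_curve)) {
    abort_baroloop("`mn_curve` and `nm_curve` must be functions", "invalid_argument")
  }
  if (!is.numeric(ap_bracket) || length(ap_bracket) != 2L ||
      any(!is.finite(ap_bracket)) || diff(ap_bracket) <= 0) {
    abort_baroloop("`ap_bracket` must be an increasing finite interval", "invalid_argument")
  }
  stopifnot_scalar_finite(tol, "tol")
  resid <- function(ap) nm_curve(mn_curve(ap)) - ap
  lo <- ap_bracket[1]; hi <- ap_bracket[2]
  r_lo <- resid(lo); r_hi <- resid(hi)
  if (!is.finite(r_lo) || !is.finite(r_hi)) {
    abort_baroloop("residual is not finite at the bracket ends", "invalid_argument")
  }
  if (r_lo == 0) hi <- lo
  if (r_hi == 0) lo <- hi
  if (lo < hi && sign(r_lo) == sign(r_hi)) {
    abort_baroloop("residual does not change sign over `ap_bracket`", "no_root")
  }
  mid <- (lo + hi) / 2
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    r_mid <- resid(mid)
    if (abs(r_mid) <= tol || (hi - lo) / 2 < .Machine$double.eps * max(1, abs(mid))) break
    if (sign(r_mid) == sign(r_lo)) {
      lo <- mid; r_lo <- r_mid
    } else {
      hi <- mid
    }
  }
  if (abs(resid(mid)) > tol) {
    abort_baroloop("bisection failed to reach the requested tolerance", "no_root")
  }
  new_operating_point(ap = mid, pne = mn_curve(mid), boundary = FALSE)
}
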