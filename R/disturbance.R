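#' Decompose the pressure response to a tilt disturbance
#'
#' Head-up tilt acts on the plant: it moves the NM arc from `nm_pre` to
#' `nm_post` while the MN arc stays put. The closed-loop response is the
#' walk of the operating point along the MN line; the open-loop
#' (reflex-disabled) response is the vertical fall of pressure when PNE
#' is frozen at its pre-disturbance value. The ratio of the two is the
#' attenuation achieved by the feedback loop, from which an implied loop
#' gain `1/ratio - 1` follows.
#'
#' Because tilt lowers the NM gain as well as the intercept, the implied
#' gain from this construction is generally smaller than the supine
#' open-loop gain; see [parallel_shift_counterfactual()] for the
#' pure-shift comparison in which the two coincide exactly.
#'
#' @param mn An [mn_arc()] object (shared by both states).
#' @param nm_pre,nm_post [nm_arc()] objects before / after the disturbance.
#' @return A `disturbance_report`: list with `ap_before`, `ap_after`,
#'   `pne_before` (mmHg, pg·ml^-1), `closed_loop_delta_ap`,
#'   `open_loop_delta_ap` (mmHg), `attenuation_ratio` and `implied_gl`
#'   (dimensionless).
#' @examples
#' mn <- mn_arc(8.92, 103)
#' tilt_disturbance_report(mn, nm_arc(0.61, 34.1, 0), nm_arc(0.36, 33.4, 15))
#' @export
tilt_disturbance_report <- function(mn, nm_pre, nm_post) {
  if (!inherits(mn, "mn_arc") || !inherits(nm_pre, "nm_arc") ||
      !inherits(nm_post, "nm_arc")) {
    abort_baroloop("arguments must be mn_arc / nm_arc objects", "invalid_argument")
  }
  before <- solve_operating_point(mn, nm_pre)
  after <- solve_operating_point(mn, nm_post)
  open_loop_ap <- nm_arc_response(before$pne, nm_post)
  closed_delta <- before$ap - after$ap
  open_delta <- before$ap - open_loop_ap
  # below the solver residual tolerance there is no disturbance to speak of
  if (abs(open_delta) <= 1e-9) {
    abort_baroloop(
      "open-loop AP change is zero (identical NM arcs?): attenuation undefined",
      "undefined_ratio"
    )
  }
  ratio <- closed_delta / open_delta
  structure(
    list(
      ap_before = before$ap,
      ap_after = after$ap,
      pne_before = before$pne,
      closed_loop_delta_ap = closed_delta,
      open_loop_delta_ap = open_delta,
      attenuation_ratio = ratio,
      implied_gl = gain_from_attenuation(ratio)
    ),
    class = "disturbance_report"
  )
}

#' @export
print.disturbance_report <- function(x, ...) {
  cat("Tilt disturbance decomposition\n")
  cat(sprintf("  operating point before: AP %.2f mmHg, PNE %.2f pg/ml\n",
              x$ap_before, x$pne_before))
  cat(sprintf("  operating point after:  AP %.2f mmHg\n", x$ap_after))
  cat(sprintf("  closed-loop AP fall: %.2f mmHg\n", x$closed_loop_delta_ap))
  cat(sprintf("  open-loop AP fall:   %.2f mmHg\n", x$open_loop_delta_ap))
  cat(sprintf("  attenuation ratio:   %.4f  (implied loop gain %.4f)\n",
              x$attenuation_ratio, x$implied_gl))
  invisible(x)
}

#' Parallel-shift counterfactual for a tilt disturbance
#'
#' Asks what the closed-loop response would have been had tilt only
#' shifted the NM arc downward without flattening it: the counterfactual
#' post-tilt NM line keeps the pre-tilt slope and passes through the
#' open-loop point (pre-tilt PNE, post-tilt NM pressure at that PNE).
#' For such a pure parallel shift the attenuation ratio is exactly
#' \eqn{1/(1+G_L)}, so the implied loop gain recovered from the report
#' equals the pre-tilt open-loop gain identically.
#'
#' @inheritParams tilt_disturbance_report
#' @return A `disturbance_report` computed against the counterfactual
#'   NM line (see [tilt_disturbance_report()]).
#' @export
parallel_shift_counterfactual <- function(mn, nm_pre, nm_post) {
  if (!inherits(mn, "mn_arc") || !inherits(nm_pre, "nm_arc") ||
      !inherits(nm_post, "nm_arc")) {
    abort_baroloop("arguments must be mn_arc / nm_arc objects", "invalid_argument")
  }
  before <- solve_operating_point(mn, nm_pre)
  ap_open <- nm_arc_response(before$pne, nm_post)
  if (abs(before$ap - ap_open) <= 1e-9) {
    abort_baroloop(
      "open-loop AP change is zero (identical NM arcs?): attenuation undefined",
      "undefined_ratio"
    )
  }
  nm_cf <- new_nm_arc(
    g_nm = nm_pre$g_nm,
    ap_nm0 = ap_open - nm_pre$g_nm * before$pne,
    angle_deg = nm_post$angle_deg
  )
  tilt_disturbance_report(mn, nm_pre, nm_cf)
}
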