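#' Equilibrium-diagram report for a pair of tilt angles
#'
#' Bundles everything the equilibrium diagram says about a postural
#' disturbance: both operating points, the open-loop gains at each
#' angle, the closed-loop/open-loop decomposition of the AP fall with
#' its attenuation ratio and implied loop gain, and the parallel-shift
#' counterfactual in which tilt would only shift (not flatten) the NM
#' arc.
#'
#' @param mn An [mn_arc()] object.
#' @param nm_pre,nm_post [nm_arc()] objects at the pre- and post-tilt
#'   angles.
#' @return An `equilibrium_report`: list with `mn`, `nm_pre`, `nm_post`,
#'   `op_pre`, `op_post` (operating points), `g_l_pre`, `g_l_post`,
#'   `attenuation_pre` (= 1/(1+g_l_pre)), `disturbance`
#'   ([tilt_disturbance_report()]) and `counterfactual`
#'   ([parallel_shift_counterfactual()]).
#' @export
equilibrium_report <- function(mn, nm_pre, nm_post) {
  dist <- tilt_disturbance_report(mn, nm_pre, nm_post)
  cf <- parallel_shift_counterfactual(mn, nm_pre, nm_post)
  g_l_pre <- open_loop_gain(mn, nm_pre)
  structure(
    list(
      mn = mn, nm_pre = nm_pre, nm_post = nm_post,
      op_pre = solve_operating_point(mn, nm_pre),
      op_post = solve_operating_point(mn, nm_post),
      g_l_pre = g_l_pre,
      g_l_post = open_loop_gain(mn, nm_post),
      attenuation_pre = attenuation_factor(g_l_pre),
      disturbance = dist,
      counterfactual = cf
    ),
    class = "equilibrium_report"
  )
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibrium-diagram report\n")
  cat(sprintf("  open-loop gain: pre %.4f, post %.4f\n", x$g_l_pre, x$g_l_post))
  print(x$disturbance)
  cat("Parallel-shift counterfactual\n")
  cat(sprintf("  closed-loop AP fall: %.2f mmHg (implied loop gain %.4f)\n",
              x$counterfactual$closed_loop_delta_ap, x$counterfactual$implied_gl))
  invisible(x)
}

#' Plot the equilibrium diagram for a tilt disturbance
#'
#' Draws the PNE--AP plane with the MN line and the pre- and post-tilt
#' NM lines, and marks Point 1 (pre-tilt operating point), Point 2
#' (post-tilt operating point) and Point 3 (the open-loop point reached
#' when PNE is frozen at its pre-tilt value).
#'
#' @inheritParams equilibrium_report
#' @param pne_range PNE range of the abscissa, pg·ml^-1.
#' @return A ggplot object.
#' @export
plot_equilibrium_diagram <- function(mn, nm_pre, nm_post,
                                     pne_range = c(0, 300)) {
  op1 <- solve_operating_point(mn, nm_pre)
  op2 <- solve_operating_point(mn, nm_post)
  p3 <- c(pne = op1$pne, ap = nm_arc_response(op1$pne, nm_post))
  pne <- seq(pne_range[1], pne_range[2], length.out = 50)
  lines <- rbind(
    data.frame(pne = pne, ap = mn$ap_mn0 - pne / mn$g_mn, curve = "MN arc"),
    data.frame(pne = pne, ap = nm_arc_response(pne, nm_pre), curve = "NM arc (pre)"),
    data.frame(pne = pne, ap = nm_arc_response(pne, nm_post), curve = "NM arc (post)")
  )
  pts <- data.frame(
    pne = c(op1$pne, op2$pne, p3[["pne"]]),
    ap = c(op1$ap, op2$ap, p3[["ap"]]),
    label = c("1", "2", "3")
  )
  ggplot2::ggplot(lines, ggplot2::aes(x = pne, y = ap)) +
    ggplot2::geom_line(ggplot2::aes(linetype = curve)) +
    ggplot2::geom_point(data = pts, size = 2) +
    ggplot2::geom_text(data = pts, ggplot2::aes(label = label),
                       nudge_x = diff(pne_range) * 0.03, nudge_y = 2) +
    ggplot2::labs(x = "Plasma norepinephrine (pg/ml)",
                  y = "Arterial pressure (mmHg)",
                  linetype = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, max(lines$ap))) +
    ggplot2::theme_classic()
}

# JSON-friendly view of an equilibrium report (stored at full precision;
# rounding happens only at presentation).
report_to_list <- function(report, provenance = list()) {
  unarc <- function(a) list(g_nm = a$g_nm, ap_nm0 = a$ap_nm0,
                            angle_deg = a$angle_deg)
  undist <- function(d) d[c("ap_before", "ap_after", "pne_before",
                            "closed_loop_delta_ap", "open_loop_delta_ap",
                            "attenuation_ratio", "implied_gl")]
  list(
    provenance = provenance,
    mn = list(g_mn = report$mn$g_mn, ap_mn0 = report$mn$ap_mn0,
              pne_floor = report$mn$pne_floor),
    nm_pre = unarc(report$nm_pre),
    nm_post = unarc(report$nm_post),
    operating_points = list(
      pre = report$op_pre[c("ap", "pne", "boundary")],
      post = report$op_post[c("ap", "pne", "boundary")]
    ),
    open_loop_gain = list(pre = report$g_l_pre, post = report$g_l_post,
                          attenuation_pre = report$attenuation_pre),
    disturbance = undist(report$disturbance),
    counterfactual = undist(report$counterfactual)
  )
}
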