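#' Least-squares fit of the mechanoneural arc
#'
#' Fits the MN line to per-subject (AP, PNE) points measured across tilt
#' angles under closed-loop baseline conditions. Ordinary least squares
#' of PNE on AP gives the line `pne = m * ap + b`; the gain is the slope
#' against the AP axis, `g_mn = -m`, and the set-point estimate is the
#' AP-axis intercept `ap_mn0 = -b/m` (where PNE reaches zero).
#'
#' @param ap Arterial pressures, mmHg (>= 3 values, not all equal).
#' @param pne Plasma norepinephrine, pg·ml^-1, same length as `ap`.
#' @return An `mn_arc_fit`: list with `params` ([mn_arc()]), `r`
#'   (Pearson correlation of the points) and `n_points`.
#' @examples
#' fit_mn_arc(ap = c(91, 87, 79, 59), pne = c(83, 92, 129, 278))
#' @export
fit_mn_arc <- function(ap, pne) {
  if (!is.numeric(ap) || !is.numeric(pne) || length(ap) != length(pne)) {
    abort_baroloop("`ap` and `pne` must be numeric vectors of equal length",
                   "invalid_argument")
  }
  if (length(ap) < 3L) {
    abort_baroloop("MN-arc fit needs at least 3 points", "insufficient_data")
  }
  if (any(!is.finite(ap)) || any(!is.finite(pne))) {
    abort_baroloop("non-finite values in MN-arc points", "invalid_argument")
  }
  if (stats::var(ap) == 0) {
    abort_baroloop("all AP values are equal: MN-arc slope is unidentifiable",
                   "degenerate_design")
  }
  fit <- stats::lm(pne ~ ap)
  m <- unname(stats::coef(fit)[["ap"]])
  b <- unname(stats::coef(fit)[["(Intercept)"]])
  if (m >= 0) {
    abort_baroloop(
      sprintf("fitted MN slope is %.4g >= 0: no reflex response in these points", m),
      "no_reflex_response"
    )
  }
  r <- if (stats::var(pne) == 0) 0 else stats::cor(ap, pne)
  structure(
    list(params = mn_arc(g_mn = -m, ap_mn0 = -b / m), r = r,
         n_points = length(ap)),
    class = "mn_arc_fit"
  )
}

#' @export
print.mn_arc_fit <- function(x, ...) {
  cat(sprintf("MN-arc fit (%d points, r = %.3f)\n", x$n_points, x$r))
  print(x$params)
  invisible(x)
}

#' Two-point fit of the neuromechanical arc
#'
#' The NM line at one tilt angle is identified from two measured points
#' on the PNE--AP plane: the closed-loop baseline operating point and
#' the point observed after ganglionic blockade opens the loop. The gain
#' is the slope against the PNE axis and the intercept is the pressure
#' at null PNE; the line passes through both points exactly.
#'
#' A negative fitted slope is physiologically anomalous; it is returned
#' with a `"negative_gain"` flag on the `nm_arc` rather than rejected,
#' so downstream summaries can report or exclude it explicitly.
#'
#' @param baseline Named numeric vector `c(pne = , ap = )` for the
#'   baseline (closed-loop) point.
#' @param blockade Named numeric vector `c(pne = , ap = )` for the
#'   ganglionic-blockade point.
#' @param angle_deg Optional tilt-angle annotation, degrees.
#' @return An [nm_arc()] object (possibly carrying flags).
#' @examples
#' fit_nm_arc(baseline = c(pne = 92, ap = 87), blockade = c(pne = 47, ap = 61))
#' @export
fit_nm_arc <- function(baseline, blockade, angle_deg = NA_real_) {
  pt <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2L || is.null(names(x)) ||
        !all(c("pne", "ap") %in% names(x)) || any(!is.finite(x))) {
      abort_baroloop(
        sprintf("`%s` must be a finite named vector c(pne = , ap = )", name),
        "invalid_argument"
      )
    }
    x[c("pne", "ap")]
  }
  b1 <- pt(baseline, "baseline")
  b2 <- pt(blockade, "blockade")
  if (b1[["pne"]] == b2[["pne"]]) {
    abort_baroloop("baseline and blockade PNE are equal: NM line is vertical",
                   "degenerate_line")
  }
  g_nm <- (b1[["ap"]] - b2[["ap"]]) / (b1[["pne"]] - b2[["pne"]])
  ap_nm0 <- b2[["ap"]] - g_nm * b2[["pne"]]
  flags <- if (g_nm < 0) "negative_gain" else character()
  new_nm_arc(g_nm, ap_nm0, angle_deg, flags = flags)
}

#' Per-subject arc and loop-gain estimation
#'
#' Runs the full per-subject analysis of a tilt + ganglionic-blockade
#' record: MN-arc regression over the baseline rows at all angles,
#' two-point NM fits at 0 and 15 degrees pairing each baseline row with
#' its blockade counterpart, and open-loop gains as the exact per-subject
#' products `g_l_0 = g_mn * g_nm(0)`, `g_l_15 = g_mn * g_nm(15)`.
#'
#' @param record Data frame with columns `condition`
#'   (`"baseline"`/`"blockade"`), `angle_deg`, `ap_mmHg`, `pne_pg_ml`
#'   (and optionally `subject_id`, `hr_bpm`) for one subject. Baseline
#'   rows at >= 3 distinct angles and blockade rows at 0 and 15 degrees
#'   are required.
#' @return A `subject_estimates`: list with `subject_id`, `mn_fit`
#'   (`mn_arc_fit`), `nm_0`, `nm_15` ([nm_arc()]), `g_l_0`, `g_l_15`
#'   and `flags`.
#' @export
estimate_subject <- function(record) {
  if (!is.data.frame(record)) {
    abort_baroloop("`record` must be a data frame", "invalid_argument")
  }
  needed <- c("condition", "angle_deg", "ap_mmHg", "pne_pg_ml")
  missing_cols <- setdiff(needed, names(record))
  if (length(missing_cols)) {
    abort_baroloop(
      sprintf("record is missing column(s): %s", paste(missing_cols, collapse = ", ")),
      "schema_violation"
    )
  }
  subject_id <- if ("subject_id" %in% names(record)) {
    as.character(record$subject_id[1])
  } else {
    NA_character_
  }
  base <- record[record$condition == "baseline", , drop = FALSE]
  block <- record[record$condition == "blockade", , drop = FALSE]
  if (length(unique(base$angle_deg)) < 3L) {
    abort_baroloop(
      sprintf("subject %s: baseline rows at >= 3 distinct angles required", subject_id),
      "schema_violation"
    )
  }
  need_rows <- rbind(
    data.frame(condition = "baseline", angle_deg = c(0, 15)),
    data.frame(condition = "blockade", angle_deg = c(0, 15))
  )
  for (i in seq_len(nrow(need_rows))) {
    cond <- need_rows$condition[i]; ang <- need_rows$angle_deg[i]
    if (!any(record$condition == cond & record$angle_deg == ang)) {
      abort_baroloop(
        sprintf("subject %s: missing required row (condition = %s, angle = %g)",
                subject_id, cond, ang),
        "schema_violation"
      )
    }
  }
  row_at <- function(df, ang) {
    r <- df[df$angle_deg == ang, , drop = FALSE][1, ]
    c(pne = r$pne_pg_ml, ap = r$ap_mmHg)
  }
  mn_fit <- fit_mn_arc(ap = base$ap_mmHg, pne = base$pne_pg_ml)
  nm_0 <- fit_nm_arc(row_at(base, 0), row_at(block, 0), angle_deg = 0)
  nm_15 <- fit_nm_arc(row_at(base, 15), row_at(block, 15), angle_deg = 15)
  structure(
    list(
      subject_id = subject_id,
      mn_fit = mn_fit,
      nm_0 = nm_0,
      nm_15 = nm_15,
      g_l_0 = mn_fit$params$g_mn * nm_0$g_nm,
      g_l_15 = mn_fit$params$g_mn * nm_15$g_nm,
      flags = c(nm_0$flags, nm_15$flags)
    ),
    class = "subject_estimates"
  )
}

#' @export
print.subject_estimates <- function(x, ...) {
  cat(sprintf("Subject %s estimates:\n", x$subject_id))
  cat(sprintf("  G_MN %.4f pg/ml/mmHg, AP_MN,0 %.2f mmHg (r = %.3f)\n",
              x$mn_fit$params$g_mn, x$mn_fit$params$ap_mn0, x$mn_fit$r))
  cat(sprintf("  G_NM(0) %.4f, AP_NM,0(0) %.2f | G_NM(15) %.4f, AP_NM,0(15) %.2f\n",
              x$nm_0$g_nm, x$nm_0$ap_nm0, x$nm_15$g_nm, x$nm_15$ap_nm0))
  cat(sprintf("  open-loop gain: G_L(0) %.4f, G_L(15) %.4f\n", x$g_l_0, x$g_l_15))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate every subject in a study table
#'
#' Applies [estimate_subject()] to each subject of a study table read by
#' [read_study_table()] or produced by [simulate_study()]. Subjects whose
#' estimation fails are collected with their error messages rather than
#' dropped silently.
#'
#' @param data Study table data frame (schema of [read_study_table()]),
#'   or a `study_dataset`.
#' @return A `cohort_estimates`: list with `estimates` (list of
#'   `subject_estimates`) and `failures` (named character vector of
#'   per-subject error messages).
#' @export
estimate_cohort <- function(data) {
  if (inherits(data, "study_dataset")) data <- data$data
  if (!is.data.frame(data) || !"subject_id" %in% names(data)) {
    abort_baroloop("`data` must be a study table with a subject_id column",
                   "invalid_argument")
  }
  ids <- unique(data$subject_id)
  estimates <- list()
  failures <- character()
  for (id in ids) {
    res <- tryCatch(
      estimate_subject(data[data$subject_id == id, , drop = FALSE]),
      baroloop_error = function(e) conditionMessage(e)
    )
    if (inherits(res, "subject_estimates")) {
      estimates[[id]] <- res
    } else {
      failures[[id]] <- res
    }
  }
  structure(list(estimates = estimates, failures = failures),
            class = "cohort_estimates")
}

#' Tidy table of per-subject estimates
#'
#' @param x A `cohort_estimates` object.
#' @param ... Unused.
#' @return Data frame with one row per successfully estimated subject.
#' @export
as.data.frame.cohort_estimates <- function(x, ...) {
  rows <- lapply(x$estimates, function(e) {
    data.frame(
      subject_id = e$subject_id,
      g_mn = e$mn_fit$params$g_mn,
      ap_mn0 = e$mn_fit$params$ap_mn0,
      r = e$mn_fit$r,
      g_nm_0 = e$nm_0$g_nm,
      ap_nm0_0 = e$nm_0$ap_nm0,
      g_nm_15 = e$nm_15$g_nm,
      ap_nm0_15 = e$nm_15$ap_nm0,
      g_l_0 = e$g_l_0,
      g_l_15 = e$g_l_15,
      flags = paste(e$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), g_mn = numeric(),
                      ap_mn0 = numeric(), r = numeric(), g_nm_0 = numeric(),
                      ap_nm0_0 = numeric(), g_nm_15 = numeric(),
                      ap_nm0_15 = numeric(), g_l_0 = numeric(),
                      g_l_15 = numeric(), flags = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Group summary of per-subject estimates
#'
#' Summarizes a cohort as mean, sample standard deviation (n - 1
#' denominator) and n for every arc parameter and open-loop gain, and
#' compares paired parameters across posture with the exact Wilcoxon
#' signed-rank test ([wilcoxon_signed_rank_exact()]): supine versus
#' 15-degree NM gain, and supine versus 15-degree open-loop gain.
#'
#' The group open-loop gain is the mean of per-subject gain products,
#' not the product of group-mean gains; the two differ whenever the arc
#' gains covary across subjects, and the product of means is reported
#' alongside as a diagnostic.
#'
#' @param estimates A `cohort_estimates`, or a list of
#'   `subject_estimates`.
#' @param exclude_flagged Drop subjects carrying quality flags (e.g. a
#'   negative fitted NM gain) before summarizing. Default FALSE.
#' @return A `group_summary`: list with `stats` (data frame of
#'   parameter, mean, sd, n), `g_l_product_of_means` (diagnostic),
#'   `tests` (data frame of comparison, W, p), `n_subjects`,
#'   `sd_denominator` (`"n-1"`), and `excluded` (flagged subject ids
#'   dropped when `exclude_flagged`).
#' @export
summarize_group <- function(estimates, exclude_flagged = FALSE) {
  if (inherits(estimates, "cohort_estimates")) estimates <- estimates$estimates
  if (!is.list(estimates) ||
      !all(vapply(estimates, inherits, logical(1), "subject_estimates"))) {
    abort_baroloop("`estimates` must be a list of subject_estimates",
                   "invalid_argument")
  }
  excluded <- character()
  if (exclude_flagged) {
    flagged <- vapply(estimates, function(e) length(e$flags) > 0, logical(1))
    excluded <- vapply(estimates[flagged], `[[`, character(1), "subject_id")
    estimates <- estimates[!flagged]
  }
  if (length(estimates) < 2L) {
    abort_baroloop("group summary needs >= 2 subjects", "insufficient_data")
  }
  tab <- as.data.frame(structure(list(estimates = estimates, failures = character()),
                                 class = "cohort_estimates"))
  params <- c("g_mn", "ap_mn0", "r", "g_nm_0", "ap_nm0_0", "g_nm_15",
              "ap_nm0_15", "g_l_0", "g_l_15")
  stats_df <- data.frame(
    parameter = params,
    mean = vapply(params, function(p) mean(tab[[p]]), numeric(1)),
    sd = vapply(params, function(p) stats::sd(tab[[p]]), numeric(1)),
    n = nrow(tab),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  run_test <- function(a, b) {
    tryCatch(
      wilcoxon_signed_rank_exact(a - b),
      baroloop_undefined_test = function(e) {
        list(W = NA_real_, p_two_sided = NA_real_)
      }
    )
  }
  t_nm <- run_test(tab$g_nm_0, tab$g_nm_15)
  t_gl <- run_test(tab$g_l_0, tab$g_l_15)
  tests <- data.frame(
    comparison = c("g_nm_0 vs g_nm_15", "g_l_0 vs g_l_15"),
    W = c(t_nm$W, t_gl$W),
    p = c(t_nm$p_two_sided, t_gl$p_two_sided),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      stats = stats_df,
      g_l_product_of_means = c(
        g_l_0 = mean(tab$g_mn) * mean(tab$g_nm_0),
        g_l_15 = mean(tab$g_mn) * mean(tab$g_nm_15)
      ),
      tests = tests,
      n_subjects = nrow(tab),
      sd_denominator = "n-1",
      excluded = excluded
    ),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Group summary (%d subjects, mean +/- SD, sd denominator %s)\n",
              x$n_subjects, x$sd_denominator))
  for (i in seq_len(nrow(x$stats))) {
    cat(sprintf("  %-10s %8.4f +/- %.4f\n", x$stats$parameter[i],
                x$stats$mean[i], x$stats$sd[i]))
  }
  cat("Paired Wilcoxon signed-rank tests:\n")
  for (i in seq_len(nrow(x$tests))) {
    cat(sprintf("  %-20s W = %g, p = %g\n", x$tests$comparison[i],
                x$tests$W[i], x$tests$p[i]))
  }
  if (length(x$excluded)) {
    cat("  excluded (flagged):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
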