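#' True generative parameters for one simulated subject
#'
#' Bundles the quantities that fully determine a subject's static
#' baroreflex behaviour in the simulator: the MN arc, the NM anchors at
#' 0 and 15 degrees from which other angles are interpolated, and the
#' non-neural PNE residual seen after ganglionic blockade.
#'
#' Defaults are representative group-mean values for healthy young
#' adults under vagal blockade: MN gain 8.92 pg·ml^-1·mmHg^-1 with set
#' point 103 mmHg; supine NM gain 0.61 mmHg·ml·pg^-1 with 34.1 mmHg
#' offset; 15-degree NM gain 0.36 with 33.4 mmHg offset; residual PNE
#' 45 pg·ml^-1.
#'
#' @param g_mn,ap_mn0,pne_floor MN-arc parameters, see [mn_arc()].
#' @param g_nm_0,ap_nm0_0 NM anchor at 0 degrees, see [nm_arc()].
#' @param g_nm_15,ap_nm0_15 NM anchor at 15 degrees.
#' @param pne_residual Post-blockade non-neural PNE, pg·ml^-1, >= 0.
#' @return A `subject_truth` object.
#' @export
subject_truth <- function(g_mn = 8.92, ap_mn0 = 103.0, pne_floor = 0,
                          g_nm_0 = 0.61, ap_nm0_0 = 34.1,
                          g_nm_15 = 0.36, ap_nm0_15 = 33.4,
                          pne_residual = 45) {
  mn <- mn_arc(g_mn, ap_mn0, pne_floor)
  stopifnot_scalar_finite(pne_residual, "pne_residual")
  if (pne_residual < 0) {
    abort_baroloop("`pne_residual` must be >= 0", "invalid_argument")
  }
  for (nm in list(c(g_nm_0, ap_nm0_0), c(g_nm_15, ap_nm0_15))) {
    if (nm[1] <= 0) abort_baroloop("NM gains must be > 0", "invalid_argument")
  }
  structure(
    list(mn = mn, g_nm_0 = g_nm_0, ap_nm0_0 = ap_nm0_0,
         g_nm_15 = g_nm_15, ap_nm0_15 = ap_nm0_15,
         pne_residual = pne_residual),
    class = "subject_truth"
  )
}

#' Configuration of a synthetic tilt-study cohort
#'
#' Describes the population and protocol the generator emulates: a
#' cohort of subjects whose true parameters are drawn from independent
#' truncated normals around population means, measured at a set of tilt
#' angles under baseline (closed-loop) conditions and at 0 and 15
#' degrees under ganglionic blockade, with additive pressure noise and
#' multiplicative norepinephrine assay noise.
#'
#' Default means and SDs are the representative group values of
#' [subject_truth()] with between-subject SDs (3.07, 9.5, 0.08, 4.9,
#' 0.05, 8.6, 10) for (g_mn, ap_mn0, g_nm_0, ap_nm0_0, g_nm_15,
#' ap_nm0_15, pne_residual).
#'
#' @param n_subjects Number of subjects (default 7).
#' @param means Named list of population means for the [subject_truth()]
#'   fields `g_mn`, `ap_mn0`, `g_nm_0`, `ap_nm0_0`, `g_nm_15`,
#'   `ap_nm0_15`, `pne_residual`.
#' @param sds Named list of population SDs, same names; 0 degenerates a
#'   parameter to its exact mean.
#' @param angles Baseline tilt angles, degrees (default -7, 0, 15, 60;
#'   must be distinct and include 0 and 15 so NM fits are possible).
#' @param ap_noise_sd Additive measurement noise SD on AP, mmHg
#'   (default 2).
#' @param pne_noise_cv Fractional (coefficient-of-variation)
#'   multiplicative lognormal noise on PNE (default 0.08).
#' @param pne_floor Sympathetic silence floor passed to [mn_arc()].
#' @param seed Integer seed controlling the whole cohort; per-subject
#'   substreams are derived from it deterministically.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 7,
                          means = list(g_mn = 8.92, ap_mn0 = 103.0,
                                       g_nm_0 = 0.61, ap_nm0_0 = 34.1,
                                       g_nm_15 = 0.36, ap_nm0_15 = 33.4,
                                       pne_residual = 45),
                          sds = list(g_mn = 3.07, ap_mn0 = 9.5,
                                     g_nm_0 = 0.08, ap_nm0_0 = 4.9,
                                     g_nm_15 = 0.05, ap_nm0_15 = 8.6,
                                     pne_residual = 10),
                          angles = c(-7, 0, 15, 60),
                          ap_noise_sd = 2,
                          pne_noise_cv = 0.08,
                          pne_floor = 0,
                          seed = 1L) {
  cfg <- structure(
    list(n_subjects = n_subjects, means = means, sds = sds, angles = angles,
         ap_noise_sd = ap_noise_sd, pne_noise_cv = pne_noise_cv,
         pne_floor = pne_floor, seed = seed),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

truth_fields <- c("g_mn", "ap_mn0", "g_nm_0", "ap_nm0_0", "g_nm_15",
                  "ap_nm0_15", "pne_residual")

validate_cohort_config <- function(cfg) {
  bad <- character()
  ok_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok_num(cfg$n_subjects) || cfg$n_subjects < 1 ||
      cfg$n_subjects != round(cfg$n_subjects)) bad <- c(bad, "n_subjects")
  for (fld in truth_fields) {
    if (!ok_num(cfg$means[[fld]])) bad <- c(bad, paste0("means$", fld))
    if (!ok_num(cfg$sds[[fld]]) || cfg$sds[[fld]] < 0) bad <- c(bad, paste0("sds$", fld))
  }
  extra <- c(setdiff(names(cfg$means), truth_fields),
             setdiff(names(cfg$sds), truth_fields))
  if (length(extra)) bad <- c(bad, paste0("unknown parameter: ", unique(extra)))
  if (!is.numeric(cfg$angles) || length(cfg$angles) < 3L ||
      anyDuplicated(cfg$angles) || any(!is.finite(cfg$angles)) ||
      !all(c(0, 15) %in% cfg$angles)) bad <- c(bad, "angles")
  if (!ok_num(cfg$ap_noise_sd) || cfg$ap_noise_sd < 0) bad <- c(bad, "ap_noise_sd")
  if (!ok_num(cfg$pne_noise_cv) || cfg$pne_noise_cv < 0) bad <- c(bad, "pne_noise_cv")
  if (!ok_num(cfg$pne_floor) || cfg$pne_floor < 0) bad <- c(bad, "pne_floor")
  if (!ok_num(cfg$seed) || cfg$seed != round(cfg$seed)) bad <- c(bad, "seed")
  if (length(bad)) {
    abort_baroloop(
      sprintf("invalid cohort configuration field(s): %s", paste(bad, collapse = ", ")),
      "validation"
    )
  }
  cfg
}

# Deterministic per-purpose substream seed below 2^31, derived from the
# cohort seed so one seed reproduces the whole study.
substream_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) * 7919 + index * 104729) %% 2147483647)
}

# One truncated-normal draw via inverse-CDF so each parameter consumes
# exactly one uniform regardless of truncation.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Draw a cohort of true subject parameters
#'
#' Draws each subject's generative parameters independently from
#' truncated normal distributions (truncated at zero for the gains and
#' the blockade PNE residual) around the configured population means.
#' With all SDs zero every subject equals the means exactly. The draw is
#' reproducible: the same configuration (including seed) yields the same
#' cohort.
#'
#' @param config A [cohort_config()].
#' @return List of [subject_truth()] objects, length `n_subjects`.
#' @export
draw_population <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_baroloop("`config` must be a cohort_config", "invalid_argument")
  }
  validate_cohort_config(config)
  lapply(seq_len(config$n_subjects), function(i) {
    set.seed(substream_seed(config$seed, i))
    draw <- function(fld, positive) {
      m <- config$means[[fld]]; s <- config$sds[[fld]]
      if (positive) rtruncnorm0(1, m, s) else if (s == 0) m else stats::rnorm(1, m, s)
    }
    subject_truth(
      g_mn = draw("g_mn", TRUE),
      ap_mn0 = draw("ap_mn0", FALSE),
      pne_floor = config$pne_floor,
      g_nm_0 = draw("g_nm_0", TRUE),
      ap_nm0_0 = draw("ap_nm0_0", FALSE),
      g_nm_15 = draw("g_nm_15", TRUE),
      ap_nm0_15 = draw("ap_nm0_15", FALSE),
      pne_residual = draw("pne_residual", TRUE)
    )
  })
}

#' Neuromechanical arc at an arbitrary tilt angle
#'
#' Interpolates a subject's NM parameters between the measured anchors
#' at 0 and 15 degrees as functions of sin(angle): the gain
#' log-linearly, `g_nm(a) = g_nm_0 * (g_nm_15/g_nm_0)^(sin a / sin 15)`,
#' which keeps it positive out to steep tilt, and the null-PNE offset
#' linearly in sin(angle). Both anchors are reproduced exactly. This
#' angle dependence beyond the two anchors is a generator assumption,
#' not an estimated quantity.
#'
#' @param truth A [subject_truth()].
#' @param angle_deg Tilt angle, degrees, within [-7, 60].
#' @return An [nm_arc()] at that angle.
#' @export
nm_params_at_angle <- function(truth, angle_deg) {
  if (!inherits(truth, "subject_truth")) {
    abort_baroloop("`truth` must be a subject_truth", "invalid_argument")
  }
  stopifnot_scalar_finite(angle_deg, "angle_deg")
  if (angle_deg < -7 || angle_deg > 60) {
    abort_baroloop(
      sprintf("angle %g deg outside the supported range [-7, 60]", angle_deg),
      "out_of_range"
    )
  }
  s <- sin(angle_deg * pi / 180) / sin(15 * pi / 180)
  g_nm <- truth$g_nm_0 * (truth$g_nm_15 / truth$g_nm_0)^s
  ap_nm0 <- truth$ap_nm0_0 + (truth$ap_nm0_15 - truth$ap_nm0_0) * s
  nm_arc(g_nm, ap_nm0, angle_deg)
}

#' Simulate a tilt plus ganglionic-blockade study
#'
#' Generates the full study table for a cohort: for each subject,
#' baseline rows are the closed-loop operating points at each configured
#' tilt angle, and blockade rows at 0 and 15 degrees sit on the NM line
#' at the subject's non-neural PNE residual (blockade PNE does not
#' respond to angle). Observed AP carries additive Gaussian measurement
#' noise; observed PNE carries multiplicative unit-mean lognormal assay
#' noise with the configured coefficient of variation. With all SDs and
#' noise set to zero the table is exactly model-consistent. Heart rate
#' is filled with plausible values as a passthrough column; it is not
#' used by the estimators.
#'
#' @param config A [cohort_config()].
#' @return A `study_dataset`: list with `data` (the study table:
#'   `subject_id`, `condition`, `angle_deg`, `ap_mmHg`, `hr_bpm`,
#'   `pne_pg_ml`), `truths` (the drawn [subject_truth()] list),
#'   `config`, `seed` and `generator_version`.
#' @export
simulate_study <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort_baroloop("`config` must be a cohort_config", "invalid_argument")
  }
  validate_cohort_config(config)
  truths <- draw_population(config)
  sdlog <- sqrt(log(1 + config$pne_noise_cv^2))
  pne_noise <- function(n) {
    if (sdlog == 0) rep(1, n) else exp(stats::rnorm(n, 0, sdlog) - sdlog^2 / 2)
  }
  ap_noise <- function(n) {
    if (config$ap_noise_sd == 0) rep(0, n) else stats::rnorm(n, 0, config$ap_noise_sd)
  }
  hr_noise <- function(n) {
    if (config$ap_noise_sd == 0 && config$pne_noise_cv == 0) rep(0, n)
    else stats::rnorm(n, 0, 3)
  }
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    truth <- truths[[i]]
    set.seed(substream_seed(config$seed, 1000000 + i))
    base <- lapply(sort(config$angles), function(ang) {
      op <- tryCatch(
        solve_operating_point(truth$mn, nm_params_at_angle(truth, ang)),
        baroloop_error = function(e) {
          abort_baroloop(
            sprintf("subject %d, angle %g: %s", i, ang, conditionMessage(e)),
            "simulation"
          )
        }
      )
      data.frame(
        condition = "baseline", angle_deg = ang,
        ap_true = op$ap, pne_true = op$pne,
        hr_base = 96 + 0.36 * ang
      )
    })
    block <- lapply(c(0, 15), function(ang) {
      nm <- nm_params_at_angle(truth, ang)
      data.frame(
        condition = "blockade", angle_deg = ang,
        ap_true = nm_arc_response(truth$pne_residual, nm),
        pne_true = truth$pne_residual,
        hr_base = 87
      )
    })
    df <- do.call(rbind, c(base, block))
    n <- nrow(df)
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%02d", i),
      condition = df$condition,
      angle_deg = df$angle_deg,
      ap_mmHg = df$ap_true + ap_noise(n),
      hr_bpm = pmax(40, df$hr_base + hr_noise(n)),
      pne_pg_ml = df$pne_true * pne_noise(n),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      data = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      truths = truths,
      config = config,
      seed = config$seed,
      generator_version = as.character(utils::packageVersion("baroloop"))
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic tilt study: %d subjects, %d rows (seed %d, generator %s)\n",
    x$config$n_subjects, nrow(x$data), x$seed, x$generator_version
  ))
  print(utils::head(x$data, 6))
  invisible(x)
}
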