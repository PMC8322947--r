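#' Write a study table to delimited text
#'
#' Writes the comma-delimited study-table schema (header row; columns
#' `subject_id`, `condition`, `angle_deg`, `ap_mmHg`, `hr_bpm`,
#' `pne_pg_ml`). Numeric columns are written with 17 significant digits
#' so a write-then-read round trip is lossless at double precision.
#' When given a `study_dataset`, a YAML provenance sidecar
#' (`<path>.provenance.yaml`: seed, generator version, config echo) is
#' written alongside.
#'
#' AP values are taken to be referenced to the clavicle/baroreceptor
#' level; this measurement convention is recorded in the sidecar and no
#' hydrostatic correction is applied.
#'
#' @param x A `study_dataset` or a study-table data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  dataset <- NULL
  if (inherits(x, "study_dataset")) {
    dataset <- x
    x <- x$data
  }
  if (!is.data.frame(x)) {
    abort_baroloop("`x` must be a study_dataset or data frame", "invalid_argument")
  }
  out <- x
  for (col in c("angle_deg", "ap_mmHg", "hr_bpm", "pne_pg_ml")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(dataset)) {
    side <- list(
      seed = dataset$seed,
      generator_version = dataset$generator_version,
      ap_reference = "clavicle (baroreceptor level), no hydrostatic correction",
      config = c(
        dataset$config[c("n_subjects", "ap_noise_sd", "pne_noise_cv",
                         "pne_floor", "seed")],
        list(angles = dataset$config$angles,
             means = dataset$config$means,
             sds = dataset$config$sds)
      )
    )
    yaml::write_yaml(side, paste0(path, ".provenance.yaml"))
  }
  invisible(path)
}

#' Read and validate a study table
#'
#' Reads the delimited study-table schema written by
#' [write_study_table()] and validates it: required columns present
#' (`hr_bpm` is optional), `condition` limited to
#' `"baseline"`/`"blockade"`, AP finite and positive, PNE finite and
#' non-negative, no missing AP/PNE. Violations raise a schema error
#' naming the offending column and rows.
#'
#' @param path Path to a delimited study table.
#' @return Data frame in the study-table schema.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) {
    abort_baroloop(sprintf("file not found: %s", path), "io")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_table(df)
}

validate_study_table <- function(df) {
  required <- c("subject_id", "condition", "angle_deg", "ap_mmHg", "pne_pg_ml")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_baroloop(
      sprintf("study table is missing required column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "schema_violation"
    )
  }
  bad_cond <- which(!df$condition %in% c("baseline", "blockade"))
  if (length(bad_cond)) {
    abort_baroloop(
      sprintf("column condition: invalid value(s) in row(s) %s (allowed: baseline, blockade)",
              paste(utils::head(bad_cond, 5), collapse = ", ")),
      "schema_violation"
    )
  }
  check_num <- function(col, lower, allow_equal) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v) | if (allow_equal) v < lower else v <= lower)
    if (length(bad)) {
      abort_baroloop(
        sprintf("column %s: missing/non-finite/out-of-range value(s) in row(s) %s",
                col, paste(utils::head(bad, 5), collapse = ", ")),
        "schema_violation"
      )
    }
    v
  }
  df$angle_deg <- check_num("angle_deg", -Inf, TRUE)
  df$ap_mmHg <- check_num("ap_mmHg", 0, FALSE)
  df$pne_pg_ml <- check_num("pne_pg_ml", 0, TRUE)
  if (!"hr_bpm" %in% names(df)) df$hr_bpm <- NA_real_
  df$hr_bpm <- suppressWarnings(as.numeric(df$hr_bpm))
  df
}

#' Read a cohort configuration file
#'
#' Reads a YAML configuration whose keys mirror the [cohort_config()]
#' arguments (`n_subjects`, `means`, `sds`, `angles`, `ap_noise_sd`,
#' `pne_noise_cv`, `pne_floor`, `seed`). Keys omitted fall back to the
#' defaults; unknown keys are an error so typos cannot silently
#' deconfigure a study.
#'
#' @param path Path to a YAML file (NULL returns the default config).
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path = NULL) {
  if (is.null(path)) return(cohort_config())
  if (!file.exists(path)) {
    abort_baroloop(sprintf("config file not found: %s", path), "io")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_baroloop(
      sprintf("unknown configuration field(s): %s", paste(unknown, collapse = ", ")),
      "validation"
    )
  }
  defaults <- formals(cohort_config)
  args <- list()
  for (nm in known) {
    args[[nm]] <- if (nm %in% names(raw)) raw[[nm]] else eval(defaults[[nm]])
  }
  # partial means/sds lists are completed from the defaults
  for (fld in c("means", "sds")) {
    full <- eval(defaults[[fld]])
    given <- args[[fld]]
    if (!is.list(given)) {
      abort_baroloop(sprintf("`%s` must be a mapping of parameter names", fld),
                     "validation")
    }
    full[names(given)] <- given
    args[[fld]] <- full
  }
  args$angles <- as.numeric(unlist(args$angles))
  do.call(cohort_config, args)
}
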