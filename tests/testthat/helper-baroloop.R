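# Reference parameter set used across tests: representative group-mean
# arc parameters of a seven-subject atropinized tilt study.
ref_mn <- function() mn_arc(g_mn = 8.92, ap_mn0 = 103.0)
ref_nm0 <- function() nm_arc(g_nm = 0.61, ap_nm0 = 34.1, angle_deg = 0)
ref_nm15 <- function() nm_arc(g_nm = 0.36, ap_nm0 = 33.4, angle_deg = 15)

zero_sds <- function() {
  lapply(cohort_config()$sds, function(x) 0)
}

# Exactly model-consistent cohort: population SDs and measurement noise
# all zero, truths equal to the configured means.
zero_noise_config <- function(n_subjects = 7, seed = 1L) {
  cohort_config(n_subjects = n_subjects, sds = zero_sds(),
                ap_noise_sd = 0, pne_noise_cv = 0, seed = seed)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected) / abs(expected), rel_tol)
}
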