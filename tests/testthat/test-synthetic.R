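test_that("population draws are reproducible and degenerate to the means at zero SD", {
  cfg <- cohort_config(seed = 5, sds = zero_sds())
  pop <- draw_population(cfg)
  expect_length(pop, 7L)
  for (tr in pop) {
    expect_equal(tr$mn$g_mn, 8.92)
    expect_equal(tr$mn$ap_mn0, 103.0)
    expect_equal(tr$g_nm_0, 0.61)
    expect_equal(tr$g_nm_15, 0.36)
    expect_equal(tr$pne_residual, 45)
  }
  cfg2 <- cohort_config(seed = 5)
  expect_identical(draw_population(cfg2), draw_population(cfg2))
  # different seeds give different cohorts
  expect_false(identical(draw_population(cohort_config(seed = 6)),
                         draw_population(cfg2)))
  # gains stay positive under the truncated draws
  pop_wide <- draw_population(cohort_config(n_subjects = 50, seed = 8))
  expect_true(all(sapply(pop_wide, function(t) t$mn$g_mn > 0)))
  expect_true(all(sapply(pop_wide, function(t) t$pne_residual >= 0)))
})

test_that("population means are recovered by Monte Carlo over many cohorts", {
  draws <- unlist(lapply(1:150, function(s) {
    sapply(draw_population(cohort_config(seed = 1000 + s)),
           function(t) t$mn$g_mn)
  }))
  se <- sd(draws) / sqrt(length(draws))
  # truncation at zero barely shifts a mean 2.9 SDs above it
  expect_lt(abs(mean(draws) - 8.92), 3 * se + 0.02)
})

test_that("invalid configurations name the offending fields", {
  expect_error(cohort_config(n_subjects = 0), "n_subjects",
               class = "baroloop_validation")
  expect_error(cohort_config(angles = c(0, 15, 15)), "angles",
               class = "baroloop_validation")
  expect_error(cohort_config(ap_noise_sd = -1), "ap_noise_sd",
               class = "baroloop_validation")
  expect_error(cohort_config(sds = list(g_mn = -3)), "sds",
               class = "baroloop_validation")
})

test_that("NM interpolation reproduces the anchors and the frozen 60-degree values", {
  tr <- subject_truth()
  nm0 <- nm_params_at_angle(tr, 0)
  expect_equal(nm0$g_nm, 0.61)
  expect_equal(nm0$ap_nm0, 34.1)
  nm15 <- nm_params_at_angle(tr, 15)
  expect_equal(nm15$g_nm, 0.36)
  expect_equal(nm15$ap_nm0, 33.4)
  nm60 <- nm_params_at_angle(tr, 60)
  expect_equal(nm60$g_nm, 0.1044694814, tolerance = 1e-7)
  expect_equal(nm60$ap_nm0, 31.7577543, tolerance = 1e-7)
  expect_error(nm_params_at_angle(tr, 75), class = "baroloop_out_of_range")
  expect_error(nm_params_at_angle(tr, -10), class = "baroloop_out_of_range")
})

test_that("zero-noise studies are exactly model-consistent", {
  ds <- simulate_study(zero_noise_config(n_subjects = 3, seed = 2))
  expect_equal(nrow(ds$data), 3 * 6)
  for (i in 1:3) {
    tr <- ds$truths[[i]]
    rows <- ds$data[ds$data$subject_id == sprintf("S%02d", i), ]
    for (j in seq_len(nrow(rows))) {
      nm <- nm_params_at_angle(tr, rows$angle_deg[j])
      # every row sits on its NM line
      expect_equal(nm_arc_response(rows$pne_pg_ml[j], nm), rows$ap_mmHg[j],
                   tolerance = 1e-9)
      if (rows$condition[j] == "baseline") {
        # baseline rows also satisfy the MN equation (closed loop)
        expect_equal(mn_arc_response(rows$ap_mmHg[j], tr$mn),
                     rows$pne_pg_ml[j], tolerance = 1e-9)
      } else {
        expect_equal(rows$pne_pg_ml[j], tr$pne_residual, tolerance = 1e-12)
      }
    }
  }
})

test_that("noiseless pressure falls and norepinephrine rises monotonically with tilt", {
  ds <- simulate_study(zero_noise_config(seed = 3))
  for (id in unique(ds$data$subject_id)) {
    base <- ds$data[ds$data$subject_id == id & ds$data$condition == "baseline", ]
    base <- base[order(base$angle_deg), ]
    expect_true(all(diff(base$ap_mmHg) < 0))
    expect_true(all(diff(base$pne_pg_ml) > 0))
  }
  # steep-tilt pressure lands in the physiologic low-60s range
  ap60 <- ds$data$ap_mmHg[ds$data$angle_deg == 60 & ds$data$condition == "baseline"]
  expect_equal(mean(ap60), 66.1226, tolerance = 1e-3)
})

test_that("a fixed seed reproduces the study exactly; noise perturbs it", {
  cfg <- cohort_config(seed = 12)
  expect_identical(simulate_study(cfg)$data, simulate_study(cfg)$data)
  noisy <- simulate_study(cfg)$data
  clean <- simulate_study(zero_noise_config(seed = 12))$data
  expect_false(isTRUE(all.equal(noisy$ap_mmHg, clean$ap_mmHg)))
  # blockade PNE does not respond to angle (identical residual pre-noise)
  blk <- clean[clean$condition == "blockade", ]
  expect_equal(blk$pne_pg_ml[blk$angle_deg == 0], blk$pne_pg_ml[blk$angle_deg == 15])
})

test_that("cohort-level estimates recover the truth under default measurement noise", {
  # 200 replicate seven-subject studies at the default noise levels
  # (AP sd 2 mmHg, PNE CV 8%), truths pinned to the population means
  errs <- t(sapply(1:200, function(s) {
    ds <- simulate_study(cohort_config(sds = zero_sds(), seed = s))
    sm <- summarize_group(estimate_cohort(ds))
    c(gmn = abs(sm$stats$mean[sm$stats$parameter == "g_mn"] - 8.92) / 8.92,
      gl0 = abs(sm$stats$mean[sm$stats$parameter == "g_l_0"] - 5.4412) / 5.4412)
  }))
  expect_lt(median(errs[, "gmn"]), 0.10)
  expect_lt(median(errs[, "gl0"]), 0.15)
})

test_that("estimation error grows with measurement noise and vanishes without it", {
  med_err <- sapply(c(0, 1, 2, 4), function(scale) {
    errs <- sapply(1:70, function(s) {
      cfg <- cohort_config(n_subjects = 1, sds = zero_sds(),
                           ap_noise_sd = 1 * scale,
                           pne_noise_cv = 0.02 * scale, seed = 300 + s)
      est <- estimate_cohort(simulate_study(cfg))$estimates
      if (!length(est)) NA else abs(est[[1]]$mn_fit$params$g_mn - 8.92) / 8.92
    })
    median(errs, na.rm = TRUE)
  })
  expect_lt(med_err[1], 1e-9)
  expect_true(all(diff(med_err) > 0))
})
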