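test_that("MN-arc regression recovers the frozen normal-equations fit of the group means", {
  fit <- fit_mn_arc(ap = c(91, 87, 79, 59), pne = c(83, 92, 129, 278))
  expect_equal(fit$params$g_mn, 6.29605263, tolerance = 1e-7)
  expect_equal(fit$params$ap_mn0, 102.10966, tolerance = 1e-5)
  expect_equal(fit$r, -0.98987215, tolerance = 1e-7)
  expect_equal(fit$n_points, 4L)
})

test_that("MN-arc regression is exact on colinear points and rejects degenerate designs", {
  ap <- c(95, 100, 85, 70)
  pne <- 8.92 * (103.0 - ap)
  fit <- fit_mn_arc(ap, pne)
  expect_equal(fit$params$g_mn, 8.92, tolerance = 1e-12)
  expect_equal(fit$params$ap_mn0, 103.0, tolerance = 1e-10)
  expect_equal(fit$r, -1, tolerance = 1e-12)
  expect_error(fit_mn_arc(c(90, 80), c(100, 150)),
               class = "baroloop_insufficient_data")
  expect_error(fit_mn_arc(c(90, 90, 90), c(80, 90, 100)),
               class = "baroloop_degenerate_design")
  # positive slope means no reflex response, not a negative gain
  expect_error(fit_mn_arc(c(70, 80, 90), c(80, 90, 100)),
               class = "baroloop_no_reflex_response")
})

test_that("two-point NM fit interpolates both measured points exactly", {
  nm_sup <- fit_nm_arc(c(pne = 92, ap = 87), c(pne = 47, ap = 61))
  expect_equal(nm_sup$g_nm, 26 / 45, tolerance = 1e-12)
  expect_equal(nm_sup$ap_nm0, 61 - 26 / 45 * 47, tolerance = 1e-12)
  nm_hut <- fit_nm_arc(c(pne = 129, ap = 79), c(pne = 40, ap = 46))
  expect_equal(nm_hut$g_nm, 33 / 89, tolerance = 1e-12)
  expect_equal(nm_hut$ap_nm0, 46 - 33 / 89 * 40, tolerance = 1e-12)
  # fitted line reproduces its inputs
  expect_equal(nm_arc_response(92, nm_sup), 87, tolerance = 1e-12)
  expect_equal(nm_arc_response(47, nm_sup), 61, tolerance = 1e-12)
  expect_error(fit_nm_arc(c(pne = 92, ap = 87), c(pne = 92, ap = 61)),
               class = "baroloop_degenerate_line")
  # an anomalous negative slope is flagged, not dropped
  flagged <- fit_nm_arc(c(pne = 92, ap = 61), c(pne = 47, ap = 87))
  expect_true("negative_gain" %in% flagged$flags)
  expect_lt(flagged$g_nm, 0)
})

test_that("per-subject pipeline recovers noiseless truth and validates required rows", {
  ds <- simulate_study(zero_noise_config(n_subjects = 1))
  est <- estimate_subject(ds$data)
  expect_rel_equal(est$mn_fit$params$g_mn, 8.92, 1e-9)
  expect_rel_equal(est$mn_fit$params$ap_mn0, 103.0, 1e-9)
  expect_rel_equal(est$nm_0$g_nm, 0.61, 1e-9)
  expect_rel_equal(est$nm_0$ap_nm0, 34.1, 1e-9)
  expect_rel_equal(est$nm_15$g_nm, 0.36, 1e-9)
  expect_rel_equal(est$nm_15$ap_nm0, 33.4, 1e-9)
  expect_rel_equal(est$g_l_0, 5.4412, 1e-9)
  expect_equal(est$mn_fit$r, -1, tolerance = 1e-9)
  # dropping the 15-degree blockade row names the missing combination
  broken <- ds$data[!(ds$data$condition == "blockade" & ds$data$angle_deg == 15), ]
  expect_error(estimate_subject(broken), "blockade.*15",
               class = "baroloop_schema_violation")
})

test_that("a pseudo-subject of group-mean rows reproduces the composed fits", {
  rec <- data.frame(
    subject_id = "GM",
    condition = c(rep("baseline", 4), rep("blockade", 2)),
    angle_deg = c(-7, 0, 15, 60, 0, 15),
    ap_mmHg = c(91, 87, 79, 59, 61, 46),
    pne_pg_ml = c(83, 92, 129, 278, 47, 40)
  )
  est <- estimate_subject(rec)
  expect_equal(est$mn_fit$params$g_mn, 6.29605263, tolerance = 1e-7)
  expect_equal(est$nm_0$g_nm, 26 / 45, tolerance = 1e-12)
  expect_equal(est$g_l_0, 3.63771930, tolerance = 1e-7)
})

test_that("group summary uses sample SD and the mean-of-products gain convention", {
  ds <- simulate_study(zero_noise_config(n_subjects = 7))
  est <- estimate_cohort(ds)
  sm <- summarize_group(est)
  expect_equal(sm$n_subjects, 7L)
  expect_true(all(sm$stats$sd < 1e-9))   # identical subjects
  # two hand-built subjects: mean 5, sd sqrt(2)
  two <- lapply(c(4, 6), function(gl) {
    e <- est$estimates[[1]]
    e$g_l_0 <- gl
    e
  })
  sm2 <- summarize_group(two)
  expect_equal(sm2$stats$mean[sm2$stats$parameter == "g_l_0"], 5)
  expect_equal(sm2$stats$sd[sm2$stats$parameter == "g_l_0"], sqrt(2),
               tolerance = 1e-12)
  expect_error(summarize_group(est$estimates[1]),
               class = "baroloop_insufficient_data")
})

test_that("group gain is the mean of per-subject products, not the product of group means", {
  mk <- function(id, g_mn, g_nm0) {
    ap <- c(95, 100, 85, 70)
    rec <- data.frame(
      subject_id = id,
      condition = c(rep("baseline", 4), rep("blockade", 2)),
      angle_deg = c(-7, 0, 15, 60, 0, 15),
      ap_mmHg = c(ap, 50, 45),
      pne_pg_ml = c(g_mn * (103 - ap),
                    (50 - (103 - 103 * 0)) / 1,  # overwritten below
                    0)
    )
    # put blockade rows on a consistent NM line with gain g_nm0
    base0_ap <- 100; base0_pne <- g_mn * (103 - base0_ap)
    rec$ap_mmHg[5] <- base0_ap - g_nm0 * (base0_pne - 20)
    rec$pne_pg_ml[5] <- 20
    rec$ap_mmHg[6] <- 85 - 0.3 * (g_mn * (103 - 85) - 20)
    rec$pne_pg_ml[6] <- 20
    estimate_subject(rec)
  }
  ests <- list(mk("A", 10, 0.5), mk("B", 8, 0.7))
  sm <- summarize_group(ests)
  expect_equal(sm$stats$mean[sm$stats$parameter == "g_l_0"],
               (10 * 0.5 + 8 * 0.7) / 2, tolerance = 1e-9)
  expect_equal(unname(sm$g_l_product_of_means["g_l_0"]), 9 * 0.6,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(sm$stats$mean[sm$stats$parameter == "g_l_0"],
                                unname(sm$g_l_product_of_means["g_l_0"]))))
})

test_that("cohort estimation collects failing subjects with reasons", {
  ds <- simulate_study(zero_noise_config(n_subjects = 3))
  bad <- ds$data
  bad <- bad[!(bad$subject_id == "S02" & bad$condition == "blockade" &
                 bad$angle_deg == 0), ]
  est <- estimate_cohort(bad)
  expect_length(est$estimates, 2L)
  expect_named(est$failures, "S02")
  expect_match(est$failures[["S02"]], "blockade")
  tab <- as.data.frame(est)
  expect_equal(nrow(tab), 2L)
})
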