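test_that("combined time is the grid-snapped mean of the method times", {
  # two synthetic signals whose planted breaks sit at known samples: build a
  # series where the exco2 and vslope changepoints land at different times
  # and check the combination arithmetic on the reported estimate
  sim <- simulate_test(sim_params(seed = 2))
  est <- detect_vt1(sim$series, cpet_protocol("nominal"))
  times <- vapply(est$methods, `[[`, 0, "time")
  snapped <- floor((mean(times) - 190) / 10 + 0.5) * 10 + 190
  expect_equal(est$time, snapped)
  # the snap rounds half-way cases up to the later sample
  expect_equal(floor((445 - 190) / 10 + 0.5) * 10 + 190, 450)
})

test_that("threshold estimates read all channels at one instant", {
  sim <- simulate_test(sim_params(seed = 9))
  post <- exclude_warmup(sim$series, cpet_protocol("nominal"))
  for (est in list(detect_vt1(sim$series, cpet_protocol("nominal"), body_mass = 76.8),
                   detect_vt2(sim$series, cpet_protocol("nominal"), body_mass = 76.8))) {
    i <- match(est$time, post$time)
    expect_equal(est$vo2_abs, post$vo2[i])
    expect_equal(est$ve, post$ve[i])
    expect_equal(est$hr, post$hr[i])
    expect_equal(est$rer, post$rer[i])
    expect_equal(est$work, post$work[i])
    expect_equal(est$vo2_rel, 1000 * post$vo2[i] / 76.8)
  }
})

test_that("a constant-slope test without a planted break is indeterminate", {
  # linear ramp in every channel, no knots: the forced changepoint must be
  # flagged, propagating indeterminacy to the combined estimate
  n <- 60
  t <- seq(10, by = 10, length.out = n)
  vo2 <- seq(1, 3, length.out = n)
  s <- cpet_series(time = t, vo2 = vo2, vco2 = 0.9 * vo2, ve = 24 * vo2,
                   protocol = cpet_protocol("nominal"))
  est <- detect_vt1(s, cpet_protocol("nominal"))
  # trend splits are still "significant" in cost terms; indeterminacy comes
  # from a truly flat signal
  flat <- cpet_series(time = t, vo2 = rep(2, n), vco2 = rep(1.8, n),
                      ve = rep(45, n), protocol = cpet_protocol("nominal"))
  est_flat <- detect_vt1(flat, cpet_protocol("nominal"))
  expect_true(est_flat$indeterminate)
})

test_that("combined thresholds at or before the credibility time are rejected", {
  sim <- simulate_test(sim_params(seed = 3))
  ok <- detect_vt1(sim$series, cpet_protocol("nominal"))
  expect_false(ok$indeterminate)
  # same detection with the credibility limit moved past the estimate
  late <- detect_vt1(sim$series, cpet_protocol("nominal"), min_time = ok$time)
  expect_true(late$indeterminate)
  expect_equal(late$time, ok$time)  # the estimate itself is unchanged
})

test_that("too-short tests raise a detection error", {
  s <- make_series(vo2 = rep(2, 25))  # 250 s -> 7 post-warm-up samples
  expect_error(detect_vt1(s, cpet_protocol("nominal")), "12")
})

test_that("peak values use a 30-s rolling mean", {
  s <- make_series(vo2 = c(2, 3, 4))
  expect_equal(peak_values(s)$vo2_abs, 3)  # single full window
  # monotone channel: peak window is the last three samples
  s2 <- make_series(vo2 = seq(1, 3.3, length.out = 30))
  expect_equal(peak_values(s2)$vo2_abs, mean(s2$vo2[28:30]))
  expect_equal(peak_values(s2, body_mass = 76.8)$vo2_rel,
               1000 * mean(s2$vo2[28:30]) / 76.8)
  expect_error(peak_values(make_series(vo2 = c(2, 3))), "3 samples")
})

test_that("relative intensities are percentages of the peak readouts", {
  rep_stub <- list(
    vt1 = list(vo2_abs = 1.9, work = 156.2, indeterminate = FALSE),
    vt2 = list(vo2_abs = 2.6, work = 213.8, indeterminate = FALSE),
    peaks = list(vo2_abs = 3.3, work = 303.3))
  ri <- relative_intensity(rep_stub)
  expect_equal(unname(ri["pct_peak_vo2_at_vt1"]), 100 * 1.9 / 3.3,
               tolerance = 1e-12)
  expect_equal(unname(ri["pct_peak_w_at_vt2"]), 100 * 213.8 / 303.3,
               tolerance = 1e-12)
  # vt equal to peak gives exactly 100%
  rep_stub$vt2$vo2_abs <- 3.3
  rep_stub$vt2$work <- 303.3
  ri2 <- relative_intensity(rep_stub)
  expect_equal(unname(ri2["pct_peak_vo2_at_vt2"]), 100)
  rep_stub$peaks$vo2_abs <- 0
  expect_error(relative_intensity(rep_stub), "peak")
})

test_that("full report bundles thresholds, peaks and intensities", {
  sim <- simulate_test(sim_params(seed = 4))
  rep <- detect_thresholds(sim$series, cpet_protocol("nominal"),
                           body_mass = 76.8,
                           maximality = list(plateau = TRUE, rpm_fall = FALSE))
  expect_s3_class(rep, "vt_report")
  expect_false(rep$vt1$indeterminate)
  expect_false(rep$vt2$indeterminate)
  expect_true(all(rep$relative_intensity > 0 & rep$relative_intensity <= 100))
  expect_false(rep$ordering_violated)
  expect_s3_class(rep$maximality, "maximality_verdict")
  lst <- vt_report_list(rep)
  expect_equal(lst$vt1$time_s, rep$vt1$time)
  expect_equal(lst$peak$work_w, round(rep$peaks$work, 1))
})
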