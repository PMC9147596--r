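test_that("sweep generation is deterministic for a fixed seed", {
  p <- na_channel_params()
  f1 <- gen_ina_family(p, "IV_ACTIVATION", noise_sd = 0.5, seed = 123)
  f2 <- gen_ina_family(p, "IV_ACTIVATION", noise_sd = 0.5, seed = 123)
  expect_identical(f1$sweeps[["-40"]]$samples, f2$sweeps[["-40"]]$samples)
  f3 <- gen_ina_family(p, "IV_ACTIVATION", noise_sd = 0.5, seed = 124)
  expect_false(identical(f1$sweeps[["-40"]]$samples,
                         f3$sweeps[["-40"]]$samples))
})

test_that("generator parameter validation catches inconsistent inputs", {
  expect_error(na_channel_params(act_k = -1), "slope")
  expect_error(na_channel_params(tau_fast_rec = 400, tau_slow_rec = 300),
               "tau_fast_rec")
  expect_error(ap_shape_params(apd25 = 5, apd50 = 4), "solver error")
  expect_error(ecg_shape_params(qrs = 60, qt = 50), "parameter error")
  expect_error(gen_ina_family(na_channel_params(), "NOT_A_PROTOCOL"),
               "arg")
})

test_that("random channel parameters are recovered through the full pipeline", {
  set.seed(55)
  for (i in 1:6) {
    p <- na_channel_params(
      gmax = runif(1, 0.5, 1.5),
      act_vhalf = runif(1, -55, -40), act_k = runif(1, 3, 6),
      inact_vhalf = runif(1, -95, -70), inact_k = runif(1, 4, 8),
      tau_at_minus40 = runif(1, 2, 4),
      tau_fast_rec = runif(1, 7, 14), tau_slow_rec = runif(1, 250, 450),
      f_late = runif(1, 0, 0.02))
    gv <- suppressWarnings(
      conductance(peak_iv(gen_ina_family(p, "IV_ACTIVATION")), erev = p$erev))
    fa <- fit_activation(gv)
    # the protocol tops out at 0 mV, so for shallow slopes the G_max plateau
    # is not fully reached and the midpoint carries a small protocol bias
    expect_lt(abs(fa$v_half - p$act_vhalf), 0.1)
    expect_lt(abs(fa$k - p$act_k), 0.05)
    fi <- fit_availability(availability_curve(gen_ina_family(p, "AVAILABILITY")))
    expect_equal(fi$v_half, p$inact_vhalf, tolerance = 0.01 / abs(p$inact_vhalf))
    expect_equal(fi$k, p$inact_k, tolerance = 0.01 / p$inact_k)
    fr <- fit_recovery(recovery_ratios(gen_ina_family(p, "RECOVERY")))
    expect_equal(fr$tau_fast, p$tau_fast_rec,
                 tolerance = 0.01 / p$tau_fast_rec)
  }
})

test_that("AP trains hit the requested morphology", {
  ap <- gen_ap_train(ap_targets_wt(n_beats = 2))
  expect_length(ap$stim_times, 2)
  p <- ap_train_params(ap$trace, ap$stim_times)[1, ]
  expect_equal(p$apd90, 115.6, tolerance = 0.5 / 115.6)
  expect_equal(p$triangulation, 113.5, tolerance = 0.15 / 113.5)
})

test_that("per-beat jitter matches its closed-form successive-difference law", {
  # for consecutive iid Normal(0, sd) jitter, E|diff| = 2 sd / sqrt(pi),
  # so E[BVR] = sd * sqrt(2 / pi); checked against a brute-force mean
  sd_j <- 4
  set.seed(56)
  sims <- replicate(400, {
    apd <- 115.6 + rnorm(15, 0, sd_j)
    c(bvr(apd)$bvr, mean(abs(diff(apd))))
  })
  expect_equal(mean(sims[1, ]), sd_j * sqrt(2 / pi), tolerance = 0.03)
  expect_equal(mean(sims[2, ]), 2 * sd_j / sqrt(pi), tolerance = 0.03)
  # the generator's own jittered trains land on the same law
  bv <- vapply(1:25, function(s) {
    ap <- gen_ap_train(ap_shape_params(n_beats = 15, jitter_sd_ms = sd_j,
                                       seed = s))
    bvr(ap_train_params(ap$trace, ap$stim_times)$apd90)$bvr
  }, numeric(1))
  expect_equal(mean(bv), sd_j * sqrt(2 / pi), tolerance = 0.12)
})

test_that("synthetic ECG annotations are exact generator fiducials", {
  e <- gen_ecg(ecg_shape_params(rr = 130.7, qt = 51.9), duration_ms = 1500)
  fid <- e$annotation$fiducials
  expect_equal(fid$qt_end_ms - fid$qrs_on_ms, rep(51.9, nrow(fid)))
  expect_equal(diff(fid$qrs_on_ms), rep(130.7, nrow(fid) - 1))
  # zero-amplitude T wave leaves the annotation contract intact
  e0 <- gen_ecg(ecg_shape_params(t_amp = 0), duration_ms = 1500)
  expect_s3_class(e0$annotation, "ecg_annotation")
  expect_true(all(e0$annotation$fiducials$qt_end_ms >
                    e0$annotation$fiducials$qrs_end_ms))
})

test_that("breath generation is seeded, quiet by default, and injects on cue", {
  b1 <- gen_breaths(seed = 9, duration_s = 600, adaptation_s = 120,
                    analysis_s = 480)
  b2 <- gen_breaths(seed = 9, duration_s = 600, adaptation_s = 120,
                    analysis_s = 480)
  expect_identical(b1$te_s, b2$te_s)
  quiet <- gen_breaths(jitter_cv = 0, duration_s = 600, adaptation_s = 120,
                       analysis_s = 480)
  expect_equal(detect_apnoeas(quiet)$count, 0)
  inj <- gen_breaths(apnoeas = data.frame(time_s = c(200, 350, 500),
                                          length_s = c(1, 1, 1)),
                     jitter_cv = 0.05, seed = 10, duration_s = 600,
                     adaptation_s = 120, analysis_s = 480)
  expect_equal(detect_apnoeas(inj)$count, 3)
  expect_error(
    gen_breaths(apnoeas = data.frame(time_s = c(200, 200.5),
                                     length_s = c(2, 2)), duration_s = 600),
    "overlapping")
})
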