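test_that("R-peak detection recovers the generator's beat times", {
  e <- gen_ecg(ecg_shape_params(rr = 130), duration_ms = 2000)
  pk <- detect_r_peaks(e$trace)
  expect_gte(length(pk), 14)
  expect_lte(length(pk), 16)
  expect_true(all(abs(diff(pk) - 130) <= 1))
  truth <- e$annotation$fiducials$r_peak_ms
  expect_true(all(abs(pk - truth[seq_along(pk)]) <= 1))
})

test_that("flat traces and noise-flagged peaks are handled", {
  expect_error(detect_r_peaks(trace(rep(0, 1000), units = "mV")),
               "detection error")
  e <- gen_ecg(ecg_shape_params(rr = 130), duration_ms = 2000)
  truth <- e$annotation$fiducials$r_peak_ms
  noise <- data.frame(start_ms = truth[3] - 5, end_ms = truth[3] + 5)
  pk <- detect_r_peaks(e$trace, noise = noise)
  expect_false(any(abs(pk - truth[3]) < 5))
})

test_that("per-complex metrics follow the interval definitions", {
  fid <- data.frame(complex_id = 1:3,
                    qrs_on_ms = c(0, 100, 200),
                    r_peak_ms = c(4, 104, 204),
                    qrs_end_ms = c(10.8, 110.8, 210.8),
                    qt_end_ms = c(51.9, 151.9, 251.9))
  m <- complex_metrics(ecg_annotation(fid))
  expect_equal(m$rr[1:2], c(100, 100))
  expect_equal(m$hr[1], 600)            # 60000 / 100
  expect_equal(m$qrs, rep(10.8, 3))     # wild-type mean QRS as a fixture
  expect_equal(m$qt, rep(51.9, 3))
  expect_true(is.na(m$rr[3]))
})

test_that("complexes overlapping noise intervals are excluded", {
  fid <- data.frame(complex_id = 1:3,
                    qrs_on_ms = c(0, 100, 200),
                    r_peak_ms = c(4, 104, 204),
                    qrs_end_ms = c(11, 111, 211),
                    qt_end_ms = c(52, 152, 252))
  ann <- ecg_annotation(fid, noise = data.frame(start_ms = 120, end_ms = 130))
  m <- complex_metrics(ann)
  expect_equal(m$clean, c(TRUE, FALSE, TRUE))
})

test_that("QTc corrections have their closed-form fixed points", {
  expect_equal(qtc(47, 100)$qtc_eq1, 47)        # unit denominator at RR = 100
  expect_equal(qtc(47, 170)$qtc_eq2, 47)        # zero correction at RR = 170
  expect_equal(qtc(51.9, 130.7)$qtc_eq2, 64.37, tolerance = 1e-3)
  # homogeneity of the square-root correction in QT
  expect_equal(qtc(2 * 51.9, 130.7)$qtc_eq1, 2 * qtc(51.9, 130.7)$qtc_eq1)
  expect_error(qtc(-1, 100), "positive")
})

test_that("ECG summary averages the first clean run, QTc per complex", {
  n <- 7
  fid <- data.frame(complex_id = 1:n,
                    qrs_on_ms = (0:(n - 1)) * 130,
                    r_peak_ms = (0:(n - 1)) * 130 + 4,
                    qrs_end_ms = (0:(n - 1)) * 130 + 10.8,
                    qt_end_ms = (0:(n - 1)) * 130 + 51.9)
  m <- complex_metrics(ecg_annotation(fid))
  s <- summarise_ecg(m, 5)
  expect_equal(s$rr, 130)
  expect_equal(s$qt, 51.9)
  expect_equal(s$qtc_eq2, qtc(51.9, 130)$qtc_eq2)  # constant train: no averaging gap
  expect_error(summarise_ecg(m[1:4, ], 5), "longest clean run")
})

test_that("per-complex QTc averaging sits close to QTc of the averages", {
  # physiological RR jitter (CV 5 percent): the convexity gap stays tiny
  set.seed(20)
  for (rep in 1:20) {
    rr <- 130.7 * (1 + rnorm(5, 0, 0.05))
    qt <- 51.9 * (1 + rnorm(5, 0, 0.02))
    per_complex <- colMeans(qtc(qt, rr))
    of_means <- qtc(mean(qt), mean(rr))
    expect_lt(abs(per_complex[["qtc_eq1"]] - of_means$qtc_eq1), 0.2)
    expect_lt(abs(per_complex[["qtc_eq2"]] - of_means$qtc_eq2), 1e-9)
  }
})

test_that("full ECG pipeline on the synthetic generator returns its targets", {
  e <- gen_ecg(ecg_shape_params(rr = 130.7, qt = 51.9, qrs = 10.8),
               duration_ms = 2000)
  m <- complex_metrics(e$annotation, detect_r_peaks(e$trace))
  s <- summarise_ecg(m, 5)
  expect_equal(s$qt, 51.9, tolerance = 1e-6)
  expect_equal(s$qrs, 10.8, tolerance = 1e-6)
  expect_equal(s$rr, 130.7, tolerance = 0.02)
})

test_that("automatic breathing-noise flagging finds injected bursts", {
  e <- gen_ecg(ecg_shape_params(noise_burst_rate_per_s = 1, seed = 44),
               duration_ms = 4000)
  flagged <- flag_breathing_noise(e$trace)
  expect_gt(nrow(flagged), 0)
  # every true burst overlaps some flagged interval
  for (i in seq_len(nrow(e$noise))) {
    hit <- any(flagged$start_ms <= e$noise$end_ms[i] &
                 flagged$end_ms >= e$noise$start_ms[i])
    expect_true(hit)
  }
  clean <- gen_ecg(ecg_shape_params(), duration_ms = 4000)
  expect_equal(nrow(flag_breathing_noise(clean$trace)), 0)
})
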