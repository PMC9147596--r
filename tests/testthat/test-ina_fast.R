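# closed-form oracle for the generator's peak current: maximise the
# continuous-time model (rise filter times decaying inactivation) directly
analytic_peak <- function(p, v) {
  a <- boltzmann_act(v, p$act_vhalf, p$act_k)
  tau <- p$tau_at_minus40 * exp(-(v + 40) / p$tau_efold_mv)
  t_act <- 7 * p$rise_tau_ms
  g <- function(t) (1 - exp(-t / p$rise_tau_ms)) *
    ((1 - p$f_late) * exp(-pmax(0, t - t_act) / tau) + p$f_late)
  opt <- optimize(g, c(0, 50), maximum = TRUE)
  p$gmax * a * (v - p$erev) * opt$objective
}

test_that("peak I-V matches the closed-form oracle within 1 percent", {
  p <- na_channel_params()
  iv <- peak_iv(gen_ina_family(p, "IV_ACTIVATION"))
  truth <- vapply(iv$vm, function(v) analytic_peak(p, v), numeric(1))
  nz <- abs(truth) > 1e-9
  expect_true(all(abs(iv$peak_density[nz] - truth[nz]) <=
                    0.01 * abs(truth[nz])))
  # most negative peak sits on the -40/-30 mV limb for wild-type parameters
  expect_true(iv$vm[which.min(iv$peak_density)] %in% c(-40, -30))
  # a zero sweep reads zero
  expect_equal(iv$peak_density[iv$vm == 0], 0, tolerance = 1e-12)
})

test_that("reversal potential extrapolation is exact on a line", {
  iv <- data.frame(vm = c(-40, -30, -20, -10), peak_density = c(-40, -30, -20, -10))
  expect_equal(estimate_erev(iv), 0, tolerance = 1e-9)
  expect_error(estimate_erev(iv[1:3, ]), "extrapolation error")
  p <- na_channel_params()
  est <- estimate_erev(peak_iv(gen_ina_family(p, "IV_ACTIVATION")))
  expect_lt(abs(est - p$erev), 2)
})

test_that("chord conductance follows Ohmic division and excludes near-Erev points", {
  gv <- conductance(data.frame(vm = -40, peak_density = -5), erev = 30)
  expect_equal(gv$g, -5 / (-70))
  expect_equal(conductance(data.frame(vm = -40, peak_density = 0), 30)$g, 0)
  expect_warning(
    conductance(data.frame(vm = c(-40, 29.9), peak_density = c(-5, 0)), 30),
    "excluding")
  expect_error(
    suppressWarnings(conductance(data.frame(vm = 29.9, peak_density = 0), 30)),
    "excluded")
})

test_that("Boltzmann fits are exact round trips on noiseless curves", {
  # property over physiological midpoints and slopes
  set.seed(42)
  for (i in 1:20) {
    vh <- runif(1, -60, -35); kk <- runif(1, 2, 8)
    v <- seq(-80, -20, 10)
    f <- fit_activation(data.frame(vm = v, g_norm = boltzmann_act(v, vh, kk)))
    expect_lt(f$residual_sse, 1e-10)
    expect_equal(f$v_half, vh, tolerance = 1e-6)
    expect_equal(f$k, kk, tolerance = 1e-6)
    vh2 <- runif(1, -100, -65); kk2 <- runif(1, 3, 9)
    v2 <- seq(-150, -50, 10)
    f2 <- fit_availability(data.frame(vm = v2,
                                      i_norm = boltzmann_avail(v2, vh2, kk2)))
    expect_lt(f2$residual_sse, 1e-10)
    expect_equal(f2$v_half, vh2, tolerance = 1e-6)
  }
  # midpoint evaluates to one half exactly
  expect_equal(boltzmann_act(-47.4, -47.4, 3.6), 0.5)
  expect_equal(boltzmann_avail(-83.1, -83.1, 6.5), 0.5)
  expect_equal(boltzmann_avail(-1e4, -83.1, 6.5), 1, tolerance = 1e-12)
})

test_that("activation fit stays unbiased under measurement noise", {
  set.seed(7)
  v <- seq(-80, -20, 10)
  truth <- boltzmann_act(v, -47.4, 3.6)
  est <- replicate(200, {
    fit_activation(data.frame(vm = v, g_norm = truth + rnorm(7, 0, 0.02)))$v_half
  })
  expect_lt(abs(mean(est) + 47.4), 0.5)
})

test_that("full IV-family round trip recovers activation parameters", {
  for (p in list(na_channel_params(), na_params_mecp2())) {
    fam <- gen_ina_family(p, "IV_ACTIVATION")
    gv <- suppressWarnings(conductance(peak_iv(fam), erev = p$erev))
    f <- fit_activation(gv)
    expect_equal(f$v_half, p$act_vhalf, tolerance = 2e-3 / abs(p$act_vhalf))
    expect_equal(f$k, p$act_k, tolerance = 2e-3 / p$act_k)
    # G_max reproduced within 2 percent of the generator's conductance scale
    expect_lt(abs(max(gv$g) - p$gmax) / p$gmax, 0.02)
  }
})

test_that("availability family round trip recovers inactivation parameters", {
  p <- na_channel_params()
  av <- availability_curve(gen_ina_family(p, "AVAILABILITY"))
  f <- fit_availability(av)
  expect_equal(f$v_half, p$inact_vhalf, tolerance = 2e-3 / abs(p$inact_vhalf))
  expect_equal(f$k, p$inact_k, tolerance = 2e-3 / p$inact_k)
})

test_that("inactivation time-constant fitting is exact and grid stable", {
  mk_decay <- function(dt) {
    tt <- seq(0, 30, dt)
    trace(ifelse(tt < 10, 0, -30 * exp(-(tt - 10) / 2.6)), dt = dt,
          units = "pA/pF")
  }
  f1 <- fit_inactivation_tau(mk_decay(0.1), step_start_ms = 10, step_dur_ms = 20)
  expect_equal(f1$tau, 2.6, tolerance = 1e-4)
  f2 <- fit_inactivation_tau(mk_decay(0.2), step_start_ms = 10, step_dur_ms = 20)
  expect_lt(abs(f2$tau - f1$tau) / f1$tau, 0.01)  # downsampling robustness
  # constant after the peak: no decay to fit
  flat <- trace(c(rep(0, 100), rep(-30, 200)), dt = 0.1, units = "pA/pF")
  expect_error(fit_inactivation_tau(flat, step_start_ms = 10,
                                    step_dur_ms = 20),
               "no decay")
})

test_that("window current closes at the grid tails and scales with gmax", {
  act <- fit_activation(data.frame(vm = seq(-80, -20, 10),
                                   g_norm = boltzmann_act(seq(-80, -20, 10),
                                                          -47.4, 3.6)))
  inact <- fit_availability(data.frame(vm = seq(-150, -50, 10),
                                       i_norm = boltzmann_avail(seq(-150, -50, 10),
                                                                -83.1, 6.5)))
  w <- window_current(act, inact, gmax = 1, erev = 0)
  expect_equal(w$vm, seq(-120, 20, 2))
  expect_true(all(w$window >= 0))
  expect_lt(w$window[w$vm == -120], 1e-4)
  expect_lt(w$window[w$vm == 20], 1e-4)
  v_pk <- w$vm[which.max(w$window)]
  expect_gt(v_pk, inact$v_half)
  expect_lt(v_pk, act$v_half)
  w2 <- window_current(act, inact, gmax = 2, erev = 0)
  expect_equal(w2$window, 2 * w$window)
})

test_that("recovery fitting is exact on noiseless biexponential ratios", {
  iv <- c(0.1, 0.3, 1, 3.2, 10, 31.6, 100, 316.2, 1000, 3162)
  r <- 1 - (0.85 * exp(-iv / 11) + 0.15 * exp(-iv / 362))
  f <- fit_recovery(data.frame(interval = iv, ratio = r))
  expect_equal(f$tau_fast, 11, tolerance = 1e-6)
  expect_equal(f$tau_slow, 362, tolerance = 1e-6)
  expect_equal(f$a_fast, 0.85, tolerance = 1e-6)
  # full recovery at the longest interval when amplitudes sum to one
  expect_equal(r[length(r)], 1, tolerance = 1e-3)
  expect_error(fit_recovery(data.frame(interval = iv[1:5], ratio = r[1:5])),
               "at least 6")
})

test_that("single-exponential recovery matches a reduced-model oracle", {
  iv <- c(0.1, 0.3, 1, 3.2, 10, 31.6, 100, 316.2, 1000, 3162)
  r <- 1 - 0.9 * exp(-iv / 15)
  # oracle: log-linear regression of the single-exponential model
  sel <- 1 - r > 1e-12
  tau_oracle <- -1 / coef(lm(log(1 - r[sel]) ~ iv[sel]))[[2]]
  f <- suppressWarnings(fit_recovery(data.frame(interval = iv, ratio = r)))
  expect_lt(abs(f$tau_fast - tau_oracle) / tau_oracle, 0.01)
})

test_that("recovery-family round trip recovers both time constants", {
  p <- na_channel_params()
  rr <- recovery_ratios(gen_ina_family(p, "RECOVERY"))
  f <- fit_recovery(rr)
  expect_equal(f$tau_fast, 11.0, tolerance = 1e-4)
  expect_equal(f$tau_slow, 362.0, tolerance = 1e-3)
  expect_equal(f$a_fast, 0.85, tolerance = 1e-4)
})
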