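#' Boltzmann activation and availability functions
#'
#' Steady-state voltage dependence of channel gating. Activation:
#' `a(V) = 1 / (1 + exp((V0.5 - V)/k))`; availability (steady-state
#' inactivation): `h(V) = 1 - 1 / (1 + exp((V0.5 - V)/k))`. `k > 0` in both.
#'
#' @param v membrane potential(s), mV.
#' @param v_half midpoint voltage, mV.
#' @param k slope factor, mV (> 0).
#' @return Numeric vector in `[0, 1]`.
#' @export
boltzmann_act <- function(v, v_half, k) 1 / (1 + exp((v_half - v) / k))

#' @rdname boltzmann_act
#' @export
boltzmann_avail <- function(v, v_half, k) 1 - 1 / (1 + exp((v_half - v) / k))

# Baseline-subtracted samples of one pulse window.
pulse_segment <- function(s, from, to, base) trace_window(s, from, to) - base

# Boxcar-smoothed copy used to locate the peak without chasing single-sample
# noise excursions; NA edges trimmed symmetrically.
boxcar <- function(y, k) {
  if (k <= 1L) return(y)
  ys <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  ys[is.na(ys)] <- y[is.na(ys)]
  ys
}

#' Peak current-voltage relation of a sweep family
#'
#' For every sweep of an IV_ACTIVATION family, subtracts the pre-step
#' baseline (mean over the window before the test step) and measures the
#' peak current within the test step — the extremum of largest magnitude,
#' i.e. the most negative value for inward sodium current. Two measurement
#' modes are available via `peak_measure`:
#'
#' * `"isochronal"` (default): the peak instant is located once, on the
#'   sweep with the largest smoothed excursion, and every sweep is read at
#'   that instant. Because the peak latency of the fast current is
#'   essentially voltage independent, this read is unbiased on sweeps
#'   carrying no current — a per-sweep extremum search would report the
#'   largest noise excursion instead and put a positive floor under the
#'   small-current tail of the I-V relation.
#' * `"search"`: classical per-sweep extremum of the boxcar-smoothed
#'   (`peak_smooth_ms`) current.
#'
#' Sweeps are normalised to pA/pF first (requires the family capacitance
#' when sweeps are in pA).
#'
#' @param family a [sweep_family] with protocol `IV_ACTIVATION`.
#' @param config an [ephys_config()]. Step timing defaults
#'   (`iv_step_start_ms`, `iv_step_dur_ms`) are overridden by family
#'   metadata `step_start_ms` / `step_dur_ms` when present.
#' @return Data frame of IV points: `vm` (mV), `peak_density` (pA/pF).
#' @export
peak_iv <- function(family, config = ephys_config()) {
  stopifnot(inherits(family, "sweep_family"))
  family <- family_density_normalise(family)
  t_on <- family$meta$step_start_ms %||% config$iv_step_start_ms
  t_dur <- family$meta$step_dur_ms %||% config$iv_step_dur_ms
  vm <- sweep_keys(family)
  segs <- lapply(family$sweeps, function(s) {
    t0 <- s$t0
    base <- mean(trace_window(s, t0, t0 + t_on))
    pulse_segment(s, t0 + t_on, t0 + t_on + t_dur, base)
  })
  peak <- measure_peaks(segs, family$sweeps[[1]]$dt, config)
  data.frame(vm = vm, peak_density = peak)[order(vm), ]
}

# Measure one peak per baseline-subtracted segment (segments share a time
# base). Isochronal mode reads all segments at the peak instant of the
# largest one; search mode takes each segment's own smoothed extremum.
measure_peaks <- function(segs, dt, config) {
  k <- max(1L, round(config$peak_smooth_ms / dt))
  sm <- lapply(segs, boxcar, k = k)
  if (identical(config$peak_measure, "isochronal")) {
    ref <- which.max(vapply(sm, function(y) max(abs(y)), numeric(1)))
    i_pk <- which.max(abs(sm[[ref]]))
    # trailing-window mean ending at the peak instant: averages the noise
    # down without reaching past the peak into the decay
    kr <- max(1L, round(config$peak_read_ms / dt))
    vapply(segs, function(y) {
      j <- min(i_pk, length(y))
      mean(y[max(1L, j - kr + 1L):j])
    }, numeric(1), USE.NAMES = FALSE)
  } else if (identical(config$peak_measure, "search")) {
    vapply(sm, function(y) y[which.max(abs(y))], numeric(1),
           USE.NAMES = FALSE)
  } else {
    stop("peak_measure must be 'isochronal' or 'search'")
  }
}

#' Reversal potential from the ascending limb of the I-V relation
#'
#' Fits a least-squares line through the I-V points positive to the voltage
#' of peak (most negative) current — the ascending limb — and extrapolates
#' to the zero-current axis crossing.
#'
#' @param iv data frame from [peak_iv()] (`vm`, `peak_density`).
#' @param config an [ephys_config()]; `erev_min_points` sets the minimum
#'   number of ascending-limb points (default 3).
#' @return Estimated reversal potential (mV).
#' @export
estimate_erev <- function(iv, config = ephys_config()) {
  v_min <- iv$vm[which.min(iv$peak_density)]
  asc <- iv[iv$vm > v_min, , drop = FALSE]
  if (nrow(asc) < config$erev_min_points)
    stop("estimate_erev: extrapolation error: only ", nrow(asc),
         " point(s) positive to the I-V minimum (need >= ",
         config$erev_min_points, ")")
  fit <- lm(peak_density ~ vm, data = asc)
  b <- coef(fit)
  unname(-b[1] / b[2])
}

#' Chord conductance from an I-V relation
#'
#' `G = I / (Vm - Erev)` per point. Points within `erev_exclusion_mv`
#' (default 1 mV) of the reversal potential are excluded with a warning,
#' since the driving force there is too small for a stable quotient.
#'
#' @param iv data frame from [peak_iv()].
#' @param erev reversal potential (mV), e.g. from [estimate_erev()].
#' @param config an [ephys_config()].
#' @return Data frame `vm`, `g` (pA/pF per mV).
#' @export
conductance <- function(iv, erev, config = ephys_config()) {
  near <- abs(iv$vm - erev) < config$erev_exclusion_mv
  if (any(near)) {
    warning("conductance: excluding ", sum(near),
            " point(s) within ", config$erev_exclusion_mv, " mV of Erev")
    iv <- iv[!near, , drop = FALSE]
  }
  if (!nrow(iv))
    stop("conductance: all points excluded near the reversal potential")
  data.frame(vm = iv$vm, g = iv$peak_density / (iv$vm - erev))
}

boltzmann_start <- function(v, y, increasing) {
  # midpoint from the half-maximum crossing, slope from the 25/75% levels
  o <- order(v)
  v <- v[o]; y <- y[o]
  lev <- function(p) {
    cross <- approx(if (increasing) y else rev(y),
                    if (increasing) v else rev(v),
                    xout = p, ties = "ordered")$y
    if (is.na(cross)) NA_real_ else cross
  }
  v50 <- lev(0.5); v25 <- lev(0.25); v75 <- lev(0.75)
  k0 <- if (!is.na(v25) && !is.na(v75)) abs(v75 - v25) / 2.2 else NA_real_
  list(v_half = if (is.na(v50)) stats::median(v) else v50,
       k = if (is.na(k0) || k0 <= 0) diff(range(v)) / 10 else k0)
}

new_boltzmann_fit <- function(fit, kind, scale) {
  p <- coef(fit)
  structure(
    list(v_half = unname(p["v_half"]), k = unname(p["k"]),
         gmax_or_imax = scale,
         residual_sse = sum(stats::resid(fit)^2),
         converged = fit$convInfo$isConv %||% TRUE,
         kind = kind, fit = fit),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit: V0.5 = %.3f mV, k = %.3f mV (SSE %.3g)\n",
              x$kind, x$v_half, x$k, x$residual_sse))
  invisible(x)
}

#' Fit the voltage dependence of activation
#'
#' Normalises conductance by `G_max` (the maximum conductance observed over
#' the protocol, not a fitted parameter) and fits the Boltzmann activation
#' function by unweighted nonlinear least squares over the configured
#' voltage range (default -80 to -20 mV). Initial guesses take the midpoint
#' from the interpolated half-maximum crossing and the slope from the
#' quartile levels.
#'
#' @param gv data frame `vm`, `g` from [conductance()], or `vm`, `g_norm`
#'   already normalised to `G/G_max`.
#' @param config an [ephys_config()].
#' @return A `boltzmann_fit` (kind `"activation"`); `gmax_or_imax` holds the
#'   normalising `G_max`.
#' @export
fit_activation <- function(gv, config = ephys_config()) {
  if ("g_norm" %in% names(gv)) {
    gmax <- 1
    dat <- data.frame(vm = gv$vm, y = gv$g_norm)
  } else {
    gmax <- max(gv$g)
    dat <- data.frame(vm = gv$vm, y = gv$g / gmax)
  }
  dat <- dat[dat$vm >= config$act_fit_min_mv & dat$vm <= config$act_fit_max_mv, ]
  if (nrow(dat) < 5L)
    stop("fit_activation: need at least 5 points in [",
         config$act_fit_min_mv, ", ", config$act_fit_max_mv, "] mV")
  st <- boltzmann_start(dat$vm, dat$y, increasing = TRUE)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + exp((v_half - vm) / k)), data = dat,
                      start = st, lower = c(v_half = -Inf, k = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = config$fit_tol,
                        ptol = config$fit_tol)),
    error = function(e) stop("fit_activation: fit error (starts v_half=",
                             round(st$v_half, 2), ", k=", round(st$k, 2),
                             "): ", conditionMessage(e)))
  new_boltzmann_fit(fit, "activation", gmax)
}

#' Fit the voltage dependence of availability (inactivation)
#'
#' Fits `I/I_max = 1 - 1/(1 + exp((V0.5 - V)/k))` to test-pulse currents
#' normalised to the maximal current observed during the protocol, by
#' unweighted nonlinear least squares over the configured conditioning
#' voltage range (default -150 to -50 mV).
#'
#' @param inact data frame with columns `vm` (conditioning voltage, mV) and
#'   `i_norm` (I/I_max, in `[0, 1]` up to noise).
#' @param config an [ephys_config()].
#' @return A `boltzmann_fit` (kind `"availability"`).
#' @export
fit_availability <- function(inact, config = ephys_config()) {
  dat <- data.frame(vm = inact$vm, y = inact$i_norm)
  if (any(dat$y < -0.05 | dat$y > 1.1))
    stop("fit_availability: i_norm values outside [0, 1] tolerance band")
  dat <- dat[dat$vm >= config$avail_fit_min_mv &
               dat$vm <= config$avail_fit_max_mv, ]
  if (nrow(dat) < 5L)
    stop("fit_availability: need at least 5 points in [",
         config$avail_fit_min_mv, ", ", config$avail_fit_max_mv, "] mV")
  st <- boltzmann_start(dat$vm, dat$y, increasing = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - 1 / (1 + exp((v_half - vm) / k)), data = dat,
                      start = st, lower = c(v_half = -Inf, k = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = config$fit_tol,
                        ptol = config$fit_tol)),
    error = function(e) stop("fit_availability: fit error (starts v_half=",
                             round(st$v_half, 2), ", k=", round(st$k, 2),
                             "): ", conditionMessage(e)))
  new_boltzmann_fit(fit, "availability", 1)
}

#' Inactivation time constant of a single sweep
#'
#' Single-exponential least-squares fit of the decaying phase of the current
#' elicited by a test step: `I(t) = A exp(-(t - t_fit)/tau) + C`, fitted
#' from shortly after the current peak (`tau_fit_start_offset_ms`, default
#' 0.2 ms) to the time at which the magnitude of the baseline-subtracted
#' current has fallen to `tau_fit_end_frac` (default 5 percent) of the peak,
#' capped at the end of the step.
#'
#' @param sweep a current [trace] containing a resolvable peak followed by
#'   decay (baseline before the step per the family/config step timing).
#' @param config an [ephys_config()].
#' @param step_start_ms,step_dur_ms test-step timing relative to the sweep
#'   start; defaults from the config.
#' @return List of class `tau_fit`: `tau` (ms), `a`, `c0`, `residual_sse`.
#' @export
fit_inactivation_tau <- function(sweep, config = ephys_config(),
                                 step_start_ms = config$iv_step_start_ms,
                                 step_dur_ms = config$iv_step_dur_ms) {
  stopifnot(inherits(sweep, "trace"))
  tt <- trace_times(sweep) - sweep$t0
  base <- mean(sweep$samples[tt <= step_start_ms])
  in_step <- tt >= step_start_ms & tt <= step_start_ms + step_dur_ms
  y <- sweep$samples[in_step] - base
  ts <- tt[in_step]
  ip <- which.max(abs(y))
  if (ip >= length(y) - 5L)
    stop("fit_inactivation_tau: fit error: current peak at the sweep end, ",
         "no decay to fit")
  peak <- y[ip]
  after <- seq(ip, length(y))
  below <- after[abs(y[after]) <= config$tau_fit_end_frac * abs(peak)]
  i_end <- if (length(below)) below[1] else length(y)
  sel <- ts >= ts[ip] + config$tau_fit_start_offset_ms & ts <= ts[i_end]
  dat <- data.frame(t = ts[sel] - ts[sel][1], y = y[sel])
  if (nrow(dat) < 5L)
    stop("fit_inactivation_tau: fit error: too few samples in the decay window")
  c0 <- dat$y[nrow(dat)]
  a0 <- dat$y[1] - c0
  if (abs(a0) < 1e-12 || sd(dat$y) < 1e-12)
    stop("fit_inactivation_tau: fit error: no decay after the peak")
  tau0 <- max((dat$t[nrow(dat)] - dat$t[1]) / 3, sweep$dt)
  fit <- minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c0,
                           data = dat,
                           start = list(a = a0, tau = tau0, c0 = c0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = config$fit_tol,
                             ptol = config$fit_tol))
  p <- coef(fit)
  if (p[["tau"]] > 10 * step_dur_ms)
    warning("fit_inactivation_tau: fitted tau exceeds the step duration ",
            "tenfold; decay unresolved")
  structure(list(tau = unname(p["tau"]), a = unname(p["a"]),
                 c0 = unname(p["c0"]),
                 residual_sse = sum(stats::resid(fit)^2), fit = fit),
            class = "tau_fit")
}

#' Steady-state window current
#'
#' Evaluates the activation and availability Boltzmann variables on a
#' voltage grid (default -120 to +20 mV in 2 mV steps), multiplies their
#' product by the maximal conductance and the driving force `(V - Erev)`,
#' and reports the magnitude (the inward negative sign is removed for
#' display, as is conventional for window-current plots).
#'
#' @param act `boltzmann_fit` of kind `"activation"`.
#' @param inact `boltzmann_fit` of kind `"availability"`.
#' @param gmax maximal conductance (pA/pF per mV), > 0.
#' @param erev reversal potential (mV).
#' @param config an [ephys_config()].
#' @return Data frame of class `window_curve`: `vm`, `window` (magnitude,
#'   pA/pF) and `window_signed`.
#' @export
window_current <- function(act, inact, gmax, erev, config = ephys_config()) {
  stopifnot(inherits(act, "boltzmann_fit"), inherits(inact, "boltzmann_fit"))
  if (!isTRUE(act$converged) || !isTRUE(inact$converged))
    stop("window_current: both Boltzmann fits must have converged")
  if (gmax <= 0) stop("window_current: gmax must be > 0")
  vm <- seq(config$window_grid_min_mv, config$window_grid_max_mv,
            by = config$window_grid_step_mv)
  a <- boltzmann_act(vm, act$v_half, act$k)
  h <- boltzmann_avail(vm, inact$v_half, inact$k)
  w <- a * h * gmax * (vm - erev)
  out <- data.frame(vm = vm, window = abs(w), window_signed = w)
  class(out) <- c("window_curve", class(out))
  out
}

#' P2/P1 recovery ratios from a RECOVERY sweep family
#'
#' Each sweep of a recovery family contains a 1 s conditioning pulse (P1)
#' followed, after the interpulse interval given by the sweep key, by a
#' 40 ms test pulse (P2). Peak currents (baseline-subtracted magnitudes) are
#' measured in both pulse windows and the ratio P2/P1 reported per interval.
#'
#' @param family a [sweep_family] with protocol `RECOVERY`. Pulse timing
#'   defaults (`recovery_baseline_ms`, `recovery_p1_ms`, `recovery_p2_ms`)
#'   are overridden by family metadata when present.
#' @param config an [ephys_config()].
#' @return Data frame `interval` (ms), `ratio`.
#' @export
recovery_ratios <- function(family, config = ephys_config()) {
  stopifnot(inherits(family, "sweep_family"))
  family <- family_density_normalise(family)
  b <- family$meta$baseline_ms %||% config$recovery_baseline_ms
  p1 <- family$meta$p1_ms %||% config$recovery_p1_ms
  p2 <- family$meta$p2_ms %||% config$recovery_p2_ms
  iv <- sweep_keys(family)
  dt <- family$sweeps[[1]]$dt
  bases <- vapply(family$sweeps, function(s)
    mean(trace_window(s, s$t0, s$t0 + b)), numeric(1))
  seg_p1 <- lapply(seq_along(iv), function(i) {
    s <- family$sweeps[[i]]
    pulse_segment(s, s$t0 + b, s$t0 + b + p1, bases[i])
  })
  seg_p2 <- lapply(seq_along(iv), function(i) {
    s <- family$sweeps[[i]]
    pulse_segment(s, s$t0 + b + p1 + iv[i], s$t0 + b + p1 + iv[i] + p2,
                  bases[i])
  })
  p1_pk <- oriented_magnitude(measure_peaks(seg_p1, dt, config))
  p2_pk <- oriented_magnitude(measure_peaks(seg_p2, dt, config))
  data.frame(interval = iv, ratio = p2_pk / p1_pk)[order(iv), ]
}

# Convert signed peak reads sharing a common current direction into
# magnitudes, orienting by the sign of the largest read. Unlike abs(), this
# keeps zero-current reads symmetrically distributed around zero.
oriented_magnitude <- function(reads) {
  s <- sign(reads[which.max(abs(reads))])
  if (s == 0) s <- 1
  s * reads
}

#' Biexponential fit of recovery from inactivation
#'
#' Fits `P2/P1(t) = 1 - (A_f exp(-t/tau_fast) + A_s exp(-t/tau_slow))` to
#' paired-pulse recovery ratios by nonlinear least squares. The time
#' constants are fitted on a log scale with `tau_slow` parameterised as
#' `tau_fast` plus a positive increment, which enforces positivity and the
#' `tau_fast < tau_slow` ordering. Initial guesses come from log-linear
#' regression of `1 - ratio` on the slow (late intervals) and fast (early
#' intervals, slow component subtracted) decades.
#'
#' @param ratios data frame `interval` (ms), `ratio` — e.g. from
#'   [recovery_ratios()]; at least 6 intervals.
#' @param config an [ephys_config()].
#' @return List of class `recovery_fit`: `tau_fast`, `tau_slow` (ms),
#'   `a_fast`, `a_slow`, `residual_sse`.
#' @export
fit_recovery <- function(ratios, config = ephys_config()) {
  dat <- data.frame(t = ratios$interval, r = ratios$ratio)
  dat <- dat[order(dat$t), ]
  if (nrow(dat) < 6L)
    stop("fit_recovery: need at least 6 interpulse intervals")
  if (any(dat$r < -0.05 | dat$r > 1.1))
    stop("fit_recovery: ratios outside [0, 1] tolerance band")

  st <- recovery_start(dat)
  do_fit <- function(start, ctrl) minpack.lm::nlsLM(
    r ~ 1 - (af * exp(-t / exp(ltf)) + as * exp(-t / (exp(ltf) + exp(lds)))),
    data = dat, start = start,
    lower = c(af = 0, as = 0, ltf = log(1e-3), lds = log(1e-3)),
    control = ctrl)
  tight <- minpack.lm::nls.lm.control(maxiter = 500, ftol = config$fit_tol,
                                      ptol = config$fit_tol)
  loose <- minpack.lm::nls.lm.control(maxiter = 500)
  fallback <- list(af = 0.8, as = 0.15, ltf = log(10), lds = log(300))
  fit <- tryCatch(do_fit(st, tight), error = function(e)
    tryCatch(do_fit(st, loose), error = function(e2)
      tryCatch(do_fit(fallback, loose), error = function(e3)
        stop("fit_recovery: fit error (starts af=", round(st$af, 2),
             ", tau_f=", round(exp(st$ltf), 1), "): ",
             conditionMessage(e3)))))
  p <- coef(fit)
  tau_f <- unname(exp(p["ltf"]))
  tau_s <- unname(exp(p["ltf"]) + exp(p["lds"]))
  a_f <- unname(p["af"]); a_s <- unname(p["as"])
  if (a_f < 1e-6 && a_s > 1e-6) {
    # single-component recovery landed in the slow slot; relabel
    warning("fit_recovery: fast amplitude vanished; reporting the single ",
            "resolved component as the fast one")
    tau_f <- tau_s; a_f <- a_s
    tau_s <- Inf; a_s <- 0
  }
  structure(
    list(tau_fast = tau_f, tau_slow = tau_s, a_fast = a_f, a_slow = a_s,
         residual_sse = sum(stats::resid(fit)^2), fit = fit),
    class = "recovery_fit"
  )
}

recovery_start <- function(dat) {
  y <- pmax(1 - dat$r, 0)
  late <- dat$t >= stats::median(dat$t) & y > 1e-8
  ts0 <- 300; as0 <- 0.15
  if (sum(late) >= 2) {
    sl <- lm(log(y[late]) ~ dat$t[late])
    if (is.finite(coef(sl)[2]) && coef(sl)[2] < 0) {
      ts0 <- min(max(-1 / coef(sl)[2], 1), 1e5)
      as0 <- min(max(exp(coef(sl)[1]), 0.01), 1)
    }
  }
  yf <- y - as0 * exp(-dat$t / ts0)
  early <- dat$t < stats::median(dat$t) & yf > 1e-8
  tf0 <- ts0 / 20; af0 <- 0.8
  if (sum(early) >= 2) {
    fl <- lm(log(yf[early]) ~ dat$t[early])
    if (is.finite(coef(fl)[2]) && coef(fl)[2] < 0) {
      tf0 <- min(max(-1 / coef(fl)[2], 0.01), ts0 * 0.9)
      af0 <- min(max(exp(coef(fl)[1]), 0.01), 1.2)
    }
  }
  list(af = af0, as = as0, ltf = log(tf0), lds = log(max(ts0 - tf0, 1e-3)))
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "Recovery fit: tau_fast = %.3f ms (A_f %.3f), tau_slow = %.1f ms (A_s %.3f)\n",
    x$tau_fast, x$a_fast, x$tau_slow, x$a_slow))
  invisible(x)
}

#' Full fast-current analysis of an I-V family
#'
#' Convenience pipeline: peak I-V, reversal-potential extrapolation, chord
#' conductance, Boltzmann activation fit, and the inactivation time constant
#' of the sweep at a chosen potential.
#'
#' @param family an `IV_ACTIVATION` [sweep_family].
#' @param tau_at_mv potential (mV) whose sweep is used for the inactivation
#'   time-constant fit; `NULL` to skip.
#' @param config an [ephys_config()].
#' @return List: `iv`, `erev`, `gv`, `activation` (`boltzmann_fit`),
#'   `gmax`, `tau_inact` (`tau_fit` or `NULL`).
#' @export
analyse_iv_family <- function(family, tau_at_mv = -40,
                              config = ephys_config()) {
  iv <- peak_iv(family, config)
  erev <- estimate_erev(iv, config)
  gv <- conductance(iv, erev, config)
  act <- fit_activation(gv, config)
  tau <- NULL
  if (!is.null(tau_at_mv)) {
    key <- names(family$sweeps)[match(tau_at_mv, sweep_keys(family))]
    if (!is.na(key)) {
      fam_n <- family_density_normalise(family)
      tau <- fit_inactivation_tau(
        fam_n$sweeps[[key]], config,
        step_start_ms = family$meta$step_start_ms %||% config$iv_step_start_ms,
        step_dur_ms = family$meta$step_dur_ms %||% config$iv_step_dur_ms)
    }
  }
  list(iv = iv, erev = erev, gv = gv, activation = act,
       gmax = max(gv$g), tau_inact = tau)
}

#' Availability curve from an AVAILABILITY sweep family
#'
#' Measures the peak test-pulse current of every sweep (baseline-subtracted
#' magnitude), normalises by the maximal current observed during the
#' protocol, and returns the `I/I_max` versus conditioning-voltage relation
#' ready for [fit_availability()].
#'
#' @param family a [sweep_family] with protocol `AVAILABILITY`; keys are the
#'   conditioning voltages (mV).
#' @param config an [ephys_config()]. Test-pulse timing defaults
#'   (`iv_step_start_ms` for the pulse onset, `recovery_p2_ms` for its
#'   duration) are overridden by family metadata when present.
#' @return Data frame `vm`, `i_norm`.
#' @export
availability_curve <- function(family, config = ephys_config()) {
  stopifnot(inherits(family, "sweep_family"))
  family <- family_density_normalise(family)
  t_on <- family$meta$step_start_ms %||% config$iv_step_start_ms
  t_dur <- family$meta$step_dur_ms %||% config$recovery_p2_ms
  vm <- sweep_keys(family)
  segs <- lapply(family$sweeps, function(s) {
    t0 <- s$t0
    base <- mean(trace_window(s, t0, t0 + t_on))
    pulse_segment(s, t0 + t_on, t0 + t_on + t_dur, base)
  })
  pk <- oriented_magnitude(measure_peaks(segs, family$sweeps[[1]]$dt, config))
  data.frame(vm = vm, i_norm = pk / max(pk))[order(vm), ]
}
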