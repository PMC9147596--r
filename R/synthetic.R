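with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sodium-channel model parameters
#'
#' Parameter set for the synthetic voltage-clamp current generator. The
#' model is a conductance-based description with instantaneous steady-state
#' activation (the upstroke is smoothed by a short rise filter),
#' single-exponential voltage-dependent inactivation, a voltage-independent
#' non-inactivating fraction `f_late` standing in for the persistent (late)
#' current, and biexponential recovery from inactivation. Defaults are
#' wild-type murine ventricular values; [na_params_mecp2()] gives the
#' Mecp2-null counterpart.
#'
#' @param gmax maximal conductance (pA/pF per mV).
#' @param erev reversal potential (mV); 0 under symmetrical 5 mM Na+.
#' @param act_vhalf,act_k activation midpoint and slope (mV).
#' @param inact_vhalf,inact_k availability midpoint and slope (mV).
#' @param tau_at_minus40 inactivation time constant at -40 mV (ms).
#' @param tau_efold_mv e-fold voltage slope of the inactivation time
#'   constant (mV per e-fold decrease with depolarization).
#' @param f_late non-inactivating fraction of the conductance, in `[0, 0.05]`.
#' @param tau_fast_rec,tau_slow_rec recovery time constants (ms),
#'   `tau_fast_rec < tau_slow_rec`.
#' @param a_fast_rec fraction of recovery carried by the fast component.
#' @param rise_tau_ms activation rise filter time constant (ms).
#' @return List of class `na_channel_params`.
#' @export
na_channel_params <- function(gmax = 1, erev = 0,
                              act_vhalf = -47.4, act_k = 3.6,
                              inact_vhalf = -83.1, inact_k = 6.5,
                              tau_at_minus40 = 2.6, tau_efold_mv = 25,
                              f_late = 0.005,
                              tau_fast_rec = 11.0, tau_slow_rec = 362.0,
                              a_fast_rec = 0.85, rise_tau_ms = 0.3) {
  if (act_k <= 0 || inact_k <= 0)
    stop("na_channel_params: slope factors must be > 0")
  if (f_late < 0 || f_late >= 1)
    stop("na_channel_params: f_late must be in [0, 1)")
  if (tau_fast_rec >= tau_slow_rec)
    stop("na_channel_params: tau_fast_rec must be < tau_slow_rec")
  structure(as.list(environment()), class = "na_channel_params")
}

#' @rdname na_channel_params
#' @param ... overrides passed to [na_channel_params()] on top of the
#'   Mecp2-null defaults (reduced conductance, steeper availability, slower
#'   inactivation at -40 mV, faster fast recovery, threefold late fraction).
#' @export
na_params_mecp2 <- function(...) {
  defaults <- list(gmax = 0.75, act_vhalf = -45.4, act_k = 3.9,
                   inact_vhalf = -79.6, inact_k = 5.1,
                   tau_at_minus40 = 3.1, f_late = 0.015,
                   tau_fast_rec = 8.6, tau_slow_rec = 311.5,
                   a_fast_rec = 0.85)
  do.call(na_channel_params, modifyList(defaults, list(...)))
}

tau_inact_of <- function(p, v) p$tau_at_minus40 * exp(-(v + 40) / p$tau_efold_mv)

# Current density (pA/pF) during a step to `v`, at times `t` (ms) from step
# onset, with full availability. The inactivation clock starts once the
# activation rise is complete (7 rise time constants), so the peak carries a
# voltage-independent attenuation (1 - e^-7) and peak ratios across voltages
# reproduce the steady-state activation curve exactly.
step_current <- function(p, v, t) {
  a <- boltzmann_act(v, p$act_vhalf, p$act_k)
  t_act <- 7 * p$rise_tau_ms
  rise <- if (p$rise_tau_ms > 0) 1 - exp(-t / p$rise_tau_ms) else 1
  decay <- (1 - p$f_late) * exp(-pmax(0, t - t_act) / tau_inact_of(p, v)) +
    p$f_late
  p$gmax * a * (v - p$erev) * rise * decay
}

#' Generate a synthetic voltage-clamp sweep family
#'
#' Produces sweep families for the four clamp protocols analysed by the
#' fast- and late-current modules, with known ground-truth parameters:
#'
#' * `IV_ACTIVATION`: 250 ms steps from -80 to 0 mV in 10 mV increments
#'   (after a pre-pulse restoring full availability).
#' * `AVAILABILITY`: 1.5 s conditioning pulses from -150 to -50 mV in 10 mV
#'   increments, each followed by a 40 ms test command to -40 mV; only the
#'   test-command current is emitted, scaled by the steady-state
#'   availability at the conditioning voltage.
#' * `RECOVERY`: paired pulses to -40 mV (P1 1 s, P2 40 ms) at interpulse
#'   intervals 0.1, 0.3, 1, 3.2, 10, 31.6, 100, 316.2, 1000 and 3162 ms;
#'   the P2 amplitude follows the biexponential recovery time course.
#' * `LATE_STEP`: a 1 s command to -20 mV from -120 mV holding; the
#'   sustained component is the non-inactivating fraction `f_late`.
#'
#' Additive Gaussian noise of standard deviation `noise_sd` (pA/pF) is
#' applied per sample; output is deterministic for a fixed seed.
#'
#' @param params a [na_channel_params()].
#' @param protocol protocol name (above).
#' @param noise_sd additive noise SD (pA/pF).
#' @param dt sampling interval (ms).
#' @param seed integer seed; `NULL` leaves the RNG state untouched (only
#'   valid with `noise_sd = 0` for reproducibility).
#' @param config an [ephys_config()] (step timing).
#' @return A [sweep_family] in pA/pF with step timing in its metadata.
#' @export
gen_ina_family <- function(params, protocol, noise_sd = 0, dt = 0.1,
                           seed = NULL, config = ephys_config()) {
  stopifnot(inherits(params, "na_channel_params"))
  protocol <- match.arg(protocol, c("IV_ACTIVATION", "AVAILABILITY",
                                    "RECOVERY", "LATE_STEP"))
  with_seed(seed, {
    mk <- function(samples, label) {
      if (noise_sd > 0) samples <- samples + rnorm(length(samples), 0, noise_sd)
      trace(samples, dt = dt, t0 = 0, units = "pA/pF", label = label)
    }
    fam <- switch(protocol,
      IV_ACTIVATION = {
        b <- config$iv_step_start_ms; dur <- config$iv_step_dur_ms
        volts <- seq(-80, 0, by = 10)
        sweeps <- lapply(volts, function(v) {
          tt <- seq(0, b + dur, by = dt)
          i <- ifelse(tt < b, 0, step_current(params, v, tt - b))
          mk(i, sprintf("step to %g mV", v))
        })
        names(sweeps) <- volts
        sweep_family(sweeps, "IV_ACTIVATION",
                     meta = list(step_start_ms = b, step_dur_ms = dur))
      },
      AVAILABILITY = {
        b <- config$iv_step_start_ms; dur <- config$recovery_p2_ms
        vconds <- seq(-150, -50, by = 10)
        v_test <- -40
        sweeps <- lapply(vconds, function(vc) {
          h <- boltzmann_avail(vc, params$inact_vhalf, params$inact_k)
          tt <- seq(0, b + dur, by = dt)
          i <- ifelse(tt < b, 0, h * step_current(params, v_test, tt - b))
          mk(i, sprintf("conditioned at %g mV", vc))
        })
        names(sweeps) <- vconds
        sweep_family(sweeps, "AVAILABILITY",
                     meta = list(step_start_ms = b, step_dur_ms = dur))
      },
      RECOVERY = {
        b <- config$recovery_baseline_ms
        p1 <- config$recovery_p1_ms; p2 <- config$recovery_p2_ms
        intervals <- c(0.1, 0.3, 1, 3.2, 10, 31.6, 100, 316.2, 1000, 3162)
        v_test <- -40
        af <- params$a_fast_rec; as_ <- 1 - af
        sweeps <- lapply(intervals, function(gap) {
          rec <- 1 - (af * exp(-gap / params$tau_fast_rec) +
                        as_ * exp(-gap / params$tau_slow_rec))
          tt <- seq(0, b + p1 + gap + p2, by = dt)
          i <- numeric(length(tt))
          in_p1 <- tt >= b & tt < b + p1
          in_p2 <- tt >= b + p1 + gap
          i[in_p1] <- step_current(params, v_test, tt[in_p1] - b)
          i[in_p2] <- rec * step_current(params, v_test, tt[in_p2] - (b + p1 + gap))
          mk(i, sprintf("interval %g ms", gap))
        })
        names(sweeps) <- intervals
        sweep_family(sweeps, "RECOVERY",
                     meta = list(baseline_ms = b, p1_ms = p1, p2_ms = p2))
      },
      LATE_STEP = {
        b <- 50; dur <- 1000
        v <- -20
        tt <- seq(0, b + dur + 50, by = dt)
        i <- ifelse(tt < b, 0, step_current(params, v, tt - b))
        sweeps <- setNames(list(mk(i, "1 s step to -20 mV")), v)
        sweep_family(sweeps, "LATE_STEP",
                     meta = list(step_start_ms = b, step_dur_ms = dur))
      })
    fam
  })
}

#' Action-potential shape parameters
#'
#' Targets for the synthetic AP-train generator: resting and peak
#' potentials, upstroke rise time constant, the four repolarization targets
#' APD25/50/75/90 (ms, measured from the maximum-upstroke-velocity instant)
#' and per-beat APD90 jitter. Defaults are the wild-type murine ventricular
#' values.
#'
#' @param rmp resting membrane potential (mV).
#' @param peak peak (overshoot) potential (mV).
#' @param upstroke_tau_ms sigmoidal upstroke time constant (ms).
#' @param apd25,apd50,apd75,apd90 repolarization targets (ms), increasing.
#' @param jitter_sd_ms SD of per-beat Gaussian APD90 jitter (ms).
#' @param n_beats number of beats in the train.
#' @param cycle_ms pacing cycle length (ms); 1000 = 1 Hz.
#' @param stim_offset_ms time of the first stimulus (ms).
#' @param seed integer seed for the jitter.
#' @return List of class `ap_shape_params`.
#' @export
ap_shape_params <- function(rmp = -72.2, peak = 48.0, upstroke_tau_ms = 0.1,
                            apd25 = 2.1, apd50 = 6.7, apd75 = 71.1,
                            apd90 = 115.6, jitter_sd_ms = 0, n_beats = 15,
                            cycle_ms = 1000, stim_offset_ms = 50,
                            seed = NULL) {
  if (is.unsorted(c(apd25, apd50, apd75, apd90), strictly = TRUE))
    stop("ap_shape_params: solver error: APD targets must satisfy ",
         "apd25 < apd50 < apd75 < apd90")
  if (jitter_sd_ms < 0) stop("ap_shape_params: jitter sd must be >= 0")
  if (8 * upstroke_tau_ms >= apd25)
    stop("ap_shape_params: solver error: upstroke (8 tau = ",
         8 * upstroke_tau_ms, " ms) must complete before apd25")
  structure(as.list(environment()), class = "ap_shape_params")
}

# monotone repolarization curve r(s): fraction of amplitude remaining above
# RMP at time s after the maximum-dV/dt instant; passes through the APD
# anchors (r = 1 - x/100 at s = apd_x).
repol_curve <- function(p) {
  s0 <- 8 * p$upstroke_tau_ms
  d <- p$apd90 - p$apd75
  s_anchor <- c(s0, p$apd25, p$apd50, p$apd75, p$apd90,
                p$apd90 + 0.5 * d, p$apd90 + 1.5 * d)
  r_anchor <- c(1, 0.75, 0.5, 0.25, 0.1, 0.03, 0)
  f <- splinefun(s_anchor, r_anchor, method = "monoH.FC")
  s_max <- s_anchor[length(s_anchor)]
  function(s) {
    r <- numeric(length(s))
    r[s <= s0] <- 1
    mid <- s > s0 & s < s_max
    r[mid] <- pmax(f(s[mid]), 0)
    r  # 0 beyond the last anchor
  }
}

#' Generate a paced action-potential train
#'
#' Builds a membrane-potential trace of `n_beats` APs at the requested cycle
#' length. Each beat is a sigmoidal upstroke multiplied by a monotone cubic
#' repolarization curve anchored so that the measured APD25/50/75/90 of a
#' noiseless beat land within 0.5 ms of the targets. Per-beat APD90 jitter
#' (Gaussian, seeded) shifts the APD90 anchor of each beat, leaving the
#' earlier anchors fixed.
#'
#' @param params an [ap_shape_params()].
#' @param dt sampling interval (ms).
#' @return List: `trace` (mV), `stim_times` (ms).
#' @export
gen_ap_train <- function(params, dt = 0.1) {
  stopifnot(inherits(params, "ap_shape_params"))
  p <- params
  amp <- p$peak - p$rmp
  stim_times <- p$stim_offset_ms + (seq_len(p$n_beats) - 1) * p$cycle_ms
  total_ms <- p$stim_offset_ms + p$n_beats * p$cycle_ms
  tt <- seq(0, total_ms, by = dt)
  v <- rep(p$rmp, length(tt))
  jitter <- with_seed(p$seed, rnorm(p$n_beats, 0, p$jitter_sd_ms))
  if (p$jitter_sd_ms == 0) jitter <- rep(0, p$n_beats)
  for (b in seq_len(p$n_beats)) {
    apd90_b <- max(p$apd90 + jitter[b], p$apd75 + 0.1 * (p$apd90 - p$apd75))
    pb <- p; pb$apd90 <- apd90_b
    r <- repol_curve(pb)
    cc <- stim_times[b] + 1.0  # 1 ms latency to the upstroke midpoint
    sel <- tt >= stim_times[b] - 1e-9 &
      tt < stim_times[b] + p$cycle_ms - 1e-9
    s <- tt[sel] - cc
    sig <- 1 / (1 + exp(-s / p$upstroke_tau_ms))
    v[sel] <- p$rmp + amp * sig * r(s)
  }
  list(trace = trace(v, dt = dt, t0 = 0, units = "mV", label = "AP train"),
       stim_times = stim_times)
}

#' ECG waveform parameters
#'
#' Targets for the synthetic ECG generator: interval structure (RR, PR,
#' QRS, QT in ms) and wave amplitudes (mV). Defaults reproduce the
#' wild-type murine surface-ECG means.
#'
#' @param rr,pr,qrs,qt interval targets (ms); requires `qrs < qt < rr`.
#' @param r_amp,t_amp,p_amp wave amplitudes (mV).
#' @param noise_burst_rate_per_s expected rate of breathing-noise bursts
#'   (per second); 0 disables them.
#' @param seed integer seed for the noise bursts.
#' @return List of class `ecg_shape_params`.
#' @export
ecg_shape_params <- function(rr = 130.7, pr = 38.4, qrs = 10.8, qt = 51.9,
                             r_amp = 1.0, t_amp = 0.2, p_amp = 0.12,
                             noise_burst_rate_per_s = 0, seed = NULL) {
  if (!(qrs < qt && qt < rr))
    stop("ecg_shape_params: parameter error: need qrs < qt < rr")
  structure(as.list(environment()), class = "ecg_shape_params")
}

gauss_wave <- function(tt, centre, sd, amp) amp * exp(-((tt - centre)^2) / (2 * sd^2))

#' Generate a synthetic ECG trace with ground-truth annotations
#'
#' Synthesises a P-QRS-T complex train as parameterised Gaussian bumps on an
#' isoelectric baseline. The emitted annotations are exactly the generator
#' fiducials (QRS onset, R peak, QRS end, QT end), so downstream interval
#' metrics have a known truth. Optional breathing-noise bursts (50 ms of
#' high-frequency interference) are added at a Poisson rate and reported as
#' noise intervals.
#'
#' @param params an [ecg_shape_params()].
#' @param duration_ms trace duration (ms).
#' @param dt sampling interval (ms).
#' @return List: `trace` (mV), `annotation` (an [ecg_annotation()]), and
#'   `noise` (data frame of burst intervals).
#' @export
gen_ecg <- function(params, duration_ms = 2000, dt = 0.1) {
  stopifnot(inherits(params, "ecg_shape_params"))
  p <- params
  tt <- seq(0, duration_ms, by = dt)
  v <- numeric(length(tt))
  qrs_on <- seq(30, duration_ms - p$qt - 20, by = p$rr)
  if (length(qrs_on) < 1L) stop("gen_ecg: duration too short for one complex")
  fid <- data.frame(
    complex_id = seq_along(qrs_on),
    qrs_on_ms = qrs_on,
    r_peak_ms = qrs_on + 0.35 * p$qrs,
    qrs_end_ms = qrs_on + p$qrs,
    qt_end_ms = qrs_on + p$qt
  )
  jt <- p$qt - p$qrs
  for (i in seq_len(nrow(fid))) {
    v <- v +
      gauss_wave(tt, fid$r_peak_ms[i], p$qrs / 7, p$r_amp) +
      gauss_wave(tt, fid$qrs_on_ms[i] + 0.1 * p$qrs, p$qrs / 10, -0.15 * p$r_amp) +
      gauss_wave(tt, fid$qrs_end_ms[i] - 0.1 * p$qrs, p$qrs / 10, -0.2 * p$r_amp) +
      gauss_wave(tt, fid$qt_end_ms[i] - 0.3 * jt, jt / 5, p$t_amp) +
      gauss_wave(tt, fid$qrs_on_ms[i] - 0.3 * p$pr, p$pr / 8, p$p_amp)
  }
  noise <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  if (p$noise_burst_rate_per_s > 0) {
    noise <- with_seed(p$seed, {
      n_burst <- stats::rpois(1, p$noise_burst_rate_per_s * duration_ms / 1000)
      starts <- sort(stats::runif(n_burst, 0, duration_ms - 50))
      for (s in starts) {
        sel <- tt >= s & tt <= s + 50
        v[sel] <- v[sel] + rnorm(sum(sel), 0, 0.3)
      }
      data.frame(start_ms = starts, end_ms = starts + 50)
    })
    if (nrow(noise)) noise <- merge_intervals(noise)
  }
  list(trace = trace(v, dt = dt, t0 = 0, units = "mV", label = "synthetic ECG"),
       annotation = ecg_annotation(fid, noise),
       noise = noise)
}

#' Generate a breath-event record with injected apnoeas
#'
#' Emits a regular breath train with lognormal expiration-time jitter; at
#' each requested apnoea the nearest breath's expiration time is replaced by
#' the requested episode length (and the following onset pushed back so
#' onsets stay increasing).
#'
#' @param base_te baseline expiration time (s).
#' @param rate breathing rate (breaths/min).
#' @param apnoeas data frame with columns `time_s`, `length_s` (may be
#'   empty); apnoeas must not overlap and must fall inside the record.
#' @param duration_s total record length (s).
#' @param jitter_cv coefficient of variation of the lognormal Te jitter.
#' @param seed integer seed.
#' @param adaptation_s,analysis_s window lengths passed to [breath_record()].
#' @return A [breath_record()].
#' @export
gen_breaths <- function(base_te = 0.2, rate = 140,
                        apnoeas = data.frame(time_s = numeric(0),
                                             length_s = numeric(0)),
                        duration_s = 2400, jitter_cv = 0.05, seed = NULL,
                        adaptation_s = 1200, analysis_s = 1200) {
  if (nrow(apnoeas)) {
    apnoeas <- apnoeas[order(apnoeas$time_s), , drop = FALSE]
    if (any(apnoeas$time_s < 0 | apnoeas$time_s > duration_s))
      stop("gen_breaths: apnoea times must lie inside the record")
    if (nrow(apnoeas) > 1 &&
        any(diff(apnoeas$time_s) <= apnoeas$length_s[-nrow(apnoeas)] + 1))
      stop("gen_breaths: overlapping apnoeas")
  }
  period <- 60 / rate
  with_seed(seed, {
    n_max <- ceiling(duration_s / period) + 10L
    sdlog <- sqrt(log(1 + jitter_cv^2))
    mult <- if (jitter_cv > 0) rlnorm(n_max, -sdlog^2 / 2, sdlog) else rep(1, n_max)
    onset <- numeric(0); te <- numeric(0)
    t_cur <- period
    next_ap <- 1L
    i <- 1L
    while (t_cur < duration_s) {
      te_i <- base_te * mult[i]
      if (next_ap <= nrow(apnoeas) && t_cur >= apnoeas$time_s[next_ap]) {
        te_i <- apnoeas$length_s[next_ap]
        next_ap <- next_ap + 1L
      }
      onset <- c(onset, t_cur)
      te <- c(te, te_i)
      t_cur <- t_cur + max(period, te_i + 0.05)
      i <- i + 1L
    }
    breath_record(onset, te, adaptation_s = adaptation_s,
                  analysis_s = analysis_s)
  })
}
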