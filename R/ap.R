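#' Segment a paced action-potential train
#'
#' Splits a membrane-potential trace recorded under fixed-rate current
#' stimulation (typically 1 Hz, 3 ms pulses) into single-AP segments, one per
#' stimulus, each spanning from its stimulus onset to the next stimulus onset
#' (the last segment runs to the end of the trace).
#'
#' @param tr membrane-potential [trace] (mV).
#' @param stim_times strictly increasing stimulus onset times (ms).
#' @return List of [trace] segments; each keeps its own `t0`.
#' @export
segment_ap_train <- function(tr, stim_times) {
  stopifnot(inherits(tr, "trace"))
  if (length(stim_times) < 1L || is.unsorted(stim_times, strictly = TRUE))
    stop("segment_ap_train: stim_times must be strictly increasing")
  tt <- trace_times(tr)
  bounds <- c(stim_times, tt[length(tt)] + tr$dt)
  lapply(seq_along(stim_times), function(i) {
    sel <- tt >= bounds[i] - 1e-9 & tt < bounds[i + 1] - 1e-9
    if (!any(sel))
      stop("segmentation error: stimulus at ", stim_times[i],
           " ms lies outside the trace")
    trace(tr$samples[sel], dt = tr$dt, t0 = tt[sel][1], units = tr$units,
          label = sprintf("beat %d", i))
  })
}

#' Action-potential parameters for a single beat
#'
#' Extracts the Table-style AP parameter set: resting membrane potential
#' (mean over the baseline window ending at the stimulus onset), overshoot
#' (maximum potential), amplitude (overshoot minus RMP), maximum upstroke
#' velocity (central-difference dV/dt after a short moving-average smooth,
#' in V/s), action-potential durations at 10/25/50/75/90 percent
#' repolarization, and triangulation (APD90 - APD25).
#'
#' APD times are measured from the instant of maximum dV/dt to the first
#' downward crossing of `overshoot - x/100 * amplitude`, with linear
#' interpolation between samples. A level that is never crossed before the
#' segment ends yields `NA` for that APD, flagged in the `missing` attribute.
#'
#' @param ap single-AP [trace], including >= `ap_baseline_ms` of
#'   pre-stimulus baseline.
#' @param stim_time stimulus onset time (ms, same clock as the trace).
#' @param config an [ephys_config()].
#' @return A one-row data frame of class `ap_params`: `rmp`, `overshoot`,
#'   `amplitude` (mV), `vmax` (V/s), `apd10`..`apd90`, `triangulation` (ms).
#' @export
ap_params <- function(ap, stim_time, config = ephys_config()) {
  stopifnot(inherits(ap, "trace"))
  tt <- trace_times(ap)
  if (stim_time - tt[1] < config$ap_baseline_ms - 1e-9)
    stop("ap_params: need at least ", config$ap_baseline_ms,
         " ms of pre-stimulus baseline")
  base <- trace_window(ap, stim_time - config$ap_baseline_ms, stim_time)
  rmp <- mean(base)
  v <- ap$samples
  overshoot <- max(v)
  amplitude <- overshoot - rmp

  k <- config$ap_smooth_points
  vs <- if (k > 1) stats::filter(v, rep(1 / k, k), sides = 2) else v
  vs <- as.numeric(vs)
  dvdt <- c(NA, (vs[-(1:2)] - vs[1:(length(vs) - 2)]) / (2 * ap$dt), NA)
  post <- which(tt >= stim_time)
  i_up <- post[which.max(dvdt[post])]
  vmax <- dvdt[i_up]  # mV/ms == V/s
  t_up <- tt[i_up]

  i_peak <- which.max(v)
  apd <- vapply(c(10, 25, 50, 75, 90), function(x) {
    level <- overshoot - x / 100 * amplitude
    j <- i_peak
    n <- length(v)
    while (j < n && !(v[j] >= level && v[j + 1] < level)) j <- j + 1
    if (j >= n) return(NA_real_)
    frac <- (v[j] - level) / (v[j] - v[j + 1])
    tt[j] + frac * ap$dt - t_up
  }, numeric(1))
  names(apd) <- paste0("apd", c(10, 25, 50, 75, 90))

  out <- data.frame(rmp = rmp, overshoot = overshoot, amplitude = amplitude,
                    vmax = vmax, t(apd),
                    triangulation = apd[["apd90"]] - apd[["apd25"]])
  class(out) <- c("ap_params", class(out))
  attr(out, "missing") <- names(apd)[is.na(apd)]
  out
}

#' Beat-to-beat variability of repolarization
#'
#' Quantifies APD90 instability over a train of consecutive beats as the
#' normalised mean absolute successive difference,
#' `BVR = sum(|APD90(n+1) - APD90(n)|) / (D * sqrt(2))`,
#' where `D` is the number of difference terms (`N - 1` beats by default;
#' the alternative denominator `N` is selectable via
#' `ephys_config(bvr_denominator = "n")`). Successive pairs are returned for
#' Poincaré plotting.
#'
#' @param apd90_series APD90 values (ms) of consecutive beats. Series longer
#'   than `bvr_max_beats` are truncated to the first `bvr_max_beats` beats;
#'   shorter than `bvr_min_beats` is an error unless `enforce_beats = FALSE`.
#' @param config an [ephys_config()].
#' @param enforce_beats apply the 10-15 beat window of the standard protocol.
#' @return List of class `bvr_result`: `bvr` (ms), `n_beats_used`,
#'   `poincare_pairs` (two-column matrix of `(APD90(n), APD90(n+1))`).
#' @examples
#' bvr(c(100, 110, 100, 110, 100), enforce_beats = FALSE)$bvr  # 40/(4*sqrt(2))
#' @export
bvr <- function(apd90_series, config = ephys_config(), enforce_beats = TRUE) {
  s <- as.numeric(apd90_series)
  if (any(!is.finite(s))) stop("bvr: APD90 series must be finite")
  if (enforce_beats && length(s) < config$bvr_min_beats)
    stop("bvr: insufficient data: ", length(s), " beats supplied, ",
         config$bvr_min_beats, " required")
  if (length(s) < 2L) stop("bvr: need at least 2 beats")
  if (enforce_beats && length(s) > config$bvr_max_beats)
    s <- s[seq_len(config$bvr_max_beats)]
  d <- diff(s)
  denom <- switch(config$bvr_denominator,
                  n_minus_1 = length(d),
                  n = length(s),
                  stop("bvr: bvr_denominator must be 'n_minus_1' or 'n'"))
  structure(
    list(bvr = sum(abs(d)) / (denom * sqrt(2)),
         n_beats_used = length(s),
         poincare_pairs = cbind(apd90_n = s[-length(s)], apd90_n1 = s[-1])),
    class = "bvr_result"
  )
}

#' @export
print.bvr_result <- function(x, ...) {
  cat(sprintf("BVR = %.3f ms over %d beats\n", x$bvr, x$n_beats_used))
  invisible(x)
}

#' AP parameters for every beat of a train
#'
#' Convenience wrapper over [ap_params()]: each beat is analysed on a window
#' running from `ap_baseline_ms` before its stimulus (so the RMP baseline is
#' the diastolic tail of the preceding beat) to the next stimulus onset.
#' The trace must start at least `ap_baseline_ms` before the first stimulus.
#'
#' @inheritParams segment_ap_train
#' @param config an [ephys_config()].
#' @return Data frame with one row per beat (column `beat` prepended).
#' @export
ap_train_params <- function(tr, stim_times, config = ephys_config()) {
  stopifnot(inherits(tr, "trace"))
  if (length(stim_times) < 1L || is.unsorted(stim_times, strictly = TRUE))
    stop("ap_train_params: stim_times must be strictly increasing")
  tt <- trace_times(tr)
  bounds <- c(stim_times, tt[length(tt)] + tr$dt)
  rows <- lapply(seq_along(stim_times), function(i) {
    sel <- tt >= stim_times[i] - config$ap_baseline_ms - 1e-9 &
      tt < bounds[i + 1] - 1e-9
    seg <- trace(tr$samples[sel], dt = tr$dt, t0 = tt[sel][1],
                 units = tr$units, label = sprintf("beat %d", i))
    cbind(beat = i, ap_params(seg, stim_times[i], config))
  })
  do.call(rbind, rows)
}
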