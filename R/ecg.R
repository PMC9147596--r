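#' Detect R peaks in an ECG trace
#'
#' Amplitude-threshold R-wave detector: a sample is a candidate peak when it
#' is a local maximum of the signal exceeding a configurable fraction
#' (default 0.6) of the 98th percentile of the rectified signal. Candidates
#' closer together than the refractory period (default 30 ms) are resolved in
#' favour of the larger peak. Peaks falling inside declared noise intervals
#' are dropped.
#'
#' @param tr an ECG [trace] (mV).
#' @param config an [ephys_config()].
#' @param noise optional data frame of noise intervals (`start_ms`, `end_ms`).
#' @return Strictly increasing numeric vector of R-peak times (ms).
#' @export
detect_r_peaks <- function(tr, config = ephys_config(), noise = NULL) {
  stopifnot(inherits(tr, "trace"))
  x <- tr$samples
  thr <- config$r_peak_threshold_frac * quantile(abs(x), 0.98, names = FALSE)
  n <- length(x)
  if (thr <= 0 || n < 3L)
    stop("detect_r_peaks: detection error: flat or empty trace (threshold ",
         format(thr), ")")
  is_peak <- c(FALSE, x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n],
               FALSE) & x > thr
  idx <- which(is_peak)
  if (!length(idx))
    stop("detect_r_peaks: detection error: no samples above threshold ",
         format(thr), " mV")
  # refractory resolution: greedy by amplitude
  keep <- logical(length(idx))
  ord <- order(x[idx], decreasing = TRUE)
  taken_t <- numeric(0)
  refr <- config$r_peak_refractory_ms
  tt <- trace_times(tr)
  for (j in ord) {
    t_j <- tt[idx[j]]
    if (!length(taken_t) || all(abs(taken_t - t_j) >= refr)) {
      keep[j] <- TRUE
      taken_t <- c(taken_t, t_j)
    }
  }
  times <- sort(tt[idx[keep]])
  if (!is.null(noise) && nrow(noise)) {
    in_noise <- vapply(times, function(t)
      any(t >= noise$start_ms & t <= noise$end_ms), logical(1))
    times <- times[!in_noise]
  }
  if (!length(times))
    stop("detect_r_peaks: detection error: all detected peaks fell inside ",
         "noise intervals")
  times
}

#' Flag breathing-noise intervals in an ECG trace
#'
#' Optional automatic noise flagging: the trace's high-frequency residual
#' (first difference) is summarised as an RMS over sliding 50 ms windows,
#' and windows whose RMS exceeds `threshold_mult` times the median window
#' RMS are flagged. The default multiple sits well above the residual the
#' QRS slopes themselves produce (about an order of magnitude over the
#' median) while broadband interference bursts run far higher. Adjacent flagged windows merge into intervals. Manually
#' declared noise intervals should always be honoured in addition to (or
#' instead of) this heuristic.
#'
#' @param tr an ECG [trace].
#' @param threshold_mult multiple of the median window RMS above which a
#'   window counts as noise.
#' @param window_ms sliding-window length (ms).
#' @return Data frame of flagged intervals (`start_ms`, `end_ms`); zero rows
#'   when the trace is clean.
#' @export
flag_breathing_noise <- function(tr, threshold_mult = 20, window_ms = 50) {
  stopifnot(inherits(tr, "trace"))
  resid <- diff(tr$samples)
  w <- max(2L, round(window_ms / tr$dt))
  n_win <- floor(length(resid) / w)
  if (n_win < 3L) return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  rms <- vapply(seq_len(n_win), function(i)
    sqrt(mean(resid[((i - 1) * w + 1):(i * w)]^2)), numeric(1))
  hot <- rms > threshold_mult * median(rms)
  if (!any(hot)) return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  tt0 <- tr$t0
  iv <- data.frame(start_ms = tt0 + (which(hot) - 1) * w * tr$dt,
                   end_ms = tt0 + which(hot) * w * tr$dt)
  merge_intervals(iv)
}

#' Per-complex ECG interval metrics
#'
#' Computes RR, heart rate, PR (when P onsets are unavailable, `NA`), QRS and
#' QT for each annotated complex. `RR(i)` is the interval from the i-th to
#' the (i+1)-th R peak, so the final complex carries `NA` RR/HR. Complexes
#' whose `[qrs_on, qt_end]` span overlaps a noise interval are marked
#' not clean and excluded by [summarise_ecg()].
#'
#' @param annotations an [ecg_annotation()].
#' @param r_peaks optional vector of R-peak times (ms), e.g. from
#'   [detect_r_peaks()]; defaults to the annotated R-peak fiducials.
#' @return Data frame with one row per complex: `complex_id`, `rr`, `hr`,
#'   `pr`, `qrs`, `qt` and logical `clean`.
#' @export
complex_metrics <- function(annotations, r_peaks = NULL) {
  stopifnot(inherits(annotations, "ecg_annotation"))
  fid <- annotations$fiducials
  if (nrow(fid) < 2L)
    stop("complex_metrics: need at least 2 annotated complexes")
  if (is.null(r_peaks)) r_peaks <- fid$r_peak_ms
  r_peaks <- sort(r_peaks)
  # match each complex to its nearest detected R peak
  r_of <- vapply(fid$r_peak_ms, function(t) r_peaks[which.min(abs(r_peaks - t))],
                 numeric(1))
  rr <- c(diff(r_of), NA_real_)
  rr[rr <= 0] <- NA_real_
  noise <- annotations$noise
  clean <- rep(TRUE, nrow(fid))
  if (nrow(noise)) {
    clean <- !vapply(seq_len(nrow(fid)), function(i)
      any(fid$qrs_on_ms[i] <= noise$end_ms & fid$qt_end_ms[i] >= noise$start_ms),
      logical(1))
  }
  data.frame(
    complex_id = fid$complex_id,
    rr  = rr,
    hr  = 60000 / rr,
    pr  = if ("p_on_ms" %in% names(fid)) fid$qrs_on_ms - fid$p_on_ms else NA_real_,
    qrs = fid$qrs_end_ms - fid$qrs_on_ms,
    qt  = fid$qt_end_ms - fid$qrs_on_ms,
    clean = clean
  )
}

#' Rate-corrected QT interval
#'
#' Two murine rate corrections are applied, with RR in milliseconds:
#' a square-root normalisation to RR = 100 ms,
#' `QTc = QT / sqrt(RR / 100)`, and a linear correction anchored at
#' RR = 170 ms, `QTc = QT + 0.3173 * (170 - RR)`.
#'
#' @param qt QT interval(s), ms; > 0.
#' @param rr RR interval(s), ms; > 0.
#' @return Data frame with columns `qtc_eq1` and `qtc_eq2` (ms).
#' @examples
#' qtc(51.9, 130.7)  # qtc_eq2 ~ 64.4 ms
#' @export
qtc <- function(qt, rr) {
  if (any(!is.finite(qt) | qt <= 0) || any(!is.finite(rr) | rr <= 0))
    stop("qtc: qt and rr must be positive (ms)")
  data.frame(qtc_eq1 = qt / sqrt(rr / 100),
             qtc_eq2 = qt + 0.3173 * (170 - rr))
}

#' Per-animal ECG summary over consecutive clean complexes
#'
#' Averages the interval metrics over the first run of `n_complexes`
#' consecutive clean complexes (default 5), skipping complexes superimposed
#' with breathing noise. QTc is computed per complex and then averaged, not
#' applied to the mean QT/RR.
#'
#' @param metrics data frame from [complex_metrics()].
#' @param n_complexes number of consecutive clean complexes required.
#' @return One-row data frame: mean `rr`, `hr`, `pr`, `qrs`, `qt`,
#'   `qtc_eq1`, `qtc_eq2` and `n_complexes`.
#' @export
summarise_ecg <- function(metrics, n_complexes = 5) {
  usable <- metrics$clean & is.finite(metrics$rr)
  run <- rle(usable)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  good <- which(run$values & run$lengths >= n_complexes)
  if (!length(good)) {
    longest <- if (any(run$values)) max(run$lengths[run$values]) else 0L
    stop("summarise_ecg: fewer than ", n_complexes, " consecutive clean ",
         "complexes available (longest clean run: ", longest, ")")
  }
  sel <- seq(starts[good[1]], length.out = n_complexes)
  m <- metrics[sel, , drop = FALSE]
  qc <- qtc(m$qt, m$rr)
  data.frame(
    rr = mean(m$rr), hr = mean(m$hr), pr = mean(m$pr),
    qrs = mean(m$qrs), qt = mean(m$qt),
    qtc_eq1 = mean(qc$qtc_eq1), qtc_eq2 = mean(qc$qtc_eq2),
    n_complexes = n_complexes
  )
}
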