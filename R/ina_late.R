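#' Sodium-sensitive current by NMDG subtraction
#'
#' Isolates the sodium-sensitive current by pointwise subtraction of the
#' trace recorded after equimolar replacement of external Na+ with
#' N-methyl-D-glucamine (NMDG) from the control trace.
#'
#' @param control,nmdg current [trace]s sharing `dt`, length and units.
#' @return A [trace], `control - nmdg`.
#' @export
na_sensitive_current <- function(control, nmdg) {
  stopifnot(inherits(control, "trace"), inherits(nmdg, "trace"))
  if (abs(control$dt - nmdg$dt) > 1e-12)
    stop("na_sensitive_current: alignment error: traces differ in dt (",
         control$dt, " vs ", nmdg$dt, " ms)")
  if (length(control$samples) != length(nmdg$samples))
    stop("na_sensitive_current: alignment error: traces differ in length")
  if (!identical(control$units, nmdg$units))
    stop("na_sensitive_current: traces differ in units")
  trace(control$samples - nmdg$samples, dt = control$dt, t0 = control$t0,
        units = control$units, label = "Na-sensitive (NMDG subtraction)")
}

#' Late sodium-current measures
#'
#' Quantifies the sustained (late) component of the sodium current elicited
#' by a 1 s depolarizing step using three complementary measures that all
#' exclude the large initial fast transient: current density at 300 ms and
#' at 600 ms into the step (mean over a +/-`late_window_ms` window, default
#' 5 ms; set 0 for a point sample), and the trapezoidal current integral
#' between 350 and 800 ms, expressed in pC/pF.
#'
#' @param tr current-density [trace] (pA/pF).
#' @param step_start time of the step onset (ms, same clock as the trace).
#' @param config an [ephys_config()].
#' @return One-row data frame of class `late_measures`: `density_300`,
#'   `density_600` (pA/pF), `integral_350_800` (pC/pF).
#' @examples
#' tr <- trace(rep(-0.5, 9001), dt = 0.1, units = "pA/pF")
#' late_measures(tr, step_start = 0)  # integral -0.225 pC/pF
#' @export
late_measures <- function(tr, step_start, config = ephys_config()) {
  stopifnot(inherits(tr, "trace"))
  if (!identical(tr$units, "pA/pF"))
    stop("late_measures: trace must be density-normalised (pA/pF)")
  tt <- trace_times(tr)
  t_end <- step_start + config$late_int_to_ms
  if (tt[length(tt)] < t_end - 1e-9)
    stop("late_measures: range error: trace ends ",
         format(t_end - tt[length(tt)]), " ms before ", t_end, " ms")
  w <- config$late_window_ms
  dens <- function(at) {
    if (w > 0) mean(trace_window(tr, step_start + at - w, step_start + at + w))
    else approx(tt, tr$samples, xout = step_start + at)$y
  }
  sel <- tt >= step_start + config$late_int_from_ms - 1e-9 &
    tt <= step_start + config$late_int_to_ms + 1e-9
  integral <- pracma::trapz(tt[sel], tr$samples[sel]) / 1000  # fC/pF -> pC/pF
  out <- data.frame(density_300 = dens(config$late_t1_ms),
                    density_600 = dens(config$late_t2_ms),
                    integral_350_800 = integral)
  class(out) <- c("late_measures", class(out))
  out
}

#' Percent inhibition of the late sodium current
#'
#' Drug effect on each of the three late-current measures, computed on
#' magnitudes: `100 * (1 - |post| / |pre|)`. Measures with a zero control
#' value are undefined and returned as `NA` with a warning.
#'
#' @param pre,post `late_measures` rows before and after drug application.
#' @return One-row data frame: `pct_inhibition_300`, `pct_inhibition_600`,
#'   `pct_inhibition_integral` (percent).
#' @export
pct_inhibition <- function(pre, post) {
  vals <- vapply(c("density_300", "density_600", "integral_350_800"),
                 function(f) {
                   if (abs(pre[[f]]) < .Machine$double.eps) return(NA_real_)
                   100 * (1 - abs(post[[f]]) / abs(pre[[f]]))
                 }, numeric(1))
  if (anyNA(vals))
    warning("pct_inhibition: undefined for measure(s) with zero control value")
  data.frame(pct_inhibition_300 = vals[[1]],
             pct_inhibition_600 = vals[[2]],
             pct_inhibition_integral = vals[[3]])
}
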