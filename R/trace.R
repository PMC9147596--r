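#' Uniformly sampled signal trace
#'
#' A `trace` holds a uniformly sampled time series (membrane potential in mV
#' or membrane current in pA or pA/pF) together with its sampling interval.
#' All times are in milliseconds; inward current is negative.
#'
#' @param samples numeric vector of sample values; must be non-empty and finite.
#' @param dt sampling interval (ms); must be > 0. The package default of
#'   0.1 ms corresponds to a 10 kHz digitization rate.
#' @param t0 time of the first sample (ms).
#' @param units unit label, one of `"mV"`, `"pA"`, `"pA/pF"`.
#' @param label free-text description.
#'
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 100)), dt = 0.1, units = "mV")
#' trace_times(tr)[1:5]
#' @export
trace <- function(samples, dt = 0.1, t0 = 0, units = "mV", label = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("trace: 'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("trace: all samples must be finite")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("trace: 'dt' must be a single positive number (ms)")
  units <- match.arg(units, c("mV", "pA", "pA/pF"))
  structure(
    list(samples = samples, dt = dt, t0 = t0, units = units, label = label),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ dt = %g ms, t0 = %g ms [%s]%s\n",
              length(x$samples), x$dt, x$t0, x$units,
              if (nzchar(x$label)) paste0(" - ", x$label) else ""))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param tr a [trace].
#' @return Numeric vector of sample times (ms), `t0 + (0:(n-1)) * dt`.
#' @export
trace_times <- function(tr) {
  stopifnot(inherits(tr, "trace"))
  tr$t0 + (seq_along(tr$samples) - 1) * tr$dt
}

#' Extract a time window from a trace
#'
#' Returns the samples whose times fall in `[from, to]` (ms, inclusive).
#' Used internally by baseline and measurement-window computations.
#'
#' @param tr a [trace].
#' @param from,to window bounds (ms).
#' @return Numeric vector of samples inside the window.
#' @export
trace_window <- function(tr, from, to) {
  tt <- trace_times(tr)
  tr$samples[tt >= from - 1e-9 & tt <= to + 1e-9]
}

#' Family of voltage-clamp sweeps
#'
#' A `sweep_family` groups the sweeps of one voltage-clamp protocol, keyed by
#' the protocol value that distinguishes them (command voltage in mV for
#' current-voltage and availability protocols, interpulse interval in ms for
#' recovery protocols), together with the cell capacitance used for
#' current-density normalisation.
#'
#' @param sweeps named list of [trace] objects; names are the protocol keys
#'   (numeric, e.g. `"-40"`). All sweeps must share the same `dt`.
#' @param protocol one of `"IV_ACTIVATION"`, `"AVAILABILITY"`, `"RECOVERY"`,
#'   `"LATE_STEP"`, `"AP_TRAIN"`.
#' @param capacitance cell capacitance (pF), or `NULL` when unknown.
#' @param meta optional named list of extra protocol metadata (e.g. step
#'   timing used by the generator).
#'
#' @return An object of class `sweep_family`.
#' @export
sweep_family <- function(sweeps, protocol, capacitance = NULL, meta = list()) {
  protocol <- match.arg(protocol, c("IV_ACTIVATION", "AVAILABILITY",
                                    "RECOVERY", "LATE_STEP", "AP_TRAIN"))
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("sweep_family: 'sweeps' must be a non-empty list of traces")
  if (is.null(names(sweeps)) || anyDuplicated(names(sweeps)))
    stop("sweep_family: sweeps must have unique protocol keys as names")
  ok <- vapply(sweeps, inherits, logical(1), what = "trace")
  if (!all(ok)) stop("sweep_family: every sweep must be a trace")
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  if (diff(range(dts)) > 1e-12)
    stop("sweep_family: all sweeps must share the same dt")
  if (!is.null(capacitance)) {
    if (!is.numeric(capacitance) || length(capacitance) != 1L || capacitance <= 0)
      stop("sweep_family: 'capacitance' must be a single positive number (pF)")
  }
  structure(
    list(sweeps = sweeps, protocol = protocol, capacitance = capacitance,
         meta = meta),
    class = "sweep_family"
  )
}

#' @export
print.sweep_family <- function(x, ...) {
  cat(sprintf("<sweep_family> %s: %d sweeps (keys %s), capacitance %s pF\n",
              x$protocol, length(x$sweeps),
              paste(names(x$sweeps), collapse = ", "),
              if (is.null(x$capacitance)) "?" else format(x$capacitance)))
  invisible(x)
}

#' Numeric protocol keys of a sweep family
#'
#' @param family a [sweep_family].
#' @return Numeric vector of protocol keys (command voltages or intervals).
#' @export
sweep_keys <- function(family) {
  stopifnot(inherits(family, "sweep_family"))
  as.numeric(names(family$sweeps))
}

#' Normalise a current trace to current density
#'
#' Divides every sample of a pA current trace by the cell capacitance,
#' yielding current density in pA/pF. Unit labels are tracked so that an
#' already-normalised trace cannot be normalised twice.
#'
#' @param tr a [trace] with units `"pA"`.
#' @param capacitance cell capacitance (pF), > 0.
#' @return A [trace] with units `"pA/pF"`.
#' @examples
#' tr <- trace(c(-300, -150), dt = 0.1, units = "pA")
#' density_normalise(tr, 150)$samples  # -2, -1
#' @export
density_normalise <- function(tr, capacitance) {
  stopifnot(inherits(tr, "trace"))
  if (is.null(capacitance) || !is.numeric(capacitance) ||
      length(capacitance) != 1L || !is.finite(capacitance) || capacitance <= 0)
    stop("density_normalise: supply a positive cell capacitance in pF")
  if (identical(tr$units, "pA/pF"))
    stop("density_normalise: trace is already in pA/pF; refusing to normalise twice")
  if (!identical(tr$units, "pA"))
    stop("density_normalise: expected a current trace in pA, got '", tr$units, "'")
  tr$samples <- tr$samples / capacitance
  tr$units <- "pA/pF"
  tr
}

#' Normalise every sweep of a family to current density
#'
#' Applies [density_normalise()] to each sweep using the family capacitance.
#' Sweeps already in pA/pF are left untouched.
#'
#' @param family a [sweep_family].
#' @return The family with all sweeps in pA/pF.
#' @export
family_density_normalise <- function(family) {
  stopifnot(inherits(family, "sweep_family"))
  units <- vapply(family$sweeps, `[[`, character(1), "units")
  if (all(units == "pA/pF")) return(family)
  if (is.null(family$capacitance))
    stop("family_density_normalise: family has pA sweeps but no capacitance; ",
         "supply the cell capacitance to normalise to pA/pF")
  family$sweeps <- lapply(family$sweeps, function(s) {
    if (identical(s$units, "pA/pF")) s else density_normalise(s, family$capacitance)
  })
  family
}
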