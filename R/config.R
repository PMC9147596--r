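.config_defaults <- list(
  # sampling
  default_dt_ms        = 0.1,    # 10 kHz digitization
  # ECG
  r_peak_threshold_frac = 0.6,   # fraction of 98th percentile of |signal|
  r_peak_refractory_ms  = 30,
  ecg_n_complexes       = 5,     # consecutive clean complexes averaged
  # action potentials
  ap_baseline_ms   = 10,         # pre-stimulus window for RMP
  ap_smooth_points = 3,          # moving average before dV/dt
  bvr_min_beats    = 10,
  bvr_max_beats    = 15,
  bvr_denominator  = "n_minus_1",  # or "n"
  # fast INa protocols
  iv_step_start_ms   = 10,
  iv_step_dur_ms     = 250,
  peak_measure       = "isochronal",  # or "search" (per-sweep extremum)
  peak_smooth_ms     = 1,             # boxcar used to locate/search the peak
  peak_read_ms       = 0.5,           # trailing mean ending at the peak instant
  erev_min_points    = 3,
  erev_exclusion_mv  = 1,        # points this close to E_rev dropped from G
  act_fit_min_mv     = -80,
  act_fit_max_mv     = -20,
  avail_fit_min_mv   = -150,
  avail_fit_max_mv   = -50,
  tau_fit_start_offset_ms = 0.2, # after the current peak
  tau_fit_end_frac        = 0.05, # stop where |I| falls to this fraction of peak
  window_grid_min_mv = -120,
  window_grid_max_mv = 20,
  window_grid_step_mv = 2,
  recovery_baseline_ms = 10,
  recovery_p1_ms       = 1000,
  recovery_p2_ms       = 40,
  # late INa
  late_window_ms  = 5,           # half-width of the mean window; 0 = point read
  late_t1_ms      = 300,
  late_t2_ms      = 600,
  late_int_from_ms = 350,
  late_int_to_ms   = 800,
  # respiration
  apnoea_factor    = 4,
  apnoea_reference = "per_minute",  # or "trailing"
  apnoea_window_s  = 60,
  # fitting
  fit_tol = 1e-10
)

#' Pipeline configuration
#'
#' Returns the package-wide configuration list. Every tunable decision of the
#' pipeline (baseline windows, detector thresholds, fit windows, apnoea rule
#' variant) has a documented default here; overrides are supplied as named
#' arguments. Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param ... named overrides of default keys.
#' @return Named list of configuration values, class `ephys_config`.
#' @examples
#' cfg <- ephys_config(late_window_ms = 0)  # point reads at 300/600 ms
#' cfg$apnoea_factor
#' @export
ephys_config <- function(...) {
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("ephys_config: all overrides must be named")
    unknown <- setdiff(names(overrides), names(.config_defaults))
    if (length(unknown))
      stop("ephys_config: unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
  }
  structure(modifyList(.config_defaults, overrides), class = "ephys_config")
}

#' Read a configuration file
#'
#' Reads a flat YAML key/value file and merges it over the defaults of
#' [ephys_config()]. Unknown keys are rejected.
#'
#' @param path path to a YAML file of scalar key/value pairs.
#' @return An `ephys_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_config requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("read_config: expected a mapping of key: value pairs")
  do.call(ephys_config, vals)
}
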