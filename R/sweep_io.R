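#' Write a sweep family to a sweep table
#'
#' The sweep-table format is a UTF-8 CSV with header
#' `time_ms,<key1>,<key2>,...` where the keys are the protocol values (e.g.
#' command voltages in mV), one data column per sweep, plus a JSON sidecar
#' `<name>.meta.json` carrying `protocol`, `capacitance_pF`, `dt_ms` and the
#' sweep unit label. Numbers are serialised in plain locale-independent
#' decimal with 17 significant digits, so a write/read round trip is
#' lossless for all finite doubles.
#'
#' @param family a [sweep_family]; all sweeps must share length as well as dt.
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @seealso [read_sweep_table()]
#' @export
write_sweep_table <- function(family, path) {
  stopifnot(inherits(family, "sweep_family"))
  ns <- vapply(family$sweeps, length, integer(1))
  if (length(unique(ns)) != 1L)
    stop("write_sweep_table: all sweeps must have the same length")
  tr1 <- family$sweeps[[1]]
  tt <- trace_times(tr1)
  cols <- c(list(time_ms = tt), lapply(family$sweeps, `[[`, "samples"))
  header <- paste(c("time_ms", names(family$sweeps)), collapse = ",")
  body <- do.call(paste, c(lapply(cols, function(x) sprintf("%.17g", x)),
                           sep = ","))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("write_sweep_table: cannot open '",
                                           path, "' for writing"))
  on.exit(close(con))
  writeLines(c(header, body), con)
  meta <- list(protocol = family$protocol,
               dt_ms = tr1$dt,
               t0_ms = tr1$t0,
               units = tr1$units)
  if (!is.null(family$capacitance)) meta$capacitance_pF <- family$capacitance
  if (length(family$meta)) meta <- c(meta, family$meta)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", "", path) |> paste0(".meta.json")

#' Read a sweep family from a sweep table
#'
#' Parses the CSV sweep-table format written by [write_sweep_table()]. The
#' first column must be `time_ms` on a uniform grid; every other column
#' becomes one sweep keyed by its header value. Sample values are preserved
#' bit-exactly. Missing sidecar fields fall back to the configuration
#' defaults (`dt` from the time column itself, `default_dt_ms` only when the
#' file has a single row).
#'
#' @param path path to a sweep-table CSV.
#' @param config an [ephys_config()] list.
#' @return A [sweep_family].
#' @export
read_sweep_table <- function(path, config = ephys_config()) {
  if (!file.exists(path)) stop("read_sweep_table: no such file: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "numeric")
  if (ncol(df) < 2L)
    stop("read_sweep_table: need a time column plus at least one sweep column")
  if (names(df)[1] != "time_ms")
    stop("read_sweep_table: malformed header: first column must be 'time_ms', ",
         "found '", names(df)[1], "'")
  keys <- names(df)[-1]
  bad <- keys[is.na(suppressWarnings(as.numeric(keys)))]
  if (length(bad))
    stop("read_sweep_table: malformed header: non-numeric sweep key(s): ",
         paste(sQuote(bad), collapse = ", "))
  tt <- df$time_ms
  if (nrow(df) >= 2L) {
    steps <- diff(tt)
    if (any(steps <= 0) || diff(range(steps)) > 1e-6 * max(abs(steps)))
      stop("read_sweep_table: sampling error: time column is not a uniform ",
           "increasing grid")
    dt <- steps[1]
  } else {
    dt <- config$default_dt_ms
  }

  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (!is.null(meta$dt_ms) && nrow(df) >= 2L &&
      abs(meta$dt_ms - dt) > 1e-6 * dt)
    warning("read_sweep_table: sidecar dt_ms (", meta$dt_ms,
            ") disagrees with time column (", dt, "); using the time column")
  units <- meta$units %||% "pA"
  protocol <- meta$protocol %||% "IV_ACTIVATION"
  if (is.null(meta$protocol))
    message("read_sweep_table: sidecar omits 'protocol'; assuming IV_ACTIVATION")
  sweeps <- lapply(keys, function(k) {
    trace(df[[k]], dt = dt, t0 = tt[1], units = units, label = paste0("key ", k))
  })
  names(sweeps) <- keys
  extra <- meta[setdiff(names(meta),
                        c("protocol", "dt_ms", "t0_ms", "units", "capacitance_pF"))]
  sweep_family(sweeps, protocol = protocol,
               capacitance = meta$capacitance_pF, meta = extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ECG complex annotations
#'
#' Per-complex fiducial times (QRS onset, R peak, QRS end, QT end; all ms)
#' plus optional noise intervals to exclude. Validates the within-complex
#' ordering `qrs_on < r_peak < qrs_end <= qt_end` and merges overlapping
#' noise intervals.
#'
#' @param fiducials data frame with columns `complex_id`, `qrs_on_ms`,
#'   `r_peak_ms`, `qrs_end_ms`, `qt_end_ms`.
#' @param noise optional data frame with columns `start_ms`, `end_ms`.
#' @return An object of class `ecg_annotation`.
#' @export
ecg_annotation <- function(fiducials, noise = NULL) {
  need <- c("complex_id", "qrs_on_ms", "r_peak_ms", "qrs_end_ms", "qt_end_ms")
  if (!all(need %in% names(fiducials)))
    stop("ecg_annotation: fiducials must have columns ",
         paste(need, collapse = ", "))
  fiducials <- fiducials[order(fiducials$qrs_on_ms), , drop = FALSE]
  with(fiducials, {
    if (any(qrs_on_ms >= r_peak_ms) || any(r_peak_ms >= qrs_end_ms) ||
        any(qrs_end_ms > qt_end_ms))
      stop("ecg_annotation: fiducials must satisfy qrs_on < r_peak < qrs_end <= qt_end")
  })
  if (!is.null(noise) && nrow(noise)) {
    if (!all(c("start_ms", "end_ms") %in% names(noise)))
      stop("ecg_annotation: noise needs columns start_ms, end_ms")
    noise <- merge_intervals(noise)
  } else {
    noise <- data.frame(start_ms = numeric(0), end_ms = numeric(0))
  }
  structure(list(fiducials = fiducials, noise = noise),
            class = "ecg_annotation")
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv$start_ms), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    j <- nrow(out)
    if (iv$start_ms[i] <= out$end_ms[j]) {
      out$end_ms[j] <- max(out$end_ms[j], iv$end_ms[i])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Read ECG annotations from CSV files
#'
#' @param path CSV with columns `complex_id,qrs_on_ms,r_peak_ms,qrs_end_ms,qt_end_ms`.
#' @param noise_path optional CSV with columns `start_ms,end_ms`.
#' @return An [ecg_annotation()].
#' @export
read_annotations <- function(path, noise_path = NULL) {
  fid <- read.csv(path)
  noise <- if (!is.null(noise_path)) read.csv(noise_path) else NULL
  ecg_annotation(fid, noise)
}
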