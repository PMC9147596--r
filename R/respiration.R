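#' Breath-event record
#'
#' An ordered series of breath events, each with its onset time and total
#' expiration time (Te), as produced by plethysmography breath segmentation.
#' The record begins with an adaptation period (default 20 min) that is
#' never scored, followed by the analysis window (default 20 min).
#'
#' @param onset_s strictly increasing breath onset times (s, from record
#'   start).
#' @param te_s expiration time of each breath (s, > 0).
#' @param adaptation_s length of the un-scored adaptation period (s).
#' @param analysis_s length of the scored analysis window (s).
#' @return An object of class `breath_record`.
#' @export
breath_record <- function(onset_s, te_s, adaptation_s = 1200,
                          analysis_s = 1200) {
  if (length(onset_s) != length(te_s))
    stop("breath_record: onset_s and te_s must have equal length")
  if (is.unsorted(onset_s, strictly = TRUE))
    stop("breath_record: onsets must be strictly increasing")
  if (any(te_s <= 0)) stop("breath_record: all Te must be > 0")
  structure(list(onset_s = as.numeric(onset_s), te_s = as.numeric(te_s),
                 adaptation_s = adaptation_s, analysis_s = analysis_s),
            class = "breath_record")
}

#' @export
print.breath_record <- function(x, ...) {
  cat(sprintf("<breath_record> %d breaths over %.1f min (adapt %.0f min + analyse %.0f min)\n",
              length(x$onset_s), max(x$onset_s) / 60,
              x$adaptation_s / 60, x$analysis_s / 60))
  invisible(x)
}

#' Detect apnoeas in a breath record
#'
#' Implements the running-average expiration-time rule: a reference
#' expiration time is taken every minute as the mean Te of the breaths in
#' the preceding 60 s window, and a breath counts as an apnoea when its Te
#' exceeds `factor` (default 4) times the reference in force for its minute.
#' Breaths already classified apnoeic are excluded from subsequent reference
#' windows, so long apnoeas do not inflate the baseline. Consecutive
#' apnoeic breaths merge into one episode whose length is the summed Te of
#' its breaths. Only episodes starting inside the analysis window (after
#' the adaptation period) are scored.
#'
#' With `ephys_config(apnoea_reference = "trailing")` the reference is
#' instead the trailing 60 s mean recomputed at every breath.
#'
#' @param record a [breath_record()].
#' @param factor threshold multiple of the running-average Te.
#' @param config an [ephys_config()].
#' @return List of class `apnoea_summary`: `count`, `lengths` (s),
#'   `mean_length` (s, `NA` when no episodes), and the per-breath logical
#'   `is_apnoea` for diagnostics.
#' @export
detect_apnoeas <- function(record, factor = NULL, config = ephys_config()) {
  stopifnot(inherits(record, "breath_record"))
  if (is.null(factor)) factor <- config$apnoea_factor
  on <- record$onset_s; te <- record$te_s
  t_an0 <- record$adaptation_s
  t_an1 <- record$adaptation_s + record$analysis_s
  if (!any(on >= t_an0 & on < t_an1))
    stop("detect_apnoeas: insufficient data: no breaths in the analysis window")
  win <- config$apnoea_window_s
  n <- length(on)
  apn <- logical(n)

  if (identical(config$apnoea_reference, "per_minute")) {
    minute <- floor(on / win)  # minute index of each breath
    last_ref <- NA_real_
    for (m in sort(unique(minute))) {
      in_win <- on >= m * win - win & on < m * win & !apn
      ref <- if (any(in_win)) mean(te[in_win]) else last_ref
      if (any(in_win)) last_ref <- ref
      if (is.na(ref)) next  # no reference yet: breaths unscored
      idx <- which(minute == m)
      apn[idx] <- te[idx] > factor * ref
    }
  } else if (identical(config$apnoea_reference, "trailing")) {
    for (i in seq_len(n)) {
      in_win <- on >= on[i] - win & on < on[i] & !apn[seq_len(n) < i]
      in_win <- which(in_win)
      if (!length(in_win)) next
      if (te[i] > factor * mean(te[in_win])) apn[i] <- TRUE
    }
  } else {
    stop("detect_apnoeas: apnoea_reference must be 'per_minute' or 'trailing'")
  }

  # merge consecutive apnoeic breaths into episodes
  runs <- rle(apn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ep_start <- starts[runs$values]
  ep_end <- ends[runs$values]
  lengths <- numeric(0)
  for (j in seq_along(ep_start)) {
    if (on[ep_start[j]] >= t_an0 && on[ep_start[j]] < t_an1)
      lengths <- c(lengths, sum(te[ep_start[j]:ep_end[j]]))
  }
  structure(list(count = length(lengths), lengths = lengths,
                 mean_length = if (length(lengths)) mean(lengths) else NA_real_,
                 is_apnoea = apn),
            class = "apnoea_summary")
}

#' @export
print.apnoea_summary <- function(x, ...) {
  cat(sprintf("%d apnoea episode(s); mean length %s s\n", x$count,
              if (is.na(x$mean_length)) "-" else sprintf("%.2f", x$mean_length)))
  invisible(x)
}

#' Correlation of APD90 with apnoea length across animals
#'
#' Pearson correlation between per-animal mean APD90 and mean apnoea
#' length, with the two-sided p-value from the t-transform
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param apd90 per-animal mean APD90 values (ms).
#' @param apnoea_length per-animal mean apnoea lengths (s).
#' @return List: `r`, `p_value`, `n`. Zero variance in either variable
#'   yields `r = NA` with a warning.
#' @export
apd_apnoea_correlation <- function(apd90, apnoea_length) {
  if (length(apd90) != length(apnoea_length))
    stop("apd_apnoea_correlation: inputs must have equal length")
  if (length(apd90) < 3L)
    stop("apd_apnoea_correlation: need at least 3 animals")
  if (sd(apd90) == 0 || sd(apnoea_length) == 0) {
    warning("apd_apnoea_correlation: undefined correlation (zero variance)")
    return(list(r = NA_real_, p_value = NA_real_, n = length(apd90)))
  }
  ct <- cor.test(apd90, apnoea_length, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(apd90))
}
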