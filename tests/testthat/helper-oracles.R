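# Independent brute-force implementation of the apnoea rule, used as the
# oracle for detect_apnoeas: per-minute reference = mean Te of non-apnoeic
# breaths in the preceding 60 s; a breath is apnoeic when Te > factor * ref;
# consecutive apnoeic breaths merge into one episode (length = summed Te);
# only episodes starting in the analysis window are scored.
oracle_apnoea <- function(onset, te, factor = 4, win = 60,
                          adapt = 1200, analysis = 1200) {
  n <- length(onset)
  apn <- rep(FALSE, n)
  last_ref <- NA_real_
  for (m in sort(unique(floor(onset / win)))) {
    ref_set <- c()
    for (i in seq_len(n)) {
      if (onset[i] >= (m - 1) * win && onset[i] < m * win && !apn[i])
        ref_set <- c(ref_set, i)
    }
    ref <- if (length(ref_set)) mean(te[ref_set]) else last_ref
    if (length(ref_set)) last_ref <- ref
    if (is.na(ref)) next
    for (i in seq_len(n)) {
      if (floor(onset[i] / win) == m && te[i] > factor * ref) apn[i] <- TRUE
    }
  }
  count <- 0L
  lengths <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (apn[i]) {
      j <- i
      while (j < n && apn[j + 1L]) j <- j + 1L
      if (onset[i] >= adapt && onset[i] < adapt + analysis) {
        count <- count + 1L
        lengths <- c(lengths, sum(te[i:j]))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(count = count, lengths = lengths)
}

# random breath series with occasional long expirations, independent of the
# package's own generator
random_breath_series <- function(duration = 300, adapt = 60, analysis = 240) {
  t_cur <- stats::runif(1, 0.2, 0.6)
  onset <- c(); te <- c()
  while (t_cur < duration) {
    te_i <- exp(stats::rnorm(1, log(0.2), 0.15))
    if (stats::runif(1) < 0.04) te_i <- te_i * stats::runif(1, 3, 8)
    onset <- c(onset, t_cur)
    te <- c(te, te_i)
    t_cur <- t_cur + max(stats::runif(1, 0.3, 0.5), te_i + 0.05)
  }
  list(onset = onset, te = te, adapt = adapt, analysis = analysis)
}

# Table-style AP targets for the two genotypes
ap_targets_wt <- function(...) ap_shape_params(...)
ap_targets_mecp2 <- function(...) {
  defaults <- list(rmp = -69.5, peak = 45.4, apd25 = 2.5, apd50 = 8.1,
                   apd75 = 99.6, apd90 = 166.0)
  do.call(ap_shape_params, utils::modifyList(defaults, list(...)))
}
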