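#' Unpaired two-sample t-test with variance-equality handling
#'
#' Student (pooled) or Welch two-sample t-test. In `"auto"` mode an F-test
#' of variance equality at the 0.05 level decides: Welch when rejected,
#' pooled otherwise — mirroring the common "equal or unequal variances as
#' appropriate" reporting convention.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param equal_var `"auto"`, `"equal"`, or `"unequal"`.
#' @return List of class `ephys_test`: `statistic`, `df`, `p_two_sided`,
#'   `method` (`"pooled_t"` or `"welch_t"`).
#' @export
unpaired_t <- function(a, b, equal_var = c("auto", "equal", "unequal")) {
  equal_var <- match.arg(equal_var)
  if (length(a) < 2L || length(b) < 2L)
    stop("unpaired_t: each group needs at least 2 values")
  if (sd(a) == 0 && sd(b) == 0) {
    warning("unpaired_t: both groups have zero variance; test degenerate")
    same <- mean(a) == mean(b)
    return(structure(list(statistic = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                          df = length(a) + length(b) - 2,
                          p_two_sided = if (same) 1 else 0,
                          method = "pooled_t"),
                     class = "ephys_test"))
  }
  pooled <- switch(equal_var,
                   equal = TRUE,
                   unequal = FALSE,
                   auto = var.test(a, b)$p.value >= 0.05)
  tt <- t.test(a, b, var.equal = pooled)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value,
                 method = if (pooled) "pooled_t" else "welch_t"),
            class = "ephys_test")
}

#' Paired t-test
#'
#' t-test on the within-cell differences `post - pre`, as used for drug
#' pre/post comparisons on the same myocytes.
#'
#' @param pre,post numeric vectors of equal length (>= 2).
#' @return List of class `ephys_test` (method `"paired_t"`).
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post))
    stop("paired_t: pre and post must have equal length")
  if (length(pre) < 2L) stop("paired_t: need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0) {
    if (any(d != 0))
      warning("paired_t: constant nonzero difference; |t| unbounded, p -> 0")
    degen <- if (all(d == 0)) list(statistic = 0, p = 1)
             else list(statistic = Inf * sign(d[1]), p = 0)
    return(structure(list(statistic = degen$statistic, df = length(d) - 1,
                          p_two_sided = degen$p, method = "paired_t"),
                     class = "ephys_test"))
  }
  tt <- t.test(post, pre, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_two_sided = tt$p.value, method = "paired_t"),
            class = "ephys_test")
}

#' @export
print.ephys_test <- function(x, ...) {
  cat(sprintf("%s: t = %.4g, df = %.4g, p = %.4g\n",
              x$method, x$statistic, x$df, x$p_two_sided))
  invisible(x)
}

#' Group summary with nested cell/animal counts
#'
#' Mean and standard error over cells (the analysis unit), with per-animal
#' counts echoed so reports can state "n cells from m mice".
#'
#' @param values per-cell values.
#' @param animals animal identifier for each cell.
#' @return List of class `group_summary`: `n_cells`, `n_animals`, `mean`,
#'   `sem`, `cells_per_animal` (named table).
#' @examples
#' group_report(c(1, 2, 3), c("m1", "m1", "m1"))$sem  # 0.577
#' @export
group_report <- function(values, animals) {
  if (!length(values)) stop("group_report: empty input")
  if (length(values) != length(animals))
    stop("group_report: every value must be mapped to an animal")
  if (anyNA(animals)) stop("group_report: unmapped cell (NA animal id)")
  structure(
    list(n_cells = length(values),
         n_animals = length(unique(animals)),
         mean = mean(values),
         sem = sd(values) / sqrt(length(values)),
         cells_per_animal = table(animals)),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g +/- %.4g (SEM), %d cells from %d animals\n",
              x$mean, x$sem, x$n_cells, x$n_animals))
  invisible(x)
}
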