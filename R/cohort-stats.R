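#' Descriptive statistics for a cohort of asymmetry ratios
#'
#' Computes the moment summary used to characterise each (group, measure)
#' cell: n, mean, sample SD, median, sample variance, skewness and excess
#' kurtosis. Skewness is the adjusted Fisher-Pearson standardized third
#' moment, `g1 * sqrt(n(n-1))/(n-2)` with `g1 = m3/m2^(3/2)`; kurtosis is
#' the adjusted *excess* kurtosis (0 for a normal sample). Both are `NA`
#' (with `degenerate = TRUE`) for constant input, where the standardized
#' moments are undefined.
#'
#' @param values numeric vector, `length >= 2`.
#' @return an object of class `cohort_summary` (a named list).
#' @examples
#' cohort_summary(c(1, 2, 3, 4, 5))
#' @export
cohort_summary <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L || anyNA(values))
    stop("need at least 2 non-missing values", call. = FALSE)
  v <- stats::var(values)
  degenerate <- v == 0
  structure(
    list(n = n,
         mean = mean(values),
         sd = sqrt(v),
         median = median(values),
         variance = v,
         skewness = if (degenerate) NA_real_ else sample_skewness(values),
         kurtosis = if (degenerate || n < 4L) NA_real_
                    else sample_excess_kurtosis(values),
         degenerate = degenerate),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<cohort_summary> n = %d\n", x$n))
  vals <- unlist(x[c("mean", "sd", "median", "variance", "skewness",
                     "kurtosis")])
  print(signif(vals, digits))
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  data.frame(n = x$n, mean = x$mean, sd = x$sd, median = x$median,
             variance = x$variance, skewness = x$skewness,
             kurtosis = x$kurtosis)
}

# adjusted Fisher-Pearson standardized third moment (needs n >= 3)
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# adjusted excess kurtosis (zero for a normal sample; needs n >= 4)
sample_excess_kurtosis <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g2 <- mean((x - m)^4) / m2^2 - 3
  ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
}

#' Percentile of a ratio sample
#'
#' Order-statistic percentile with the linear-interpolation convention
#' (`stats::quantile` type 7) by default. The raw order-statistic
#' convention (type 1) is exposed via `interpolate = FALSE` because with
#' small reference cohorts (a few dozen controls) the two can differ
#' materially at the 5th percentile that defines the screening cutoffs.
#'
#' @param values non-empty numeric vector.
#' @param probe percentile in (0, 100); may be a vector.
#' @param interpolate `TRUE` for linear interpolation between closest ranks
#'   (default), `FALSE` for the raw (inverse-ECDF) order statistic.
#' @return percentile value(s), unnamed.
#' @export
ratio_percentile <- function(values, probe, interpolate = TRUE) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("'values' must be non-empty without NA", call. = FALSE)
  if (any(probe <= 0 | probe >= 100))
    stop("'probe' must lie strictly between 0 and 100", call. = FALSE)
  unname(quantile(values, probe / 100, type = if (interpolate) 7L else 1L))
}

#' Percentile grid of a ratio sample
#'
#' The standard reporting grid: 5th, 10th, 25th, 50th, 75th, 90th and 95th
#' percentiles.
#'
#' @inheritParams ratio_percentile
#' @param probes percentiles to report.
#' @return named numeric vector, one element per probe.
#' @export
percentile_grid <- function(values, probes = c(5, 10, 25, 50, 75, 90, 95),
                            interpolate = TRUE) {
  setNames(ratio_percentile(values, probes, interpolate),
           paste0("p", probes))
}

#' Mann-Whitney U test for two independent cohorts
#'
#' Two-sided test of the intergroup difference in ratio distributions. For
#' small untied samples (combined n up to `exact_limit`) the p-value comes
#' from the exact null distribution of U (equivalent to exhaustive
#' enumeration of rank assignments); otherwise the tie-corrected normal
#' approximation is used. Computation is delegated to
#' [stats::wilcox.test()], whose W statistic is the Mann-Whitney U for the
#' first sample.
#'
#' @param a,b numeric samples, non-empty.
#' @param exact_limit largest combined sample size for the exact path
#'   (default 20); ties always force the normal approximation.
#' @return an object of class `mann_whitney`: list with `u_statistic`,
#'   `p_value`, `method` (`"exact_enumeration"` or
#'   `"normal_approx_tie_corrected"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))   # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b, exact_limit = 20) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L || anyNA(a) || anyNA(b))
    stop("both samples must be non-empty without NA", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && (length(a) + length(b)) <= exact_limit
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = !use_exact))
  structure(
    list(u_statistic = unname(wt$statistic),
         p_value = min(1, wt$p.value),
         method = if (use_exact) "exact_enumeration"
                  else "normal_approx_tie_corrected",
         n1 = length(a), n2 = length(b)),
    class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s]\n",
              x$u_statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Compare two cohorts on one asymmetry measure
#'
#' Builds the full descriptive comparison for one measure: per-cohort moment
#' summaries, the difference between the cohort means (control minus
#' patient), and the Mann-Whitney intergroup test.
#'
#' @param control,tmd numeric ratio samples for the two cohorts.
#' @param measure label for the measure (e.g. `"bR-MEPs%"` or `"ipJJ%"`).
#' @return an object of class `cohort_comparison`.
#' @export
compare_cohorts <- function(control, tmd, measure = "") {
  cs <- cohort_summary(control)
  ts <- cohort_summary(tmd)
  structure(
    list(measure = measure, control = cs, tmd = ts,
         diff_means = cs$mean - ts$mean,
         test = mann_whitney(control, tmd)),
    class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort comparison%s\n",
              if (nzchar(x$measure)) paste0(": ", x$measure) else ""))
  print(signif(as.matrix(as.data.frame(x)[, -1]), digits))
  cat(sprintf("difference between means (control - TMD): %.3g\n",
              x$diff_means))
  print(x$test)
  invisible(x)
}

#' @export
as.data.frame.cohort_comparison <- function(x, ...) {
  out <- rbind(cbind(group = "control", as.data.frame(x$control)),
               cbind(group = "TMD", as.data.frame(x$tmd)))
  if (nzchar(x$measure)) out <- cbind(measure = x$measure, out)
  rownames(out) <- NULL
  out
}
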