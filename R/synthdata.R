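# Largest skewness a skew-normal can attain: the |delta| -> 1 limit of
# (4-pi)/2 * (delta*sqrt(2/pi))^3 / (1 - 2 delta^2/pi)^(3/2).
SKEW_NORMAL_MAX_SKEWNESS <- 0.9952717

#' Fit a skew-normal distribution to target moments
#'
#' Closed-form moment inversion: given a target mean, SD and skewness, the
#' direct parameters (location xi, scale omega, shape alpha) are recovered
#' from the skew-normal moment equations so that the analytic moments of
#' the returned distribution equal the targets exactly. Zero skewness
#' collapses to the normal distribution. The family's skewness range is
#' bounded (about |0.995|); infeasible targets raise an error suggesting
#' the truncated-normal fallback family.
#'
#' @param mean,sd,skewness target moments (`sd > 0`).
#' @return object of class `sn_params`: list with `xi`, `omega`, `alpha`,
#'   `delta` and the `target` moments.
#' @examples
#' p <- fit_skew_normal(0.24, 0.14, 0.79)
#' sn_moments(p)   # recovers (0.24, 0.14, 0.79)
#' @export
fit_skew_normal <- function(mean, sd, skewness = 0) {
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  if (abs(skewness) > SKEW_NORMAL_MAX_SKEWNESS)
    stop(sprintf(
      "skewness %.3g is infeasible for the skew-normal family (|skewness| <= %.4g); use family = 'truncated_normal'",
      skewness, SKEW_NORMAL_MAX_SKEWNESS), call. = FALSE)
  if (skewness == 0) {
    delta <- 0
  } else {
    g23 <- abs(skewness)^(2/3)
    a23 <- ((4 - pi) / 2)^(2/3)
    delta <- sign(skewness) * sqrt((pi / 2) * g23 / (g23 + a23))
  }
  omega <- sd / sqrt(1 - 2 * delta^2 / pi)
  xi <- mean - omega * delta * sqrt(2 / pi)
  structure(
    list(xi = xi, omega = omega,
         alpha = delta / sqrt(1 - delta^2), delta = delta,
         target = c(mean = mean, sd = sd, skewness = skewness)),
    class = "sn_params")
}

#' Analytic moments of fitted skew-normal parameters
#'
#' @param params an `sn_params` object from [fit_skew_normal()].
#' @return named vector `c(mean, sd, skewness)`.
#' @export
sn_moments <- function(params) {
  stopifnot(inherits(params, "sn_params"))
  b <- sqrt(2 / pi)
  mz <- params$delta * b
  vz <- 1 - mz^2
  c(mean = params$xi + params$omega * mz,
    sd = params$omega * sqrt(vz),
    skewness = (4 - pi) / 2 * mz^3 / vz^1.5)
}

#' Specify a ratio distribution by its moments
#'
#' A `ratio_spec` describes one (group, measure) asymmetry-ratio
#' distribution by mean, SD and skewness, together with the sampling family
#' used to realize it. With `family = "auto"` (default) the skew-normal is
#' used whenever the target skewness is feasible for that family; otherwise
#' the spec falls back to a mean/SD-matched normal truncated to positive
#' values and the skewness target is dropped (recorded in
#' `skewness_matched`).
#'
#' @param mean,sd,skewness target moments of the ratio distribution.
#' @param family `"auto"`, `"skew_normal"` or `"truncated_normal"`.
#' @param group,measure optional labels carried through for provenance.
#' @return object of class `ratio_spec`.
#' @export
ratio_spec <- function(mean, sd, skewness = 0,
                       family = c("auto", "skew_normal", "truncated_normal"),
                       group = NULL, measure = NULL) {
  family <- match.arg(family)
  if (sd <= 0) stop("'sd' must be positive", call. = FALSE)
  feasible <- abs(skewness) <= SKEW_NORMAL_MAX_SKEWNESS
  if (family == "auto")
    family <- if (feasible) "skew_normal" else "truncated_normal"
  if (family == "skew_normal" && !feasible)
    stop("skewness infeasible for skew_normal; use family = 'truncated_normal' or 'auto'",
         call. = FALSE)
  params <- if (family == "skew_normal") fit_skew_normal(mean, sd, skewness)
            else NULL
  structure(
    list(mean = mean, sd = sd, skewness = skewness, family = family,
         skewness_matched = family == "skew_normal",
         params = params, group = group, measure = measure),
    class = "ratio_spec")
}

#' @export
print.ratio_spec <- function(x, ...) {
  cat(sprintf("<ratio_spec>%s%s %s: mean %.3g, sd %.3g, skewness %.3g%s\n",
              if (is.null(x$group)) "" else paste0(" ", x$group),
              if (is.null(x$measure)) "" else paste0(" ", x$measure),
              x$family, x$mean, x$sd, x$skewness,
              if (x$skewness_matched) "" else " (skewness target dropped)"))
  invisible(x)
}

#' Draw asymmetry ratios from a ratio specification
#'
#' Samples from the spec's family; skew-normal draws use the
#' delta-representation (`delta * |Z0| + sqrt(1 - delta^2) * Z1`). Negative
#' draws are rejected and redrawn, enforcing the positivity of amplitude
#' ratios; for the cohorts of interest the rejected mass is well below 1%,
#' so sample moments still converge to the spec targets.
#'
#' @param n number of draws.
#' @param spec a [ratio_spec()] (or an `sn_params` object, drawn without
#'   truncation adjustments beyond positivity).
#' @param seed optional RNG seed for reproducibility.
#' @return numeric vector of `n` positive ratios.
#' @export
sample_ratios <- function(n, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(spec, "sn_params"))
    spec <- structure(list(family = "skew_normal", params = spec,
                           mean = NA, sd = NA), class = "ratio_spec")
  stopifnot(inherits(spec, "ratio_spec"), n >= 1)
  draw <- function(m) {
    if (spec$family == "skew_normal") {
      p <- spec$params
      z <- p$delta * abs(rnorm(m)) + sqrt(1 - p$delta^2) * rnorm(m)
      p$xi + p$omega * z
    } else {
      rnorm(m, spec$mean, spec$sd)
    }
  }
  out <- draw(n)
  bad <- out < 0
  while (any(bad)) {
    out[bad] <- draw(sum(bad))
    bad <- out < 0
  }
  out
}

#' Published group-level ratio moments
#'
#' The reference moment table for the two asymmetry measures in the two
#' study cohorts (33 TMD patients, 36 controls): mean, SD, median, skewness
#' and excess kurtosis of bR-MEPs% and ipJJ% per group. These moments
#' calibrate the synthetic-cohort generator; kurtosis is reported but not
#' matched by the generator (mean/SD/skewness matching only). Note the TMD
#' bR-MEPs% skewness (-1.7) exceeds the skew-normal feasible range, so
#' `auto` specs for that cell fall back to the truncated normal.
#'
#' @return data frame with columns `measure`, `group`, `n`, `mean`, `sd`,
#'   `median`, `skewness`, `kurtosis`.
#' @export
published_ratio_moments <- function() {
  data.frame(
    measure = rep(c("bR-MEPs%", "ipJJ%"), each = 2),
    group = rep(c("tmd", "control"), 2),
    n = c(33L, 36L, 33L, 36L),
    mean = c(0.91, 0.93, 0.24, 0.61),
    sd = c(0.22, 0.12, 0.14, 0.20),
    median = c(0.92, 0.90, 0.23, 0.60),
    skewness = c(-1.7, 1.5, 0.79, 0.21),
    kurtosis = c(4.7, 3.13, -0.11, -1.1),
    stringsAsFactors = FALSE)
}

#' Ratio spec for one published (group, measure) cell
#'
#' @param group `"control"` or `"tmd"`.
#' @param measure `"ipJJ%"` or `"bR-MEPs%"`.
#' @param family passed to [ratio_spec()].
#' @return a [ratio_spec()].
#' @examples
#' published_ratio_spec("tmd", "ipJJ%")
#' @export
published_ratio_spec <- function(group = c("control", "tmd"),
                                 measure = c("ipJJ%", "bR-MEPs%"),
                                 family = "auto") {
  group <- match.arg(group)
  measure <- match.arg(measure)
  tab <- published_ratio_moments()
  row <- tab[tab$group == group & tab$measure == measure, ]
  ratio_spec(row$mean, row$sd, row$skewness, family = family,
             group = group, measure = measure)
}

#' Published group-level amplitude means and SDs
#'
#' Reference-side and contralateral peak-to-peak amplitudes (mV) of the
#' intercuspal jaw jerk and the trigeminal-root MEPs in the two study
#' cohorts. The reference side is the pain side for the TMD group and the
#' non-preferred masticatory side for controls.
#'
#' @return data frame with columns `group`, `test`, `side`, `mean`, `sd`.
#' @export
published_amplitudes <- function() {
  data.frame(
    group = rep(c("control", "tmd"), each = 4),
    test = rep(c("JJ", "JJ", "MEP", "MEP"), 2),
    side = rep(c("reference", "contralateral"), 4),
    mean = c(0.8, 1.3, 4.4, 4.7, 0.4, 1.5, 4.2, 5.2),
    sd = c(0.5, 0.6, 1.9, 2.1, 0.4, 1.1, 2.9, 2.5),
    stringsAsFactors = FALSE)
}

#' Subject-level amplitude generator specification
#'
#' Bundles the bilateral JJ and MEP amplitude means and SDs used by
#' [sample_subjects()]. `amplitude_spec("control")` and
#' `amplitude_spec("tmd")` load the published group values; any field can
#' be overridden.
#'
#' @param group `"control"` or `"tmd"` (selects published defaults), or
#'   `"custom"`.
#' @param jj_ref_mean,jj_ref_sd,jj_contra_mean,jj_contra_sd jaw-jerk
#'   amplitude moments (mV).
#' @param mep_ref_mean,mep_ref_sd,mep_contra_mean,mep_contra_sd MEP
#'   amplitude moments (mV).
#' @return object of class `amplitude_spec`.
#' @export
amplitude_spec <- function(group = c("control", "tmd", "custom"),
                           jj_ref_mean = NULL, jj_ref_sd = NULL,
                           jj_contra_mean = NULL, jj_contra_sd = NULL,
                           mep_ref_mean = NULL, mep_ref_sd = NULL,
                           mep_contra_mean = NULL, mep_contra_sd = NULL) {
  group <- match.arg(group)
  vals <- list(jj_ref_mean = jj_ref_mean, jj_ref_sd = jj_ref_sd,
               jj_contra_mean = jj_contra_mean, jj_contra_sd = jj_contra_sd,
               mep_ref_mean = mep_ref_mean, mep_ref_sd = mep_ref_sd,
               mep_contra_mean = mep_contra_mean,
               mep_contra_sd = mep_contra_sd)
  if (group != "custom") {
    tab <- published_amplitudes()
    tab <- tab[tab$group == group, ]
    pick <- function(test, side, col)
      tab[tab$test == test & tab$side == side, col]
    defaults <- list(
      jj_ref_mean = pick("JJ", "reference", "mean"),
      jj_ref_sd = pick("JJ", "reference", "sd"),
      jj_contra_mean = pick("JJ", "contralateral", "mean"),
      jj_contra_sd = pick("JJ", "contralateral", "sd"),
      mep_ref_mean = pick("MEP", "reference", "mean"),
      mep_ref_sd = pick("MEP", "reference", "sd"),
      mep_contra_mean = pick("MEP", "contralateral", "mean"),
      mep_contra_sd = pick("MEP", "contralateral", "sd"))
    for (k in names(vals)) if (is.null(vals[[k]])) vals[[k]] <- defaults[[k]]
  }
  if (any(vapply(vals, is.null, logical(1))))
    stop("custom amplitude_spec requires all eight mean/sd fields",
         call. = FALSE)
  means <- unlist(vals[grep("_mean$", names(vals))])
  sds <- unlist(vals[grep("_sd$", names(vals))])
  if (any(means < 0) || any(sds <= 0))
    stop("amplitude means must be >= 0 and sds > 0", call. = FALSE)
  structure(c(vals, list(group = group)), class = "amplitude_spec")
}

#' Generate synthetic subject records
#'
#' Draws per-subject bilateral JJ and MEP peak-to-peak amplitudes from
#' normal distributions at the spec's means/SDs. Within-subject
#' correlations between sides (`side_correlation`, shared by JJ and MEP)
#' and between the two tests on the same side (`jj_mep_correlation`)
#' default to 0 - the source cohorts report no correlation structure.
#' Negative draws are truncated at a small positive floor, preserving
#' amplitude positivity.
#'
#' @param n number of subjects.
#' @param spec an [amplitude_spec()]; default is the control group.
#' @param seed optional RNG seed.
#' @param side_correlation,jj_mep_correlation within-subject correlations
#'   in `[-1, 1]`.
#' @param floor truncation floor in mV (default 0.01).
#' @return data frame of subject records: `subject_id`, `group`,
#'   `reference_side`, `reference_side_kind`, `jj_ip_ref`, `jj_ip_contra`,
#'   `mep_ref`, `mep_contra`, `unit`.
#' @export
sample_subjects <- function(n, spec = amplitude_spec("control"),
                            seed = NULL, side_correlation = 0,
                            jj_mep_correlation = 0, floor = 0.01) {
  stopifnot(inherits(spec, "amplitude_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- c(spec$jj_ref_mean, spec$jj_contra_mean, spec$mep_ref_mean,
          spec$mep_contra_mean)
  sd4 <- c(spec$jj_ref_sd, spec$jj_contra_sd, spec$mep_ref_sd,
           spec$mep_contra_sd)
  # order: jj_ref, jj_contra, mep_ref, mep_contra
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- side_correlation
  corr[3, 4] <- corr[4, 3] <- side_correlation
  corr[1, 3] <- corr[3, 1] <- jj_mep_correlation
  corr[2, 4] <- corr[4, 2] <- jj_mep_correlation
  sigma <- corr * tcrossprod(sd4)
  amps <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  amps <- matrix(pmax(amps, floor), nrow = n)
  data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = spec$group,
    reference_side = sample(c("right", "left"), n, replace = TRUE),
    reference_side_kind = if (identical(spec$group, "tmd")) "pain_side"
                          else "non_preferred_side",
    jj_ip_ref = amps[, 1], jj_ip_contra = amps[, 2],
    mep_ref = amps[, 3], mep_contra = amps[, 4],
    unit = "mV", stringsAsFactors = FALSE)
}

#' Specification of a synthetic evoked-response waveform
#'
#' Describes one biphasic evoked response: onset latency, oscillation
#' period, target peak-to-peak amplitude and per-trial additive Gaussian
#' noise, within a given acquisition window. Defaults follow the clinical
#' acquisition settings (50 ms window for JJ, 20 ms for MEP) with a 10 kHz
#' sampling rate comfortably above the 2 kHz analog bandwidth.
#'
#' @param peak_to_peak_mv target peak-to-peak amplitude of the clean
#'   averaged trace (mV).
#' @param latency_ms response onset latency (ms); the response (one full
#'   period) must fit inside the window.
#' @param period_ms duration of the biphasic deflection (ms).
#' @param noise_sd_mv SD of additive white noise per trial (mV).
#' @param window_ms acquisition window (ms).
#' @param sampling_rate sampling rate (Hz).
#' @param side,test_type recording metadata.
#' @return object of class `waveform_spec`.
#' @export
waveform_spec <- function(peak_to_peak_mv, latency_ms = 7, period_ms = 8,
                          noise_sd_mv = 0, window_ms = 50,
                          sampling_rate = 10000, side = "right",
                          test_type = "JJ") {
  if (peak_to_peak_mv < 0) stop("'peak_to_peak_mv' must be >= 0", call. = FALSE)
  if (noise_sd_mv < 0) stop("'noise_sd_mv' must be >= 0", call. = FALSE)
  if (latency_ms < 0 || latency_ms + period_ms > window_ms)
    stop("response (latency + period) must lie within the acquisition window",
         call. = FALSE)
  structure(
    list(peak_to_peak_mv = peak_to_peak_mv, latency_ms = latency_ms,
         period_ms = period_ms, noise_sd_mv = noise_sd_mv,
         window_ms = window_ms, sampling_rate = sampling_rate,
         side = side, test_type = test_type),
    class = "waveform_spec")
}

#' Synthesize a multi-trial evoked recording
#'
#' Builds `n_trials` sweeps of a clean biphasic deflection (one sine period
#' starting at the latency, rescaled so that the *sampled* clean trace has
#' exactly the spec's peak-to-peak amplitude) plus independent white noise
#' per trial. Averaging the trials therefore recovers the spec amplitude
#' with noise shrinking as `1/sqrt(n_trials)`.
#'
#' @param spec a [waveform_spec()].
#' @param n_trials number of sweeps (clinical protocols use 10 or 20).
#' @param seed optional RNG seed.
#' @return a [trial_set].
#' @export
synthesize_waveform <- function(spec, n_trials = 10, seed = NULL) {
  stopifnot(inherits(spec, "waveform_spec"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_samp <- round(spec$window_ms / 1000 * spec$sampling_rate)
  t_ms <- (seq_len(n_samp) - 1L) / spec$sampling_rate * 1000
  clean <- numeric(n_samp)
  active <- t_ms >= spec$latency_ms & t_ms <= spec$latency_ms + spec$period_ms
  clean[active] <- sin(2 * pi * (t_ms[active] - spec$latency_ms) /
                         spec$period_ms)
  span <- max(clean) - min(clean)
  if (span > 0 && spec$peak_to_peak_mv > 0)
    clean <- clean * spec$peak_to_peak_mv / span
  else clean[] <- 0
  trial_set(lapply(seq_len(n_trials), function(i)
    emg_trace(clean + rnorm(n_samp, 0, spec$noise_sd_mv),
              spec$sampling_rate, spec$side, spec$test_type,
              spec$window_ms)))
}

#' Read and write subject-record tables
#'
#' Subject records are CSV rows with `subject_id`, `group`,
#' `reference_side`, `reference_side_kind`, `jj_ip_ref`, `jj_ip_contra`,
#' `mep_ref`, `mep_contra` and `unit` (`mV` or `uV`). Amplitudes recorded
#' in microvolts are converted to mV on read.
#'
#' @param path file path.
#' @return `read_subjects()` returns a data frame in mV.
#' @export
read_subjects <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("jj_ip_ref", "jj_ip_contra", "mep_ref", "mep_contra")
  if (!all(need %in% names(df)))
    stop("subject file must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if ("unit" %in% names(df)) {
    bad <- !df$unit %in% c("mV", "uV")
    if (any(bad))
      stop("unknown amplitude unit(s): ",
           paste(unique(df$unit[bad]), collapse = ", "), call. = FALSE)
    scale <- ifelse(df$unit == "uV", 1e-3, 1)
    for (col in need) df[[col]] <- df[[col]] * scale
    df$unit <- "mV"
  }
  df
}

#' @rdname read_subjects
#' @param records data frame of subject records (mV).
#' @export
write_subjects <- function(records, path) {
  records$unit <- "mV"
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
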