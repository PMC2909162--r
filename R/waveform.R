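#' Construct a single evoked-EMG sweep
#'
#' An `emg_trace` holds one recorded sweep for one masseter side: a vector of
#' signed voltages in mV, the sampling rate, the acquisition window and the
#' recording metadata. Acquisition settings used in the clinic are a 50 ms
#' window for the jaw-jerk reflex and a 20 ms window for trigeminal-root
#' motor evoked potentials; the window length must agree with
#' `length(samples) / sampling_rate` to within one sample period.
#'
#' @param samples numeric vector of voltages (mV), non-empty.
#' @param sampling_rate sampling rate in Hz, positive.
#' @param side `"left"` or `"right"`.
#' @param test_type `"JJ"` (jaw jerk), `"MEP"` (motor evoked potential) or
#'   `"clench"` (maximal voluntary contraction trial).
#' @param window_ms acquisition window in ms; defaults to the duration
#'   implied by `samples` and `sampling_rate`.
#' @return an object of class `emg_trace`.
#' @examples
#' tr <- emg_trace(sin(seq(0, 2 * pi, length.out = 200)),
#'                 sampling_rate = 4000, side = "right", test_type = "JJ")
#' peak_to_peak(tr)
#' @export
emg_trace <- function(samples, sampling_rate, side = c("right", "left"),
                      test_type = c("JJ", "MEP", "clench"),
                      window_ms = NULL) {
  side <- match.arg(side)
  test_type <- match.arg(test_type)
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples))
    stop("'samples' must be a non-empty numeric vector without NA", call. = FALSE)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("'sampling_rate' must be a single positive number (Hz)", call. = FALSE)
  implied_ms <- length(samples) / sampling_rate * 1000
  if (is.null(window_ms)) window_ms <- implied_ms
  period_ms <- 1000 / sampling_rate
  if (abs(implied_ms - window_ms) > period_ms + 1e-9)
    stop(sprintf(
      "window_ms (%.4g) inconsistent with %d samples at %g Hz (%.4g ms)",
      window_ms, length(samples), sampling_rate, implied_ms), call. = FALSE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         window_ms = window_ms, side = side, test_type = test_type),
    class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("<emg_trace> %s %s: %d samples @ %g Hz, %.3g ms window\n",
              x$test_type, x$side, length(x$samples), x$sampling_rate,
              x$window_ms))
  cat(sprintf("  peak-to-peak %.4g mV\n", peak_to_peak(x)))
  invisible(x)
}

#' Bundle repeated sweeps of one test into a trial set
#'
#' All trials must share side, test type, sampling rate, window and length;
#' averaging and MVC estimation operate on these sets.
#'
#' @param trials a list of [emg_trace] objects (or several traces passed
#'   directly as `...`-style list).
#' @return an object of class `trial_set` with attribute `n_trials`.
#' @export
trial_set <- function(trials) {
  if (inherits(trials, "emg_trace")) trials <- list(trials)
  if (!is.list(trials) || length(trials) == 0L)
    stop("'trials' must be a non-empty list of emg_trace objects", call. = FALSE)
  if (!all(vapply(trials, inherits, logical(1), "emg_trace")))
    stop("all elements must be emg_trace objects", call. = FALSE)
  ref <- trials[[1L]]
  for (tr in trials[-1L]) {
    if (length(tr$samples) != length(ref$samples) ||
        tr$sampling_rate != ref$sampling_rate ||
        tr$side != ref$side || tr$test_type != ref$test_type ||
        abs(tr$window_ms - ref$window_ms) > 1e-9)
      stop("trials are dimensionally mismatched (length, rate, window, side or test_type differ)",
           call. = FALSE)
  }
  structure(list(trials = trials, n_trials = length(trials)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  ref <- x$trials[[1L]]
  cat(sprintf("<trial_set> %d x %s %s trials (%d samples @ %g Hz)\n",
              x$n_trials, ref$test_type, ref$side, length(ref$samples),
              ref$sampling_rate))
  invisible(x)
}

#' Average repeated trials into one trace
#'
#' Evoked responses are routinely averaged over repeated stimulations (20
#' trials for the jaw jerk in the normative protocol, 10 in the clinical
#' screening protocol) before the peak-to-peak amplitude is read off; the
#' average is the pointwise arithmetic mean and metadata are preserved.
#'
#' @param trials a [trial_set].
#' @return an [emg_trace]; the number of averaged trials is recorded in the
#'   `"n_trials"` attribute.
#' @export
average_trials <- function(trials) {
  if (!inherits(trials, "trial_set")) trials <- trial_set(trials)
  mat <- vapply(trials$trials, function(tr) tr$samples,
                numeric(length(trials$trials[[1L]]$samples)))
  mat <- matrix(mat, ncol = trials$n_trials)
  ref <- trials$trials[[1L]]
  out <- emg_trace(rowMeans(mat), ref$sampling_rate, ref$side, ref$test_type,
                   ref$window_ms)
  attr(out, "n_trials") <- trials$n_trials
  out
}

#' Peak-to-peak amplitude of a trace
#'
#' The diagnostic amplitude is the maximal positive peak minus the maximal
#' negative peak of the (averaged) trace, in mV. An optional search window
#' restricts the scan to a post-stimulus interval; by default the whole
#' acquisition window is scanned.
#'
#' @param trace an [emg_trace], or a bare numeric vector of samples.
#' @param search_window_ms optional `c(from, to)` in ms (relative to sweep
#'   onset); must lie within the acquisition window. Only available when
#'   `trace` is an [emg_trace].
#' @return non-negative amplitude in the units of the samples (mV).
#' @export
peak_to_peak <- function(trace, search_window_ms = NULL) {
  if (is.numeric(trace)) {
    if (!is.null(search_window_ms))
      stop("search_window_ms requires an emg_trace (sampling rate unknown)",
           call. = FALSE)
    samples <- trace
    if (length(samples) == 0L)
      stop("empty trace", call. = FALSE)
  } else {
    stopifnot(inherits(trace, "emg_trace"))
    samples <- trace$samples
    if (!is.null(search_window_ms)) {
      if (length(search_window_ms) != 2L || diff(search_window_ms) <= 0)
        stop("search_window_ms must be c(from, to) with from < to", call. = FALSE)
      if (search_window_ms[1L] < 0 || search_window_ms[2L] > trace$window_ms + 1e-9)
        stop("search window lies outside the acquisition window", call. = FALSE)
      t_ms <- (seq_along(samples) - 1L) / trace$sampling_rate * 1000
      keep <- t_ms >= search_window_ms[1L] & t_ms <= search_window_ms[2L]
      if (!any(keep))
        stop("search window contains no samples", call. = FALSE)
      samples <- samples[keep]
    }
  }
  max(samples) - min(samples)
}

#' Estimate the maximal voluntary contraction level
#'
#' MVC is measured from a few brief maximal clenches (five, up to 3 s each,
#' in the reference protocol): the level is the mean rectified
#' (absolute-value) EMG amplitude averaged over the clench trials. The
#' rectified mean - rather than RMS - defines the level here; see
#' `method`.
#'
#' @param clench_traces a [trial_set] of clench recordings (a single
#'   [emg_trace] is accepted).
#' @param facilitation_target fraction of MVC at which reflex facilitation
#'   trials are held (default 0.20).
#' @param method `"rectified_mean"` (default) or `"rms"`.
#' @return an object of class `mvc_estimate`: list with `mvc_level` (mV),
#'   `n_clenches`, `facilitation_target`, `method`.
#' @export
estimate_mvc <- function(clench_traces, facilitation_target = 0.20,
                         method = c("rectified_mean", "rms")) {
  method <- match.arg(method)
  if (!inherits(clench_traces, "trial_set"))
    clench_traces <- trial_set(clench_traces)
  if (facilitation_target <= 0 || facilitation_target >= 1)
    stop("'facilitation_target' must lie in (0, 1)", call. = FALSE)
  level_of <- switch(method,
    rectified_mean = function(s) mean(abs(s)),
    rms = function(s) sqrt(mean(s^2)))
  per_trial <- vapply(clench_traces$trials, function(tr) level_of(tr$samples),
                      numeric(1))
  structure(
    list(mvc_level = mean(per_trial), n_clenches = clench_traces$n_trials,
         facilitation_target = facilitation_target, method = method),
    class = "mvc_estimate")
}

#' @export
print.mvc_estimate <- function(x, ...) {
  cat(sprintf("<mvc_estimate> %.4g mV (%s over %d clenches), facilitation target %g%% of MVC\n",
              x$mvc_level, x$method, x$n_clenches,
              100 * x$facilitation_target))
  invisible(x)
}

#' Check a facilitation trial against the MVC target
#'
#' Reflex facilitation trials are held at about 20% of the maximal voluntary
#' contraction under visual feedback. This check compares the mean rectified
#' amplitude of a trace with `facilitation_target * mvc_level` and reports
#' whether it falls within a relative tolerance band.
#'
#' @param trace an [emg_trace].
#' @param mvc an `mvc_estimate` from [estimate_mvc()]; `mvc_level` must be
#'   positive.
#' @param tolerance_frac relative half-width of the acceptance band
#'   (default 0.25, i.e. 15-25% of MVC for a 20% target).
#' @return `"within_target"`, `"below"` or `"above"`.
#' @export
check_facilitation <- function(trace, mvc, tolerance_frac = 0.25) {
  stopifnot(inherits(trace, "emg_trace"), inherits(mvc, "mvc_estimate"))
  if (mvc$mvc_level <= 0)
    stop("MVC level is zero: facilitation target undefined", call. = FALSE)
  if (tolerance_frac <= 0)
    stop("'tolerance_frac' must be positive", call. = FALSE)
  level <- mean(abs(trace$samples))
  target <- mvc$facilitation_target * mvc$mvc_level
  if (level < target * (1 - tolerance_frac)) "below"
  else if (level > target * (1 + tolerance_frac)) "above"
  else "within_target"
}

#' Read and write multi-trial EMG trace files
#'
#' Trace files are plain delimited text: `#`-prefixed header lines carry
#' `sampling_rate_hz`, `window_ms`, `side`, `test_type` and `unit`, followed
#' by a tab-separated table with one column per trial. Voltages recorded in
#' microvolts (`unit: uV`) are converted to mV on read; everything inside
#' the package is mV.
#'
#' @param path file path.
#' @return `read_trace_file()` returns a [trial_set].
#' @export
read_trace_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(hit) != 1L)
      stop(sprintf("trace file header must carry exactly one '%s' line", key),
           call. = FALSE)
    trimws(sub("^#[^:]*:", "", hit))
  }
  rate <- as.numeric(get("sampling_rate_hz"))
  window_ms <- as.numeric(get("window_ms"))
  side <- get("side")
  test_type <- get("test_type")
  unit <- get("unit")
  scale <- switch(unit, mV = 1, uV = 1e-3,
                  stop(sprintf("unknown unit '%s' (use mV or uV)", unit),
                       call. = FALSE))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t")
  trial_set(lapply(tab, function(col)
    emg_trace(as.numeric(col) * scale, rate, side, test_type, window_ms)))
}

#' @rdname read_trace_file
#' @param trials a [trial_set] to serialize.
#' @export
write_trace_file <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  ref <- trials$trials[[1L]]
  hdr <- c(
    sprintf("# sampling_rate_hz: %g", ref$sampling_rate),
    sprintf("# window_ms: %g", ref$window_ms),
    sprintf("# side: %s", ref$side),
    sprintf("# test_type: %s", ref$test_type),
    "# unit: mV")
  tab <- as.data.frame(lapply(trials$trials, function(tr) tr$samples))
  names(tab) <- sprintf("trial_%d", seq_len(trials$n_trials))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
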