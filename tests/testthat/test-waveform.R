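test_that("trial averaging is the pointwise mean and preserves metadata", {
  base <- sin(seq(0, 2 * pi, length.out = 100))
  ts <- trial_set(replicate(20, make_trace(base), simplify = FALSE))
  avg <- average_trials(ts)
  expect_equal(avg$samples, base)
  expect_identical(attr(avg, "n_trials"), 20L)
  expect_identical(avg$side, "right")
  expect_identical(avg$test_type, "JJ")

  # equal counts of opposite constant trials cancel exactly
  pm <- trial_set(c(replicate(5, const_trace(1), simplify = FALSE),
                    replicate(5, const_trace(-1), simplify = FALSE)))
  expect_equal(average_trials(pm)$samples, rep(0, 50))

  # noisy sinusoids: average equals the per-sample mean oracle, and the
  # residual sd shrinks like sigma/sqrt(n_trials)
  set.seed(42)
  sigma <- 0.5
  trials <- replicate(10, make_trace(base + rnorm(100, 0, sigma)),
                      simplify = FALSE)
  avg <- average_trials(trial_set(trials))
  oracle <- colMeans(do.call(rbind, lapply(trials, `[[`, "samples")))
  expect_equal(avg$samples, oracle)
  expect_lt(abs(sd(avg$samples - base) - sigma / sqrt(10)),
            0.4 * sigma / sqrt(10))
})

test_that("dimensionally mismatched trials are rejected", {
  a <- make_trace(rep(0, 50))
  expect_error(trial_set(list(a, make_trace(rep(0, 60)))), "mismatch")
  expect_error(trial_set(list(a, make_trace(rep(0, 50), side = "left"))),
               "mismatch")
  expect_error(trial_set(list(a, make_trace(rep(0, 50), rate = 2000))),
               "mismatch")
  expect_error(emg_trace(rep(0, 50), 1000, window_ms = 10), "inconsistent")
  expect_error(emg_trace(numeric(0), 1000), "non-empty")
})

test_that("peak_to_peak measures max positive minus max negative peak", {
  expect_equal(peak_to_peak(const_trace(3)), 0)

  # sampled sinusoid of amplitude A: within one sample step of 2A
  A <- 1.7
  n <- 400
  tr <- make_trace(A * sin(2 * pi * 3 * seq(0, 1, length.out = n)))
  expect_lt(abs(peak_to_peak(tr) - 2 * A), 2 * A * 2 * pi * 3 / n)

  # asymmetric biphasic wavelet: +2 / -1 peaks -> 3, equals brute-force scan
  w <- make_wavelet(2, 1)
  expect_equal(peak_to_peak(make_trace(w)), 3, tolerance = 1e-3)
  expect_equal(peak_to_peak(make_trace(w)), max(w) - min(w))
})

test_that("peak_to_peak is offset-invariant and gain-linear", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(80)
    offset <- runif(1, -5, 5)
    gain <- runif(1, 0.1, 10)
    expect_equal(peak_to_peak(x + offset), peak_to_peak(x))
    expect_equal(peak_to_peak(gain * x), gain * peak_to_peak(x))
  }
})

test_that("averaging commutes with peak_to_peak only for identical trials", {
  base <- make_wavelet(1.5, 0.8)
  identical_set <- trial_set(replicate(6, make_trace(base), simplify = FALSE))
  expect_equal(peak_to_peak(average_trials(identical_set)),
               peak_to_peak(make_trace(base)))

  # mixed-phase trials: averaged amplitude cannot exceed the largest single
  set.seed(8)
  for (i in 1:10) {
    trials <- replicate(5, make_trace(rnorm(60)), simplify = FALSE)
    avg_amp <- peak_to_peak(average_trials(trial_set(trials)))
    max_amp <- max(vapply(trials, peak_to_peak, numeric(1)))
    expect_lte(avg_amp, max_amp + 1e-12)
  }
})

test_that("search windows restrict the scan and are validated", {
  x <- c(rep(0, 100), rep(5, 100), rep(-5, 100), rep(0, 100))
  tr <- make_trace(x, rate = 4000)  # 100 ms window
  expect_equal(peak_to_peak(tr), 10)
  expect_equal(peak_to_peak(tr, c(0, 24)), 0)
  expect_equal(peak_to_peak(tr, c(20, 45)), 5)
  expect_error(peak_to_peak(tr, c(50, 500)), "outside")
  expect_error(peak_to_peak(tr, c(30, 30)), "from < to")
  expect_error(peak_to_peak(numeric(0)), "empty")
})

test_that("MVC estimation is the mean rectified level over clenches", {
  clench <- function(x) make_trace(x, type = "clench")
  five <- trial_set(replicate(5, clench(rep(1, 40)), simplify = FALSE))
  expect_equal(estimate_mvc(five)$mvc_level, 1.0)
  expect_identical(estimate_mvc(five)$n_clenches, 5L)

  alt <- trial_set(list(clench(rep(c(2, -2), 20))))
  expect_equal(estimate_mvc(alt)$mvc_level, 2.0)

  set.seed(9)
  traces <- replicate(5, clench(rnorm(40)), simplify = FALSE)
  est <- estimate_mvc(trial_set(traces))
  oracle <- mean(vapply(traces, function(tr) mean(abs(tr$samples)),
                        numeric(1)))
  expect_equal(est$mvc_level, oracle)

  # permutation invariance over trials
  perm <- sample(5)
  expect_equal(estimate_mvc(trial_set(traces[perm]))$mvc_level,
               est$mvc_level)

  # RMS variant differs for non-constant signals
  expect_gt(estimate_mvc(trial_set(traces), method = "rms")$mvc_level,
            est$mvc_level)
})

test_that("facilitation check classifies traces against the MVC target", {
  clench <- trial_set(replicate(5, const_trace(10, type = "clench"),
                                simplify = FALSE))
  mvc <- estimate_mvc(clench)  # 10 mV, target 20% -> 2 mV
  expect_identical(check_facilitation(const_trace(2), mvc), "within_target")
  expect_identical(check_facilitation(const_trace(0.5), mvc), "below")
  expect_identical(check_facilitation(const_trace(4), mvc), "above")

  # randomized traces agree with the direct inequality check
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(30, sd = runif(1, 0.1, 5))
    got <- check_facilitation(make_trace(x), mvc, tolerance_frac = 0.25)
    level <- mean(abs(x))
    want <- if (level < 2 * 0.75) "below"
            else if (level > 2 * 1.25) "above" else "within_target"
    expect_identical(got, want)
  }

  zero <- estimate_mvc(trial_set(list(const_trace(0, type = "clench"))))
  expect_error(check_facilitation(const_trace(1), zero), "zero")
})

test_that("trace files round-trip and microvolt inputs are converted", {
  set.seed(11)
  ts <- trial_set(replicate(3, make_trace(rnorm(40), rate = 2000),
                            simplify = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_file(ts, path)
  back <- read_trace_file(path)
  expect_identical(back$n_trials, 3L)
  expect_equal(back$trials[[1]]$samples, ts$trials[[1]]$samples,
               tolerance = 1e-6)
  expect_identical(back$trials[[1]]$side, "right")

  # a uV-labelled file comes back scaled to mV
  lines <- readLines(path)
  writeLines(sub("unit: mV", "unit: uV", lines), path)
  uv <- read_trace_file(path)
  expect_equal(uv$trials[[2]]$samples, ts$trials[[2]]$samples / 1000,
               tolerance = 1e-6)
})
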