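test_that("skew-normal moment inversion round-trips exactly", {
  # zero skewness reduces to the plain normal
  p0 <- fit_skew_normal(0.61, 0.2, 0)
  expect_equal(p0$alpha, 0)
  expect_equal(p0$xi, 0.61)
  expect_equal(p0$omega, 0.2)

  grid <- expand.grid(mean = c(0.24, 0.61, 0.93),
                      sd = c(0.05, 0.14, 0.3),
                      skewness = c(-0.9, -0.21, 0, 0.21, 0.79, 0.9))
  for (i in seq_len(nrow(grid))) {
    p <- fit_skew_normal(grid$mean[i], grid$sd[i], grid$skewness[i])
    expect_equal(unname(sn_moments(p)),
                 c(grid$mean[i], grid$sd[i], grid$skewness[i]),
                 tolerance = 1e-10)
  }

  # the printed TMD MEP skewness (-1.7) is outside the family's range
  expect_error(fit_skew_normal(0.91, 0.22, -1.7), "infeasible")
  expect_error(ratio_spec(0.91, 0.22, -1.7, family = "skew_normal"),
               "infeasible")
})

test_that("infeasible skewness triggers the truncated-normal fallback", {
  spec <- published_ratio_spec("tmd", "bR-MEPs%")
  expect_identical(spec$family, "truncated_normal")
  expect_false(spec$skewness_matched)
  spec_jj <- published_ratio_spec("tmd", "ipJJ%")
  expect_identical(spec_jj$family, "skew_normal")
  expect_true(spec_jj$skewness_matched)
})

test_that("sampled ratios are positive, seeded-deterministic and moment-matched", {
  spec <- published_ratio_spec("tmd", "ipJJ%")
  expect_identical(sample_ratios(1, spec, seed = 61),
                   sample_ratios(1, spec, seed = 61))

  x <- sample_ratios(1e5, spec, seed = 62)
  expect_true(all(x > 0))
  # positivity rejection discards ~1% of the mass near zero, so the sample
  # moments sit slightly above the targets; bands are absolute
  expect_lt(abs(mean(x) - 0.24), 0.01)
  expect_lt(abs(sd(x) - 0.14), 0.01)
  expect_lt(abs(cohort_summary(x)$skewness - 0.79), 0.1)

  # truncated-normal fallback still matches mean/sd (truncation mass ~0)
  y <- sample_ratios(1e5, published_ratio_spec("control", "bR-MEPs%"),
                     seed = 63)
  expect_equal(mean(y), 0.93, tolerance = 0.01)
  expect_equal(sd(y), 0.12, tolerance = 0.01)
})

test_that("control-spec cohorts place their 5th percentiles near the published cutoffs", {
  mep <- sample_ratios(1e4, published_ratio_spec("control", "bR-MEPs%"),
                       seed = 64)
  jj <- sample_ratios(1e4, published_ratio_spec("control", "ipJJ%"))
  expect_lt(abs(ratio_percentile(mep, 5) - 0.76), 0.05)
  expect_lt(abs(ratio_percentile(jj, 5) - 0.32), 0.05)
})

test_that("subject sampling respects the spec in the degenerate and bulk limits", {
  # sd -> 0: every subject sits at the means, ratios equal ratio-of-means
  tight <- amplitude_spec("custom",
                          jj_ref_mean = 0.4, jj_ref_sd = 1e-9,
                          jj_contra_mean = 1.5, jj_contra_sd = 1e-9,
                          mep_ref_mean = 4.2, mep_ref_sd = 1e-9,
                          mep_contra_mean = 5.2, mep_contra_sd = 1e-9)
  s <- sample_subjects(5, tight, seed = 65)
  expect_equal(s$jj_ip_ref, rep(0.4, 5), tolerance = 1e-6)
  expect_equal(side_ratio(s$mep_ref, s$mep_contra), rep(4.2 / 5.2, 5),
               tolerance = 1e-6)

  # TMD cohort: mean pain-side JJ over mean pain-side MEP ~ 9.5%; the
  # truncation floor lifts both means slightly (the MEP SD is large
  # relative to its mean), so the band is wider than pure MC noise
  tmd <- sample_subjects(1e4, amplitude_spec("tmd"), seed = 66)
  expect_lt(abs(mean(tmd$jj_ip_ref) / mean(tmd$mep_ref) - 0.095), 0.015)
  expect_true(all(tmd$jj_ip_ref >= 0.01))  # truncation floor
  expect_identical(unique(tmd$reference_side_kind), "pain_side")

  # seeded reproducibility
  expect_identical(sample_subjects(7, amplitude_spec("control"), seed = 67),
                   sample_subjects(7, amplitude_spec("control"), seed = 67))

  # within-subject correlation is honoured
  corr <- sample_subjects(4000, amplitude_spec("control"), seed = 68,
                          side_correlation = 0.7)
  expect_gt(cor(corr$jj_ip_ref, corr$jj_ip_contra), 0.5)
})

test_that("synthetic waveforms carry the spec amplitude through averaging", {
  spec <- waveform_spec(peak_to_peak_mv = 2.5, noise_sd_mv = 0)
  clean <- average_trials(synthesize_waveform(spec, n_trials = 5))
  expect_equal(peak_to_peak(clean), 2.5)

  # averaging 20 noisy trials shrinks the amplitude error ~ 1/sqrt(20)
  noisy_spec <- waveform_spec(peak_to_peak_mv = 2.5, noise_sd_mv = 0.4)
  set.seed(69)
  err <- replicate(40, {
    ts <- synthesize_waveform(noisy_spec, n_trials = 20)
    c(avg = abs(peak_to_peak(average_trials(ts)) - 2.5),
      single = abs(peak_to_peak(ts$trials[[1]]) - 2.5))
  })
  expect_lt(mean(err["avg", ]), mean(err["single", ]) / 2)

  expect_error(waveform_spec(1, latency_ms = 48, period_ms = 8),
               "within the acquisition window")
})

test_that("waveform synthesis round-trips through amplitude extraction to the ratio", {
  # two sides synthesized at a prescribed amplitude ratio recover it
  set.seed(70)
  for (i in 1:5) {
    target_ratio <- runif(1, 0.2, 1.1)
    contra_amp <- runif(1, 1, 5)
    ref <- synthesize_waveform(
      waveform_spec(target_ratio * contra_amp, noise_sd_mv = 0.05))
    contra <- synthesize_waveform(
      waveform_spec(contra_amp, side = "left", noise_sd_mv = 0.05))
    got <- side_ratio(peak_to_peak(average_trials(ref)),
                      peak_to_peak(average_trials(contra)))
    expect_equal(got, target_ratio, tolerance = 0.15)
  }
})
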