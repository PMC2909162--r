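---
title: "Two-step electrophysiological screening of orofacial pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step electrophysiological screening of orofacial pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(trigdiag)
```

## The diagnostic problem

Pain from temporomandibular disorders (TMD) presents with much the same
clinical picture as orofacial pain (OP) of other origins, including early
organic neurological disease. Two masseter-muscle EMG tests probe
complementary levels of the trigeminal system:

* **bR-MEPs** — motor evoked potentials of both trigeminal roots after
  bilateral electrical transcranial stimulation. They test the *organic*
  integrity of the trigeminal motor fibers: in the absence of root damage
  the two sides respond almost symmetrically regardless of pain.
* **ipJJ** — the jaw-jerk reflex with the mandible in the intercuspal
  (maximal tooth contact) position. It tests the *functional* state of the
  reflex arc: in TMD the reflex fails to facilitate on the painful side,
  producing a marked bilateral asymmetry that healthy subjects and
  non-TMD pain patients do not show.

Both tests reduce to a single number per subject and test: the **bilateral
asymmetry ratio**, the peak-to-peak amplitude of the *reference* side
(painful side in patients, non-preferred masticatory side in controls)
divided by the contralateral amplitude. The ratio is deliberately not
folded to `min/max`; values above 1 simply mean the reference side
responded more strongly, and they occur in healthy cohorts.

## From raw sweeps to a ratio

An evoked recording is a set of repeated sweeps (`emg_trace` objects
bundled into a `trial_set`). The pipeline averages the trials pointwise
*first* and then measures the peak-to-peak amplitude of the averaged trace
(maximal positive peak minus maximal negative peak); this matches the
clinical measurement convention and is not equivalent to averaging
per-trial amplitudes, which would be biased upward by noise. Analog
filtering settings (20–2000 Hz for the jaw jerk, 0.1–2000 Hz for MEPs) are
treated as acquisition metadata: the analysis assumes already-conditioned
traces and applies no digital filtering of its own. All amplitudes are
carried in mV; file readers convert µV inputs on load.

Reflex facilitation trials are held near 20% of the maximal voluntary
contraction (MVC). `estimate_mvc()` defines the MVC level as the mean
*rectified* EMG amplitude over a handful of maximal clenches — the
rectified mean rather than RMS, a documented and configurable choice since
the measurement protocol specifies only a "mean EMG value" —
and `check_facilitation()` grades a trial as below/within/above the target
band (±25% relative tolerance by default).

```{r waveform}
ts <- synthesize_waveform(waveform_spec(peak_to_peak_mv = 2.5,
                                        noise_sd_mv = 0.3), n_trials = 20,
                          seed = 1)
peak_to_peak(average_trials(ts))
```

## The fitted model: percentile cutoffs from a control cohort

The screening thresholds are *reference percentiles*, not parametric
confidence bounds: the observed ratio distributions are visibly
non-normal (skewness up to |1.7|, excess kurtosis up to 4.7), so the 5th
percentile of a control cohort defines each cutoff directly.

* **cutoff a** = 5th percentile of control MEP ratios (published value
  0.76). Step 1: an MEP ratio below it ends the evaluation with the
  `ORGANIC_DAMAGE` label — the asymmetry is too large to be functional.
* **cutoff b** = 5th percentile of control intercuspal jaw-jerk ratios
  (published value 0.32). Step 2, reached only after step 1 passes: below
  it the label is `TMD`, at or above it `OP`.

`trig_model()` fits the pair from control data; `published_cutoffs()`
returns the frozen published pair, which ships as the default because the
underlying per-subject control data were never deposited — re-deriving
cutoffs from a user's own cohort is an explicit opt-in.

Two numerical conventions matter at typical cohort sizes (a few dozen
controls) and are both exposed:

* the percentile itself: linear interpolation between closest ranks
  (`stats::quantile` type 7, the default) versus the raw order statistic
  (`interpolate = FALSE`);
* the boundary: a ratio *exactly equal* to a cutoff **passes** the screen
  at both steps. The published worked cases fix "≥ cutoff a" as a step-1
  pass; equality at cutoff b is assigned to `OP` for consistency. Users
  with ratios on the boundary should be aware the convention at cutoff b
  is a package decision, as published descriptions of that boundary are
  contradictory.

Degenerate inputs are surfaced, never guessed: an absent (zero)
contralateral MEP is itself maximal asymmetry and classifies as
`ORGANIC_DAMAGE` with an `absent_contralateral_mep` flag, while an absent
contralateral jaw jerk after a step-1 pass yields an `NA` label flagged
`indeterminate_jj`.

```{r cases}
classify(0.672, 3)             # extreme MEP asymmetry: stops at step 1
classify(3.4, 3.5, 0.329, 1.5) # symmetric MEPs, failed JJ facilitation
```

A rest-position jaw-jerk ratio (rpJJ) is the same generic ratio operation
and can be computed with `side_ratio()`, but no cutoff attaches to it: no
reference values exist for that condition, so the classifier does not
consume it.

## The synthetic-cohort generator

No subject-level recordings are publicly available, so the generator
recreates the *study conditions* at two levels and is itself first-class,
tested code.

**Ratio level.** Each (group, measure) cell is a `ratio_spec` holding the
published mean, SD and skewness. The default family is the skew-normal,
fitted by closed-form moment inversion (`fit_skew_normal()`) so the
analytic moments reproduce the targets exactly. The family was chosen
because the TMD jaw-jerk cell (mean 0.24, SD 0.14, skewness 0.79) is
feasible and, independently, the implied mass below cutoff b —
about 74% — matches the reported share of TMD patients flagged by step 2
(75%). The skew-normal's skewness range is bounded at about |0.995|: both
MEP cells (printed skewness −1.7 and 1.5) are infeasible for it, and
`family = "auto"` falls back to a mean/SD-matched normal for those cells,
dropping the skewness target and recording the compromise in the spec
object. Kurtosis is never matched (three-moment matching only); the
printed kurtosis values are treated as excess kurtosis, the only
convention under which the negative entries are possible. Draws are
rejected-and-redrawn below zero to keep ratios positive; for these cells
the rejected mass is under 1%, which lifts sample means and skewness
slightly above the targets (visible only at Monte-Carlo scale).

**Subject level.** `sample_subjects()` draws bilateral JJ and MEP
amplitudes from normal distributions at the published group means/SDs
(e.g. TMD: JJ 0.4 ± 0.4 mV pain side, 1.5 ± 1.1 mV contralateral; MEP
4.2 ± 2.9 and 5.2 ± 2.5 mV), truncated at a 0.01 mV floor. Within-subject
side–side and JJ–MEP correlations are free parameters defaulting to 0, as
no correlation structure was reported. This is a deliberate idealisation
with a visible consequence: real bilateral amplitudes are strongly
correlated within subject, so ratios of *independent* draws have much
heavier tails than clinical ratio data. Cohorts intended to emulate the
published ratio distributions should therefore be generated at the ratio
level; the amplitude level exists to exercise the record-handling
pipeline end to end. `synthesize_waveform()` closes the loop at the
lowest level, building biphasic multi-trial sweeps (one sine period at a
set latency, rescaled so the sampled clean trace hits the target
peak-to-peak exactly) with additive white noise; it emulates averaged
evoked responses, not motor-unit physiology, stimulus artifacts or
baseline drift.

What passing tests on these cohorts show, and what they do not: they
verify the pipeline's arithmetic, conventions and statistical machinery
under distributions matched to the published moments; they cannot
validate the clinical discriminative performance of the cutoffs, which
only new clinical cohorts could.

```{r generator}
spec <- published_ratio_spec("tmd", "ipJJ%")
x <- sample_ratios(10000, spec, seed = 20100701)
mean(x < coef(published_cutoffs())[["b"]])   # share flagged TMD at step 2
```

## Cohort statistics

`cohort_summary()` reports the moment set used for cohort description:
sample (n−1) variance, adjusted Fisher–Pearson skewness and adjusted
*excess* kurtosis (both `NA`-flagged for constant input, where the
standardized moments are undefined). The intergroup comparison uses the
two-sided Mann–Whitney U test: the exact null distribution of U when the
pooled sample is small (≤ 20) and untied, and the tie-corrected normal
approximation otherwise, via `stats::wilcox.test`. The test suite holds
the exact path equal to an exhaustive enumeration oracle over all group
sizes up to 6.

```{r stats}
ctl <- sample_ratios(36, published_ratio_spec("control", "ipJJ%"), seed = 3)
tmd <- sample_ratios(33, published_ratio_spec("tmd", "ipJJ%"))
compare_cohorts(ctl, tmd, measure = "ipJJ%")
```

## Problem sizes and reproducibility

Monte-Carlo checks in the package use n = 10⁴ cohorts for percentile and
classification-share recovery and n = 10⁵ for generator moment recovery —
sizes at which the Monte-Carlo error (≈ 0.4 percentage points on the
TMD share at n = 10⁴) is comfortably below the tolerances being checked,
while remaining quick on a single CPU. All sampling functions accept an
explicit seed and are bit-reproducible under it.

## Known limitations

* The published cutoffs travel with every classification, but their
  sampling uncertainty is substantial at n = 36 controls;
  `bootstrap_cutoffs()` quantifies it for user cohorts.
* The model is defined only for subjects presenting with pain; it has no
  "healthy" label, and overlapping pathologies (TMD plus organic damage)
  resolve to the organic-damage cell by construction of step 1.
* Latency, silent-period and blink-reflex measures are out of scope;
  markers beyond amplitude are not extracted from traces.
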