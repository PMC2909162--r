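# Independent brute-force oracles used across the suite.

# Exhaustive Mann-Whitney: enumerate all assignments of the pooled sample to
# the two groups, compute the U statistic of each, and take the two-sided
# tail probability of deviations from n1*n2/2 at least as large as observed.
# Valid for untied samples.
mw_enumeration_oracle <- function(a, b) {
  u_of <- function(x, y) sum(outer(x, y, ">"))
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(k) u_of(pooled[k], pooled[-k]))
  centre <- n1 * length(b) / 2
  p <- mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-12)
  list(u = u_obs, p = p)
}

# Sorted linear interpolation percentile (the type-7 convention, written out
# longhand).
percentile_interp_oracle <- function(values, probe) {
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * probe / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# A biphasic wavelet with prescribed positive and negative peak values, for
# peak-to-peak checks: half-sine lobes of different heights.
make_wavelet <- function(pos_peak, neg_peak, n = 200) {
  t <- seq(0, 1, length.out = n)
  w <- numeric(n)
  first <- t <= 0.5
  w[first] <- pos_peak * sin(2 * pi * t[first])
  w[!first] <- -abs(neg_peak) * sin(2 * pi * (t[!first] - 0.5))
  w
}

make_trace <- function(samples, rate = 1000, side = "right", type = "JJ") {
  emg_trace(samples, rate, side, type)
}

const_trace <- function(value, n = 50, ...) make_trace(rep(value, n), ...)
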