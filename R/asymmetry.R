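#' Bilateral asymmetry ratio (reference side over contralateral)
#'
#' The laterality index used throughout the diagnostic model: the
#' peak-to-peak amplitude of the reference side divided by that of the
#' contralateral side. The reference side is the painful side in patients
#' and the non-preferred masticatory side in controls, and it is *always*
#' the numerator - the ratio is deliberately not folded to `min/max`, so
#' values above 1 are meaningful (the reference side responded more
#' strongly) and do occur in healthy cohorts.
#'
#' The same operation yields all three clinical indices: the MEP asymmetry
#' (bR-MEPs%), the intercuspal jaw-jerk asymmetry (ipJJ%) and the
#' rest-position jaw-jerk asymmetry (rpJJ%); only the amplitudes fed in
#' differ.
#'
#' @param reference reference-side amplitude(s), mV, non-negative.
#' @param contralateral contralateral amplitude(s), mV, strictly positive.
#' @return dimensionless ratio(s) `reference / contralateral`. A zero or
#'   negative contralateral amplitude is a degenerate denominator (an absent
#'   response) and raises an error; the classifier handles that case
#'   explicitly before calling this.
#' @examples
#' side_ratio(0.672, 3)   # strong asymmetry
#' side_ratio(3.4, 3.5)   # near-symmetric
#' @export
side_ratio <- function(reference, contralateral) {
  if (any(reference < 0))
    stop("'reference' amplitudes must be non-negative", call. = FALSE)
  if (any(contralateral <= 0))
    stop("degenerate denominator: contralateral amplitude is zero (absent response)",
         call. = FALSE)
  reference / contralateral
}

#' Jaw-jerk amplitude as a fraction of the MEP amplitude
#'
#' The reflex response is physiologically a fraction of the maximal evoked
#' response of the same muscle (around 30% in healthy muscle); a markedly
#' lower fraction on the painful side signals failed reflex facilitation
#' rather than motor-fiber damage.
#'
#' @param jj_amp jaw-jerk peak-to-peak amplitude (mV).
#' @param mep_amp MEP peak-to-peak amplitude (mV), positive.
#' @return dimensionless fraction `jj_amp / mep_amp`.
#' @examples
#' jj_mep_fraction(0.4, 4.2)  # ~0.095: TMD pain-side group means
#' @export
jj_mep_fraction <- function(jj_amp, mep_amp) {
  if (any(jj_amp < 0))
    stop("'jj_amp' must be non-negative", call. = FALSE)
  if (any(mep_amp <= 0))
    stop("'mep_amp' must be strictly positive", call. = FALSE)
  jj_amp / mep_amp
}

#' Between-side skewness percentage of an asymmetry ratio
#'
#' Clinical reports often phrase an asymmetry ratio as the percentage
#' deficit of the reference side: `(1 - ratio) * 100`. A ratio of 0.76 is a
#' 24% between-side skewness; 0.32 is 68%. Ratios above 1 give negative
#' values (the reference side is the larger one).
#'
#' @param ratio asymmetry ratio(s), non-negative.
#' @return percentage(s); strictly decreasing in `ratio`.
#' @export
skewness_percent <- function(ratio) {
  if (any(ratio < 0))
    stop("'ratio' must be non-negative", call. = FALSE)
  (1 - ratio) * 100
}
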