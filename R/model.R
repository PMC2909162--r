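#' Fit the two-step trigeminal screening model from a control cohort
#'
#' The screening model consists of two thresholds derived as a low
#' percentile of a control cohort's bilateral asymmetry ratios:
#'
#' * **cutoff a** - the 5th percentile (by default) of the control
#'   trigeminal-root MEP asymmetry (bR-MEPs%). An MEP ratio below it
#'   signals organic damage to the trigeminal motor pathway.
#' * **cutoff b** - the 5th percentile of the control intercuspal jaw-jerk
#'   asymmetry (ipJJ%). After the MEP screen is passed, a jaw-jerk ratio
#'   below it signals the failed reflex facilitation characteristic of
#'   temporomandibular disorder (TMD); at or above it the subject is
#'   classed as other orofacial pain (OP).
#'
#' `trig_model()` fits this cutoff pair from control data; the fitted object
#' classifies new subjects through [predict.trig_model()]. For the frozen
#' reference thresholds (0.76, 0.32) use [published_cutoffs()].
#'
#' Control data can be supplied either as a subject-level data frame
#' (columns `mep_ref`, `mep_contra`, `jj_ip_ref`, `jj_ip_contra`; ratios are
#' formed with [side_ratio()]) or directly as ratio vectors.
#'
#' @param data optional data frame of control subjects (see above).
#' @param mep_ratio,jj_ratio control asymmetry-ratio vectors, used when
#'   `data` is not given.
#' @param percentile percentile (in percent) defining both cutoffs;
#'   default 5.
#' @param interpolate percentile convention, see [ratio_percentile()].
#' @return an object of class `trig_model` with components `cutoffs` (named
#'   vector `c(a=, b=)`), `percentile`, `interpolate`, `control` (the ratio
#'   vectors, or `NULL` for published/deserialized models) and `provenance`.
#' @examples
#' set.seed(1)
#' ctl <- sample_subjects(36, amplitude_spec("control"))
#' fit <- trig_model(ctl)
#' coef(fit)
#' predict(fit, sample_subjects(10, amplitude_spec("tmd")))
#' @seealso [published_cutoffs()], [predict.trig_model()], [classify()]
#' @export
trig_model <- function(data = NULL, mep_ratio = NULL, jj_ratio = NULL,
                       percentile = 5, interpolate = TRUE) {
  if (percentile <= 0 || percentile >= 100)
    stop("'percentile' must lie strictly between 0 and 100", call. = FALSE)
  if (!is.null(data)) {
    need <- c("mep_ref", "mep_contra", "jj_ip_ref", "jj_ip_contra")
    if (!all(need %in% names(data)))
      stop("'data' must carry columns ", paste(need, collapse = ", "),
           call. = FALSE)
    mep_ratio <- side_ratio(data$mep_ref, data$mep_contra)
    jj_ratio <- side_ratio(data$jj_ip_ref, data$jj_ip_contra)
  }
  if (is.null(mep_ratio) || is.null(jj_ratio))
    stop("supply either 'data' or both 'mep_ratio' and 'jj_ratio'",
         call. = FALSE)
  if (any(mep_ratio < 0) || any(jj_ratio < 0))
    stop("asymmetry ratios must be non-negative", call. = FALSE)
  cutoffs <- c(a = ratio_percentile(mep_ratio, percentile, interpolate),
               b = ratio_percentile(jj_ratio, percentile, interpolate))
  if (any(cutoffs <= 0))
    stop("derived cutoffs must be positive; control cohort contains zero ratios",
         call. = FALSE)
  structure(
    list(cutoffs = cutoffs, percentile = percentile,
         interpolate = interpolate,
         control = list(mep_ratio = as.numeric(mep_ratio),
                        jj_ratio = as.numeric(jj_ratio)),
         provenance = list(source = "derived",
                           n_mep = length(mep_ratio),
                           n_jj = length(jj_ratio)),
         call = match.call()),
    class = "trig_model")
}

#' The published screening thresholds
#'
#' Returns the frozen reference model: cutoff a = 0.76 (MEP asymmetry
#' screen) and cutoff b = 0.32 (jaw-jerk TMD/OP discriminator), both the 5th
#' percentile of a 36-subject control cohort in the source study. These ship
#' as defaults because the underlying per-subject control data were never
#' deposited; re-derivation from your own cohort is the explicit opt-in via
#' [trig_model()].
#'
#' @return a `trig_model` with provenance `"published"` and no stored
#'   control data.
#' @examples
#' m <- published_cutoffs()
#' coef(m)                      # a = 0.76, b = 0.32
#' classify(0.672, 3, NA, NA, m)  # organic damage at step 1
#' @export
published_cutoffs <- function() {
  structure(
    list(cutoffs = c(a = 0.76, b = 0.32), percentile = 5,
         interpolate = TRUE, control = NULL,
         provenance = list(source = "published", n_mep = 36L, n_jj = 36L),
         call = quote(published_cutoffs())),
    class = "trig_model")
}

#' @export
print.trig_model <- function(x, ...) {
  cat("Two-step trigeminal screening model\n")
  cat(sprintf("  cutoff a (bR-MEPs%% organic-damage screen) : %.3g\n",
              x$cutoffs[["a"]]))
  cat(sprintf("  cutoff b (ipJJ%% TMD/OP discriminator)     : %.3g\n",
              x$cutoffs[["b"]]))
  cat(sprintf("  derivation: %s percentile %g%% (%s), n = %d/%d\n",
              x$provenance$source, x$percentile,
              if (x$interpolate) "interpolated" else "order statistic",
              x$provenance$n_mep, x$provenance$n_jj))
  invisible(x)
}

#' @export
coef.trig_model <- function(object, ...) object$cutoffs

#' Summarize a fitted screening model
#'
#' For a model fitted from control data, reports the moment summary and the
#' percentile grid of both control ratio distributions alongside the
#' cutoffs. Published or deserialized models carry no cohort, so only the
#' cutoffs are reported.
#'
#' @param object a `trig_model`.
#' @param ... unused.
#' @export
summary.trig_model <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$control)) {
    out$mep <- cohort_summary(object$control$mep_ratio)
    out$jj <- cohort_summary(object$control$jj_ratio)
    out$mep_percentiles <- percentile_grid(object$control$mep_ratio,
                                           interpolate = object$interpolate)
    out$jj_percentiles <- percentile_grid(object$control$jj_ratio,
                                          interpolate = object$interpolate)
  }
  structure(out, class = "summary.trig_model")
}

#' @export
print.summary.trig_model <- function(x, digits = 3, ...) {
  print(x$model)
  if (!is.null(x$mep)) {
    cat("\nControl bR-MEPs% ratios:\n")
    print(x$mep, digits = digits)
    print(signif(x$mep_percentiles, digits))
    cat("\nControl ipJJ% ratios:\n")
    print(x$jj, digits = digits)
    print(signif(x$jj_percentiles, digits))
  }
  invisible(x)
}

#' Classify subjects with the 2x2 matrix diagnostic model
#'
#' Applies the two-step cascade to each subject:
#'
#' 1. **Step 1 (organic screen).** `mep_ratio = mep_ref / mep_contra`. A
#'    ratio below cutoff a classifies the subject as `ORGANIC_DAMAGE` and
#'    stops - there is no passage to step 2. A ratio at or exactly equal to
#'    the cutoff passes.
#' 2. **Step 2 (TMD/OP discriminator).** `jj_ratio = jj_ip_ref /
#'    jj_ip_contra`. Below cutoff b the label is `TMD`; at or above it,
#'    `OP`.
#'
#' Equality at either cutoff counts as a pass (step 1) / as `OP` (step 2);
#' the boundary convention is deliberate and applied consistently at both
#' steps. An absent (zero) contralateral MEP response is itself maximal
#' asymmetry and yields `ORGANIC_DAMAGE` with flag
#' `"absent_contralateral_mep"`; an absent contralateral jaw jerk after a
#' step-1 pass cannot be resolved by the model and yields an `NA` label with
#' flag `"indeterminate_jj"`.
#'
#' @param object a `trig_model` (fitted or [published_cutoffs()]).
#' @param newdata data frame of subjects with columns `mep_ref`,
#'   `mep_contra`, `jj_ip_ref`, `jj_ip_contra` (mV); `subject_id` is carried
#'   through if present.
#' @param ... unused.
#' @return a data frame of class `trig_prediction`, one row per subject:
#'   `subject_id`, `mep_ratio`, `jj_ratio` (`NA` when step 2 is not
#'   reached), `step_reached`, `label`
#'   (`ORGANIC_DAMAGE` / `TMD` / `OP`), `flag`. The cutoffs travel with the
#'   result as attribute `"cutoffs"`; `print()` adds a label frequency
#'   table.
#' @export
predict.trig_model <- function(object, newdata, ...) {
  if (missing(newdata) || !is.data.frame(newdata) || nrow(newdata) == 0L)
    stop("'newdata' must be a non-empty data frame of subject records",
         call. = FALSE)
  need <- c("mep_ref", "mep_contra", "jj_ip_ref", "jj_ip_contra")
  if (!all(need %in% names(newdata)))
    stop("'newdata' must carry columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(newdata)
  cut_a <- object$cutoffs[["a"]]
  cut_b <- object$cutoffs[["b"]]
  mep_ratio <- rep(NA_real_, n)
  jj_ratio <- rep(NA_real_, n)
  step <- integer(n)
  label <- character(n)
  flag <- rep("", n)
  for (i in seq_len(n)) {
    if (is.na(newdata$mep_ref[i]) || is.na(newdata$mep_contra[i])) {
      step[i] <- 1L; label[i] <- NA_character_; flag[i] <- "missing_mep"
      next
    }
    if (newdata$mep_contra[i] <= 0) {
      step[i] <- 1L; label[i] <- "ORGANIC_DAMAGE"
      flag[i] <- "absent_contralateral_mep"
      next
    }
    mep_ratio[i] <- newdata$mep_ref[i] / newdata$mep_contra[i]
    if (mep_ratio[i] < cut_a) {
      step[i] <- 1L; label[i] <- "ORGANIC_DAMAGE"
      next
    }
    step[i] <- 2L
    if (is.na(newdata$jj_ip_ref[i]) || is.na(newdata$jj_ip_contra[i])) {
      label[i] <- NA_character_; flag[i] <- "missing_jj"
      next
    }
    if (newdata$jj_ip_contra[i] <= 0) {
      label[i] <- NA_character_; flag[i] <- "indeterminate_jj"
      next
    }
    jj_ratio[i] <- newdata$jj_ip_ref[i] / newdata$jj_ip_contra[i]
    label[i] <- if (jj_ratio[i] < cut_b) "TMD" else "OP"
  }
  out <- data.frame(
    subject_id = if ("subject_id" %in% names(newdata)) newdata$subject_id
                 else seq_len(n),
    mep_ratio = mep_ratio, jj_ratio = jj_ratio,
    step_reached = step, label = label, flag = flag,
    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- object$cutoffs
  class(out) <- c("trig_prediction", "data.frame")
  out
}

#' @export
print.trig_prediction <- function(x, ...) {
  cutoffs <- attr(x, "cutoffs")
  cat(sprintf("2x2 matrix classification of %d subject(s) [cutoff a = %.3g, b = %.3g]\n\n",
              nrow(x), cutoffs[["a"]], cutoffs[["b"]]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("\nLabel frequencies:\n")
  print(label_table(x))
  invisible(x)
}

#' Label counts and proportions of a cohort classification
#'
#' @param prediction a `trig_prediction` from [predict.trig_model()].
#' @return data frame with one row per label (`NA`-labelled, flagged
#'   subjects are reported under `"indeterminate"`).
#' @export
label_table <- function(prediction) {
  stopifnot(inherits(prediction, "trig_prediction"))
  lab <- prediction$label
  lab[is.na(lab)] <- "indeterminate"
  tab <- table(factor(lab, levels = c("ORGANIC_DAMAGE", "TMD", "OP",
                                      "indeterminate")))
  tab <- tab[tab > 0 | names(tab) != "indeterminate"]
  data.frame(label = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / nrow(prediction),
             row.names = NULL)
}

#' Classify a single subject
#'
#' Convenience scalar interface over [predict.trig_model()]: supply the
#' four peak-to-peak amplitudes (mV) directly. Jaw-jerk amplitudes may be
#' `NA` when the subject is expected to stop at step 1.
#'
#' @param mep_ref,mep_contra reference/contralateral MEP amplitudes (mV).
#' @param jj_ip_ref,jj_ip_contra reference/contralateral intercuspal
#'   jaw-jerk amplitudes (mV).
#' @param model a `trig_model`; defaults to [published_cutoffs()].
#' @return one-row `trig_prediction`.
#' @examples
#' classify(8, 10.3, 3, 3.3)        # passes both screens: OP
#' classify(3.4, 3.5, 0.329, 1.5)   # fails step 2: TMD
#' @export
classify <- function(mep_ref, mep_contra, jj_ip_ref = NA, jj_ip_contra = NA,
                     model = published_cutoffs()) {
  predict(model, data.frame(mep_ref = mep_ref, mep_contra = mep_contra,
                            jj_ip_ref = jj_ip_ref,
                            jj_ip_contra = jj_ip_contra))
}

#' Classify a cohort of subject records
#'
#' Thin wrapper over [predict.trig_model()] keeping the record/cutoffs
#' argument order natural for batch use.
#'
#' @param records data frame of subject records.
#' @param model a `trig_model`; defaults to [published_cutoffs()].
#' @return a `trig_prediction`.
#' @export
classify_cohort <- function(records, model = published_cutoffs()) {
  predict(model, records)
}

#' Plot the control ratio distributions behind a fitted model
#'
#' Histograms of the control bR-MEPs% and ipJJ% ratio samples with the
#' derived cutoffs marked. Only available for models fitted from data.
#'
#' @param x a `trig_model` with stored control ratios.
#' @param ... passed to [graphics::hist()].
#' @export
plot.trig_model <- function(x, ...) {
  if (is.null(x$control))
    stop("no control cohort stored in this model (published/deserialized cutoffs)",
         call. = FALSE)
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  hist(x$control$mep_ratio, main = "Control bR-MEPs%",
       xlab = "reference / contralateral MEP amplitude", ...)
  abline(v = x$cutoffs[["a"]], lwd = 2, lty = 2)
  hist(x$control$jj_ratio, main = "Control ipJJ%",
       xlab = "reference / contralateral jaw-jerk amplitude", ...)
  abline(v = x$cutoffs[["b"]], lwd = 2, lty = 2)
  invisible(x)
}

#' Simulate synthetic control cohorts from a fitted model
#'
#' Draws new ratio cohorts from skew-normal distributions moment-matched to
#' the stored control ratio samples (falling back to a positivity-truncated
#' normal where the sample skewness is infeasible for the skew-normal
#' family). Returns a list of `nsim` data frames rather than the single
#' wide data frame of [stats::simulate()], since each replicate is a
#' two-column cohort.
#'
#' @param object a `trig_model` fitted from data.
#' @param nsim number of replicate cohorts.
#' @param seed optional RNG seed.
#' @param n cohort size per replicate; defaults to the fitted cohort size.
#' @param ... unused.
#' @return list of `nsim` data frames with columns `mep_ratio`, `jj_ratio`.
#' @export
simulate.trig_model <- function(object, nsim = 1, seed = NULL, n = NULL,
                                ...) {
  if (is.null(object$control))
    stop("no control cohort stored; simulate from ratio_spec()/sample_ratios() instead",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- length(object$control$mep_ratio)
  spec_of <- function(v) {
    s <- cohort_summary(v)
    ratio_spec(s$mean, s$sd, if (is.na(s$skewness)) 0 else s$skewness)
  }
  mep_spec <- spec_of(object$control$mep_ratio)
  jj_spec <- spec_of(object$control$jj_ratio)
  lapply(seq_len(nsim), function(i)
    data.frame(mep_ratio = sample_ratios(n, mep_spec),
               jj_ratio = sample_ratios(n, jj_spec)))
}

#' Serialize cutoffs to and from a JSON config
#'
#' Writes the cutoff pair with its derivation provenance to a small JSON
#' file (the format consumed by the command-line `classify` subcommand) and
#' reads it back as a `trig_model` without stored cohort data.
#'
#' @param model a `trig_model`.
#' @param path file path.
#' @return `read_cutoffs()` returns a `trig_model`.
#' @export
write_cutoffs <- function(model, path) {
  stopifnot(inherits(model, "trig_model"))
  jsonlite::write_json(
    list(cutoff_a = model$cutoffs[["a"]], cutoff_b = model$cutoffs[["b"]],
         percentile = model$percentile, interpolate = model$interpolate,
         source = model$provenance$source,
         n_mep = model$provenance$n_mep, n_jj = model$provenance$n_jj),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("cutoff_a", "cutoff_b", "percentile"))
    if (is.null(cfg[[k]]) || !is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop(sprintf("cutoff config is missing a valid '%s'", k), call. = FALSE)
  structure(
    list(cutoffs = c(a = cfg$cutoff_a, b = cfg$cutoff_b),
         percentile = cfg$percentile,
         interpolate = isTRUE(cfg$interpolate), control = NULL,
         provenance = list(source = if (is.null(cfg$source)) "file" else cfg$source,
                           n_mep = if (is.null(cfg$n_mep)) NA_integer_ else cfg$n_mep,
                           n_jj = if (is.null(cfg$n_jj)) NA_integer_ else cfg$n_jj),
         call = quote(read_cutoffs())),
    class = "trig_model")
}

#' Bootstrap confidence interval for derived cutoffs
#'
#' Percentile bootstrap of the cutoff pair over resampled control cohorts.
#' The screening model itself uses the plain percentile with no smoothing;
#' this utility only quantifies the sampling uncertainty of a derived
#' cutoff, which is considerable at typical control-cohort sizes.
#'
#' @param mep_ratio,jj_ratio control ratio vectors.
#' @param percentile cutoff percentile (default 5).
#' @param n_boot bootstrap replicates.
#' @param conf confidence level.
#' @param interpolate see [ratio_percentile()].
#' @return matrix with rows `a`, `b` and columns `lower`, `upper`.
#' @export
bootstrap_cutoffs <- function(mep_ratio, jj_ratio, percentile = 5,
                              n_boot = 1000, conf = 0.95,
                              interpolate = TRUE) {
  draws <- vapply(seq_len(n_boot), function(i) {
    c(ratio_percentile(sample(mep_ratio, replace = TRUE), percentile,
                       interpolate),
      ratio_percentile(sample(jj_ratio, replace = TRUE), percentile,
                       interpolate))
  }, numeric(2))
  alpha <- (1 - conf) / 2
  out <- t(apply(draws, 1, quantile, probs = c(alpha, 1 - alpha)))
  dimnames(out) <- list(c("a", "b"), c("lower", "upper"))
  out
}
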