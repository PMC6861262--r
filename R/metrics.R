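#' Diagnostic performance metrics
#'
#' The five study metrics — percent correct, mean absolute error, Brier
#' score, rank AUC, F1 — plus sensitivity and specificity. Count-based
#' metrics take a [confusion_matrix()]; probabilistic metrics take a
#' `diagnosis_set` and `case_set`.
#'
#' @param cm a `confusion_matrix`.
#' @return a numeric scalar in the metric's natural range.
#' @name metrics
NULL

#' @rdname metrics
#' @export
percent_correct <- function(cm) {
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0L) stop("empty confusion matrix", call. = FALSE)
  100 * (cm$tp + cm$tn) / total
}

#' @rdname metrics
#' @export
f1 <- function(cm) {
  denom <- 2 * cm$tp + cm$fp + cm$fn
  if (denom == 0L)
    stop("F1 undefined: no positives predicted or present", call. = FALSE)
  if (cm$tp == 0L) {
    warning("F1 is 0: no true positives", call. = FALSE)
    return(0)
  }
  2 * cm$tp / denom
}

#' @rdname metrics
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0L)
    stop("sensitivity undefined: no positive cases", call. = FALSE)
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname metrics
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0L)
    stop("specificity undefined: no negative cases", call. = FALSE)
  cm$tn / (cm$tn + cm$fp)
}

#' @rdname metrics
#' @param diag a `diagnosis_set` covering every case.
#' @param cases a `case_set`.
#' @export
mae <- function(diag, cases) {
  p <- probs_for(diag, cases)
  mean(abs(p - cases$label))
}

#' @rdname metrics
#' @export
brier <- function(diag, cases) {
  p <- probs_for(diag, cases)
  mean((p - cases$label)^2)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Fraction of (positive, negative) case pairs in which the positive
#' case received the higher probability, ties counted one half. Refused
#' for augmented diagnosis sets, whose probabilities mix two scales
#' (machine-model and swarm) and are not rank-comparable.
#'
#' @param diag a `diagnosis_set` covering every case.
#' @param cases a `case_set` containing both classes.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(diag, cases) {
  if (inherits(diag, "diagnosis_set") && diag$kind == "augmented")
    stop("AUC not applicable to augmented sets: probabilities mix scales",
         call. = FALSE)
  p <- probs_for(diag, cases)
  out <- auc_value(p, cases$label)
  if (is.na(out)) stop("AUC undefined: single-class case set", call. = FALSE)
  out
}

auc_value <- function(p, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Normalize a threshold spec (scalar, per-case vector, or named vector)
# to one threshold per case, aligned with `cases`. Augmented sets carry a
# named per-case threshold attribute because their two origins binarize
# at different cutoffs.
align_threshold <- function(threshold, cases) {
  if (length(threshold) == 1L) return(rep(threshold, nrow(cases)))
  if (!is.null(names(threshold))) {
    thr <- threshold[cases$case_id]
    if (anyNA(thr)) stop("threshold missing for some cases", call. = FALSE)
    return(unname(thr))
  }
  if (length(threshold) != nrow(cases))
    stop("threshold must be scalar or one per case", call. = FALSE)
  threshold
}

# Metric value from raw vectors; NA when undefined on this sample (used
# by the bootstrap to trigger a redraw). `threshold` may be per-case.
eval_metric <- function(metric, p, y, threshold) {
  switch(metric,
    percent_correct = 100 * mean((p > threshold) == (y == 1L)),
    accuracy = mean((p > threshold) == (y == 1L)),
    f1 = {
      pred <- p > threshold
      tp <- sum(pred & y == 1L)
      denom <- 2 * tp + sum(pred & y == 0L) + sum(!pred & y == 1L)
      if (denom == 0) NA_real_ else 2 * tp / denom
    },
    sensitivity = if (sum(y == 1L) == 0L) NA_real_
                  else sum(p > threshold & y == 1L) / sum(y == 1L),
    specificity = if (sum(y == 0L) == 0L) NA_real_
                  else sum(p <= threshold & y == 0L) / sum(y == 0L),
    mae = mean(abs(p - y)),
    brier = mean((p - y)^2),
    auc = auc_value(p, y),
    stop("unknown metric: ", metric, call. = FALSE))
}

metric_names <- function() {
  c("percent_correct", "mae", "brier", "auc", "f1",
    "sensitivity", "specificity")
}

#' Percentile-bootstrap confidence interval for a metric
#'
#' Resamples whole cases with replacement (unstratified by default, the
#' plain "full set of cases from the observed population" scheme;
#' stratified resampling within each class is available by flag),
#' recomputes the metric on each resample, and reads the CI off the
#' percentiles. Resamples on which the metric is undefined (single-class
#' draws for AUC, sensitivity or specificity) are redrawn and the redraw
#' count recorded.
#'
#' @param diag a `diagnosis_set`.
#' @param cases a `case_set`.
#' @param metric one of `"percent_correct"`, `"mae"`, `"brier"`,
#'   `"auc"`, `"f1"`, `"sensitivity"`, `"specificity"`.
#' @param threshold binarization threshold for count-based metrics.
#' @param n_boot number of bootstrap resamples (>= 1).
#' @param level CI level in (0, 1).
#' @param seed optional integer seed.
#' @param stratified resample within each class, preserving class counts.
#' @return one-row data frame: `source_id`, `metric`, `value`, `ci_lo`,
#'   `ci_hi`, `level`, `n_boot`, `n_redraws`.
#' @export
bootstrap_ci <- function(diag, cases, metric, threshold = 0.5,
                         n_boot = 1000, level = 0.95, seed = NULL,
                         stratified = FALSE) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  p <- probs_for(diag, cases)
  y <- cases$label
  threshold <- align_threshold(threshold, cases)
  point <- eval_metric(metric, p, y, threshold)
  if (is.na(point))
    stop("metric '", metric, "' undefined on the original sample",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  ipos <- which(y == 1L)
  ineg <- which(y == 0L)
  stat <- numeric(n_boot)
  redraws <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- if (stratified)
        c(sample(ipos, length(ipos), replace = TRUE),
          sample(ineg, length(ineg), replace = TRUE))
      else sample.int(n, n, replace = TRUE)
      v <- eval_metric(metric, p[idx], y[idx], threshold[idx])
      if (!is.na(v)) break
      redraws <- redraws + 1L
      if (redraws > 100L * n_boot)
        stop("bootstrap cannot find resamples with a defined metric",
             call. = FALSE)
    }
    stat[b] <- v
  }
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(stat, c(a, 1 - a), type = 7))
  data.frame(source_id = if (inherits(diag, "diagnosis_set"))
               diag$source_id else NA_character_,
             metric = metric, value = point,
             ci_lo = ci[1L], ci_hi = ci[2L], level = level,
             n_boot = as.integer(n_boot), n_redraws = redraws,
             stringsAsFactors = FALSE)
}

#' Paired bootstrap comparison of two sources
#'
#' Resamples cases with replacement jointly for both sources and
#' recomputes the metric difference on each resample. The two-sided
#' p-value is twice the fraction of resamples whose difference has the
#' opposite sign to (or equals zero against) the observed difference,
#' capped at 1; an observed difference of zero gives p = 1.
#'
#' @param diag_a,diag_b two `diagnosis_set`s covering the same cases.
#' @param metric metric name, as in [bootstrap_ci()].
#' @param cases a `case_set`.
#' @param threshold_a,threshold_b per-source binarization thresholds.
#' @param n_boot resample count.
#' @param seed optional integer seed.
#' @return list with `p_value`, `observed_diff`, `n_boot`.
#' @export
paired_bootstrap_pvalue <- function(diag_a, diag_b, metric, cases,
                                    threshold_a = 0.5, threshold_b = 0.5,
                                    n_boot = 10000, seed = NULL) {
  pa <- probs_for(diag_a, cases)
  pb <- probs_for(diag_b, cases)
  y <- cases$label
  threshold_a <- align_threshold(threshold_a, cases)
  threshold_b <- align_threshold(threshold_b, cases)
  d_obs <- eval_metric(metric, pa, y, threshold_a) -
           eval_metric(metric, pb, y, threshold_b)
  if (is.na(d_obs))
    stop("metric undefined on the original sample", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (d_obs == 0) return(list(p_value = 1, observed_diff = 0,
                              n_boot = n_boot))
  n <- length(y)
  flips <- 0L
  kept <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- eval_metric(metric, pa[idx], y[idx], threshold_a[idx]) -
         eval_metric(metric, pb[idx], y[idx], threshold_b[idx])
    if (is.na(d)) next
    kept <- kept + 1L
    if (d * sign(d_obs) <= 0) flips <- flips + 1L
  }
  list(p_value = min(1, 2 * flips / max(kept, 1L)),
       observed_diff = d_obs, n_boot = kept)
}

#' Metric table for a set of sources
#'
#' Builds the per-source x per-metric report (point value with
#' percentile-bootstrap CI) mirroring the study's summary-table layout.
#' AUC rows are skipped for augmented sets.
#'
#' @param diagnoses named list of `diagnosis_set`s.
#' @param cases a `case_set`.
#' @param thresholds named numeric vector of binarization thresholds per
#'   source id; sources not named use `default_threshold`.
#' @param default_threshold fallback threshold (the human 50% cutoff).
#' @param metrics metric names to compute.
#' @param n_boot,level,seed bootstrap settings.
#' @return data frame of [bootstrap_ci()] rows.
#' @export
metric_table <- function(diagnoses, cases, thresholds = NULL,
                         default_threshold = 0.5,
                         metrics = metric_names(),
                         n_boot = 1000, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (d in diagnoses) {
    t <- if (!is.null(attr(d, "threshold"))) attr(d, "threshold")
    else if (!is.null(thresholds) && d$source_id %in% names(thresholds))
      thresholds[[d$source_id]] else default_threshold
    for (m in metrics) {
      if (m == "auc" && d$kind == "augmented") next
      rows[[length(rows) + 1L]] <-
        bootstrap_ci(d, cases, m, threshold = t, n_boot = n_boot,
                     level = level)
    }
  }
  do.call(rbind, rows)
}
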