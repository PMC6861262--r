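#' Binarize probabilistic diagnoses at a discrimination threshold
#'
#' A prediction is positive iff the probability is strictly above the
#' threshold ("above the threshold" read literally): boundary
#' probabilities are negative calls.
#'
#' @param diag a [diagnosis_set()] (or a named probability vector).
#' @param t discrimination threshold in (0, 1).
#' @return named integer vector of 0/1 predictions.
#' @export
binarize <- function(diag, t) {
  stopifnot(t > 0, t < 1)
  p <- if (inherits(diag, "diagnosis_set")) diag$probabilities else diag
  stats::setNames(as.integer(p > t), names(p))
}

#' Crowd mean-probability aggregate
#'
#' @param sets list of reader `diagnosis_set`s with identical case
#'   coverage.
#' @param source_id label for the aggregate.
#' @return a `diagnosis_set` of kind `"crowd_mean"` holding the per-case
#'   arithmetic mean probability.
#' @export
crowd_mean <- function(sets, source_id = "crowd_mean") {
  if (!length(sets)) stop("no readers given", call. = FALSE)
  if (!same_coverage(sets))
    stop("readers cover different cases", call. = FALSE)
  ids <- names(sets[[1L]]$probabilities)
  m <- matrix(vapply(sets, function(s) s$probabilities[ids],
                     numeric(length(ids))), nrow = length(ids))
  avg <- rowMeans(m)
  diagnosis_set(source_id, stats::setNames(avg, ids), kind = "crowd_mean")
}

#' Crowd majority-vote aggregate
#'
#' Each reader is binarized at the cutoff; the crowd calls a case
#' positive only when strictly more readers call it positive than
#' negative. Even-panel ties therefore yield the negative diagnosis.
#'
#' @param sets list of reader `diagnosis_set`s with identical coverage.
#' @param cutoff per-reader binarization cutoff (default 0.5).
#' @param source_id label for the aggregate.
#' @return a `diagnosis_set` of kind `"crowd_majority"` with
#'   probabilities in {0, 1}.
#' @export
crowd_majority <- function(sets, cutoff = 0.5,
                           source_id = "crowd_majority") {
  if (!length(sets)) stop("no readers given", call. = FALSE)
  if (!same_coverage(sets))
    stop("readers cover different cases", call. = FALSE)
  ids <- names(sets[[1L]]$probabilities)
  votes <- matrix(vapply(sets, function(s)
    as.integer(s$probabilities[ids] > cutoff), integer(length(ids))),
    nrow = length(ids))
  pos <- rowSums(votes)
  call <- as.integer(pos > length(sets) - pos)
  diagnosis_set(source_id, stats::setNames(as.numeric(call), ids),
                kind = "crowd_majority")
}

#' Youden-optimal discrimination threshold
#'
#' Maximizes J = sensitivity + specificity - 1 over candidate thresholds
#' drawn from the observed probabilities (under the strict `> t`
#' binarization, each observed value is a distinct operating point).
#' Ties are broken toward the smallest threshold.
#'
#' @param diag a `diagnosis_set`.
#' @param cases a `case_set` containing both classes.
#' @return the selected threshold.
#' @export
youden_threshold <- function(diag, cases) {
  if (n_positive(cases) == 0L || n_negative(cases) == 0L)
    stop("both classes must be present", call. = FALSE)
  p <- probs_for(diag, cases)
  y <- cases$label
  cand <- sort(unique(p))
  j <- vapply(cand, function(t) {
    pred <- p > t
    sens <- sum(pred & y == 1L) / sum(y == 1L)
    spec <- sum(!pred & y == 0L) / sum(y == 0L)
    sens + spec - 1
  }, numeric(1L))
  cand[which.max(j)]  # which.max takes the first, i.e. smallest threshold
}

#' Confusion matrix from binary predictions
#'
#' @param predictions named 0/1 vector covering every case.
#' @param cases a `case_set`.
#' @return a `confusion_matrix`: list with integer `tp`, `fp`, `tn`,
#'   `fn`. Row sums always equal the class counts.
#' @export
confusion <- function(predictions, cases) {
  pred <- predictions[cases$case_id]
  if (anyNA(pred))
    stop(sprintf("missing prediction for case '%s'",
                 cases$case_id[which(is.na(pred))[1L]]), call. = FALSE)
  if (!all(pred %in% c(0L, 1L)))
    stop("predictions must be binary", call. = FALSE)
  y <- cases$label
  confusion_matrix(tp = sum(pred == 1L & y == 1L),
                   fp = sum(pred == 1L & y == 0L),
                   tn = sum(pred == 0L & y == 0L),
                   fn = sum(pred == 0L & y == 1L))
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative integer counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP=%d FP=%d TN=%d FN=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# round half up: printed rates are themselves rounded, and half-up
# inversion reproduces the published counts
round_half_up <- function(x) floor(x + 0.5)

#' Reconstruct a confusion matrix from printed sensitivity/specificity
#'
#' Inverts rounded published rates back to integer counts:
#' `TP = round(sens * n_pos)`, `TN = round(spec * n_neg)` with half-up
#' rounding, complements for FN/FP. Used to recompute accuracy, F1 and
#' error-rate figures from reported operating points.
#'
#' @param sens,spec rates in \[0, 1\].
#' @param n_pos,n_neg positive/negative class sizes (> 0).
#' @return a `confusion_matrix`.
#' @examples
#' confusion_from_rates(0.900, 0.767, 20, 30)  # TP 18, FN 2, TN 23, FP 7
#' @export
confusion_from_rates <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            n_pos > 0, n_neg > 0)
  tp <- round_half_up(sens * n_pos)
  tn <- round_half_up(spec * n_neg)
  confusion_matrix(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}
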