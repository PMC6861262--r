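#' Route low-confidence machine diagnoses to the swarm
#'
#' A machine diagnosis is low-confidence when its probability falls in a
#' closed band around the machine's discrimination threshold; those
#' cases are deferred to the human swarm. The plan partitions routed
#' cases by the machine's own predicted sign (above/below the
#' threshold) — selection never sees ground truth.
#'
#' @param ml a machine `diagnosis_set`.
#' @param band length-2 numeric, closed band `[lo, hi]` within (0, 1).
#' @param threshold the machine discrimination threshold.
#' @return an `augmentation_plan`: list with `band`, `threshold`,
#'   `routed`, `pos_pred`, `neg_pred`, `ml_source`.
#' @examples
#' ml <- diagnosis_set("ml", c(a = 0.01, b = 0.04, c = 0.9), kind = "ml")
#' route(ml, c(0.025, 0.055), threshold = 0.04008)$routed
#' @export
route <- function(ml, band = c(0.025, 0.055), threshold = 0.04008) {
  p <- ml$probabilities
  if (!length(p)) stop("empty diagnosis set", call. = FALSE)
  stopifnot(length(band) == 2L, band[1L] < band[2L],
            band[1L] > 0, band[2L] < 1)
  routed <- names(p)[p >= band[1L] & p <= band[2L]]
  structure(list(band = band, threshold = threshold, routed = routed,
                 pos_pred = routed[p[routed] > threshold],
                 neg_pred = routed[p[routed] <= threshold],
                 ml_source = ml$source_id),
            class = "augmentation_plan")
}

#' Build the augmented human-in-the-loop diagnosis set
#'
#' Routed cases take the swarm's probability (binarized downstream at
#' the human 0.5 cutoff); all other cases keep the machine probability
#' (binarized at the machine threshold). The mixed-scale provenance is
#' recorded per case so rank AUC is refused for the result, and the
#' per-case thresholds travel with the set.
#'
#' @param ml a machine `diagnosis_set`.
#' @param swarm a swarm `diagnosis_set` covering every routed case.
#' @param plan an [route()] plan.
#' @param human_threshold cutoff for swarm-originated probabilities.
#' @param source_id label for the augmented set.
#' @return a `diagnosis_set` of kind `"augmented"` with attributes
#'   `origin` (per-case `"ml"`/`"swarm"`) and `threshold` (per-case).
#' @export
augment <- function(ml, swarm, plan, human_threshold = 0.5,
                    source_id = "augmented") {
  p <- ml$probabilities
  missing_sw <- setdiff(plan$routed, names(swarm$probabilities))
  if (length(missing_sw))
    stop(sprintf("swarm missing routed case '%s'", missing_sw[1L]),
         call. = FALSE)
  origin <- stats::setNames(rep("ml", length(p)), names(p))
  origin[plan$routed] <- "swarm"
  p[plan$routed] <- swarm$probabilities[plan$routed]
  thr <- stats::setNames(rep(plan$threshold, length(p)), names(p))
  thr[plan$routed] <- human_threshold
  out <- diagnosis_set(source_id, p, kind = "augmented")
  attr(out, "origin") <- origin
  attr(out, "threshold") <- thr
  out
}

#' Binary predictions from a diagnosis set
#'
#' Applies the per-case threshold for augmented sets, or a single
#' threshold otherwise.
#'
#' @param diag a `diagnosis_set`.
#' @param threshold scalar threshold for non-augmented sets.
#' @return named 0/1 integer vector.
#' @export
predictions_of <- function(diag, threshold = 0.5) {
  p <- diag$probabilities
  thr <- attr(diag, "threshold")
  thr <- if (is.null(thr)) rep(threshold, length(p))
         else unname(thr[names(p)])
  stats::setNames(as.integer(p > thr), names(p))
}

#' Deferral-fraction sensitivity sweep
#'
#' Varies how many low-confidence cases are deferred to the swarm:
#' cases are ranked by their distance to the machine's discrimination
#' threshold (smallest first, i.e. lowest confidence), and at each grid
#' point k an equal number (k/2) of machine-predicted-positive and
#' machine-predicted-negative cases are deferred. When one side runs
#' out, the count is capped at availability and the asymmetry recorded.
#' Augmented accuracy at each point carries a percentile-bootstrap CI;
#' the accuracy increase relative to the machine alone is also emitted.
#'
#' The selection is nested (the deferred set at k is a subset of that at
#' k + 2), so the curve starts exactly at the machine-only accuracy
#' (k = 0) and ends exactly at the swarm-only accuracy (all deferred).
#'
#' @param ml machine `diagnosis_set`.
#' @param swarm swarm `diagnosis_set` covering all cases.
#' @param cases a `case_set`.
#' @param threshold machine discrimination threshold.
#' @param human_threshold cutoff for swarm probabilities.
#' @param grid even deferral counts; default 0, 2, ... up to all cases.
#' @param n_boot bootstrap resample count for the accuracy CI.
#' @param level CI level (the study sweep uses 0.90).
#' @param seed optional integer seed.
#' @param balance rank and balance deferral by the machine's predicted
#'   sign (`"prediction"`, default — selection cannot peek at labels) or
#'   by ground-truth class (`"label"`).
#' @param distance `"probability"` for `|p - t|`, or `"logit"` for
#'   distance on the log-odds scale (the machine's probabilities are
#'   compressed near its threshold).
#' @return a `sweep_result` data frame: `k`, `n_routed`, `fraction`,
#'   `n_pos_side`, `n_neg_side`, `accuracy`, `ci_lo`, `ci_hi`,
#'   `delta_vs_ml`.
#' @export
sweep_deferral <- function(ml, swarm, cases, threshold = 0.04008,
                           human_threshold = 0.5, grid = NULL,
                           n_boot = 1000, level = 0.90, seed = NULL,
                           balance = c("prediction", "label"),
                           distance = c("probability", "logit")) {
  balance <- match.arg(balance)
  distance <- match.arg(distance)
  p <- probs_for(ml, cases)
  ps <- probs_for(swarm, cases)
  y <- cases$label
  n <- nrow(cases)
  dist <- switch(distance,
                 probability = abs(p - threshold),
                 logit = abs(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)) -
                             stats::qlogis(threshold)))
  side <- if (balance == "prediction") as.integer(p > threshold) else y
  pos_rank <- cases$case_id[side == 1L][order(dist[side == 1L])]
  neg_rank <- cases$case_id[side == 0L][order(dist[side == 0L])]
  if (is.null(grid)) grid <- seq(0L, 2L * max(length(pos_rank),
                                              length(neg_rank)), by = 2L)
  ml_correct <- (p > threshold) == (y == 1L)
  sw_correct <- (ps > human_threshold) == (y == 1L)
  names(ml_correct) <- names(sw_correct) <- cases$case_id

  if (!is.null(seed)) set.seed(seed)
  boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  a <- (1 - level) / 2
  ml_acc <- mean(ml_correct)

  rows <- lapply(grid, function(k) {
    take_pos <- min(k %/% 2L, length(pos_rank))
    take_neg <- min(k %/% 2L, length(neg_rank))
    deferred <- c(pos_rank[seq_len(take_pos)], neg_rank[seq_len(take_neg)])
    correct <- ml_correct
    correct[deferred] <- sw_correct[deferred]
    acc <- mean(correct)
    boot_acc <- colMeans(matrix(correct[boot_idx], n, n_boot))
    ci <- unname(stats::quantile(boot_acc, c(a, 1 - a), type = 7))
    data.frame(k = k, n_routed = length(deferred),
               fraction = length(deferred) / n,
               n_pos_side = take_pos, n_neg_side = take_neg,
               accuracy = acc, ci_lo = ci[1L], ci_hi = ci[2L],
               delta_vs_ml = acc - ml_acc)
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  attr(out, "n_boot") <- n_boot
  class(out) <- c("sweep_result", "data.frame")
  out
}
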