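#' Operating point of a synthetic diagnostic source
#'
#' A source is characterized by its target sensitivity and specificity
#' at a given discrimination threshold, plus a logit-scale spread. The
#' class-conditional generative model is logit-normal:
#' `logit(p) ~ N(mu_class, sigma)` with
#' `mu_pos = logit(t) + sigma * qnorm(sens)` and
#' `mu_neg = logit(t) - sigma * qnorm(spec)`, so the true exceedance
#' probabilities at the threshold equal the targets exactly by
#' construction.
#'
#' @param sens,spec target sensitivity and specificity in (0, 1).
#' @param threshold discrimination threshold `t` in (0, 1).
#' @param sigma logit-scale standard deviation (> 0).
#' @return an `operating_point` list, including the implied `mu_pos`
#'   and `mu_neg`.
#' @export
operating_point <- function(sens, spec, threshold, sigma = 1) {
  stopifnot(sens > 0, sens < 1, spec > 0, spec < 1,
            threshold > 0, threshold < 1, sigma > 0)
  lt <- stats::qlogis(threshold)
  structure(list(sens = sens, spec = spec, threshold = threshold,
                 sigma = sigma,
                 mu_pos = lt + sigma * stats::qnorm(sens),
                 mu_neg = lt - sigma * stats::qnorm(spec)),
            class = "operating_point")
}

#' Generate a case set with exact class composition
#'
#' The positive count is `round(n * prevalence)` (half-up), fixed
#' deterministically; only the ordering of cases is randomized by the
#' seed.
#'
#' @param n number of cases (>= 2).
#' @param prevalence positive-class fraction in (0, 1).
#' @param seed optional integer seed.
#' @return a [case_set()].
#' @examples
#' gen_cases(50, 0.4, seed = 1)  # 20 positive, 30 negative
#' @export
gen_cases <- function(n, prevalence, seed = NULL) {
  stopifnot(n >= 2, prevalence > 0, prevalence < 1)
  n_pos <- round_half_up(n * prevalence)
  if (n_pos == 0 || n_pos == n)
    stop("composition yields an empty class", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  case_set(sprintf("case_%03d", seq_len(n)), labels)
}

#' Draw probabilistic diagnoses from an operating point
#'
#' @param cases a `case_set`.
#' @param op an [operating_point()].
#' @param seed optional integer seed.
#' @param source_id,kind identity of the resulting `diagnosis_set`.
#' @return a `diagnosis_set`; probabilities never leave (0, 1).
#' @export
gen_probs <- function(cases, op, seed = NULL, source_id = "source",
                      kind = "reader") {
  if (!is.null(seed)) set.seed(seed)
  mu <- ifelse(cases$label == 1L, op$mu_pos, op$mu_neg)
  p <- stats::plogis(stats::rnorm(nrow(cases), mu, op$sigma))
  diagnosis_set(source_id, stats::setNames(p, cases$case_id),
                kind = kind, cases = cases)
}

#' Generate an exchangeable panel of readers
#'
#' Each reader perturbs the shared operating point by a common
#' logit-scale location shift drawn from `N(0, between_reader_sd)`
#' (applied to both class means: a stricter reader is stricter on every
#' case), then draws diagnoses. Readers are exchangeable given the
#' hyper-parameters.
#'
#' `reader_correlation` splits the operating point's logit spread into a
#' shared case-difficulty component (`sigma * sqrt(rho)`, drawn once per
#' case) and a per-reader idiosyncratic component
#' (`sigma * sqrt(1 - rho)`), so each reader's marginal sensitivity and
#' specificity stay exactly at the operating point while any two
#' readers' case-level logits correlate at `rho`. The default 0 gives
#' fully independent readers.
#'
#' @param cases a `case_set`.
#' @param n_readers panel size (>= 2).
#' @param op shared [operating_point()].
#' @param between_reader_sd logit-scale sd of the per-reader shift.
#' @param reader_correlation shared case-difficulty correlation `rho`
#'   in \[0, 1).
#' @param shared_effect optional pre-drawn per-case difficulty vector
#'   (logit scale, one value per case); lets several panels reading the
#'   same images share one difficulty realization. Overrides the
#'   internal draw; its scale should be `sigma * sqrt(rho)`.
#' @param seed optional integer seed.
#' @param prefix reader source-id prefix.
#' @return list of reader `diagnosis_set`s.
#' @export
gen_reader_panel <- function(cases, n_readers, op, between_reader_sd = 0.3,
                             reader_correlation = 0, shared_effect = NULL,
                             seed = NULL, prefix = "reader") {
  stopifnot(n_readers >= 2, between_reader_sd >= 0,
            reader_correlation >= 0, reader_correlation < 1)
  if (!is.null(seed)) set.seed(seed)
  shifts <- stats::rnorm(n_readers, 0, between_reader_sd)
  shared <- if (!is.null(shared_effect)) {
    stopifnot(length(shared_effect) == nrow(cases))
    shared_effect
  } else {
    stats::rnorm(nrow(cases), 0, op$sigma * sqrt(reader_correlation))
  }
  sd_own <- op$sigma * sqrt(1 - reader_correlation)
  mu <- ifelse(cases$label == 1L, op$mu_pos, op$mu_neg) + shared
  lapply(seq_len(n_readers), function(i) {
    p <- stats::plogis(stats::rnorm(nrow(cases), mu + shifts[i], sd_own))
    diagnosis_set(sprintf("%s_%d", prefix, i),
                  stats::setNames(p, cases$case_id),
                  kind = "reader", cases = cases)
  })
}

#' Study-like synthetic scenario
#'
#' Emulates the reader study's conditions: 50 cases (20 positive, 30
#' negative), two reader groups of 7 and 6, readers operating near
#' sensitivity 0.65 / specificity 0.85 at the human 50% cutoff, and a
#' machine model calibrated to sensitivity 0.90 / specificity 0.767 at
#' its 4.008% threshold with deliberately compressed spread (sigma 0.8),
#' so machine probabilities concentrate near its low threshold while
#' human probabilities center near 50%.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param n number of cases.
#' @param prevalence positive fraction.
#' @param n_readers_a,n_readers_b group sizes.
#' @param reader_op,machine_op operating points; defaults as above.
#' @param between_reader_sd per-reader logit shift sd.
#' @param reader_correlation shared case-difficulty correlation; both
#'   groups read the same images, so they share one difficulty
#'   realization. The default 0.5 makes crowd and swarm aggregates gain
#'   modestly over individuals, as reader panels do in practice, rather
#'   than the near-perfect aggregate that independent readers would
#'   give.
#' @return list with `cases`, `readers_a`, `readers_b`, `ml`,
#'   `reader_op`, `machine_op`, `seed`.
#' @export
study_scenario <- function(seed = 1, n = 50, prevalence = 0.4,
                           n_readers_a = 7, n_readers_b = 6,
                           reader_op = operating_point(0.65, 0.85, 0.5,
                                                       sigma = 1.5),
                           machine_op = operating_point(0.90, 0.767,
                                                        0.04008,
                                                        sigma = 0.8),
                           between_reader_sd = 0.3,
                           reader_correlation = 0.5) {
  set.seed(seed)
  cases <- gen_cases(n, prevalence)
  shared <- stats::rnorm(n, 0,
                         reader_op$sigma * sqrt(reader_correlation))
  readers_a <- gen_reader_panel(cases, n_readers_a, reader_op,
                                between_reader_sd,
                                reader_correlation = reader_correlation,
                                shared_effect = shared,
                                prefix = "reader_a")
  readers_b <- gen_reader_panel(cases, n_readers_b, reader_op,
                                between_reader_sd,
                                reader_correlation = reader_correlation,
                                shared_effect = shared,
                                prefix = "reader_b")
  ml <- gen_probs(cases, machine_op, source_id = "machine", kind = "ml")
  list(cases = cases, readers_a = readers_a, readers_b = readers_b,
       ml = ml, reader_op = reader_op, machine_op = machine_op,
       seed = seed)
}
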