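#' Pool per-group diagnoses into a combined evaluation
#'
#' When two swarm groups each evaluate every case, the combined analysis
#' treats each (case, group) pair as one diagnosis: 50 cases x 2 groups
#' = 100 pooled diagnoses. Sources that do not vary by group (the
#' machine model, ground truth) are duplicated across groups.
#'
#' @param cases a `case_set`.
#' @param per_group named list of `diagnosis_set`s, one per group (names
#'   become id suffixes).
#' @param source_id label for the pooled set.
#' @param kind kind of the pooled set; defaults to the first group's.
#' @return list with `cases` (pooled `case_set`) and `diag` (pooled
#'   `diagnosis_set`).
#' @export
pool_groups <- function(cases, per_group, source_id = "pooled",
                        kind = NULL) {
  stopifnot(length(per_group) >= 2L, !is.null(names(per_group)))
  ids <- unlist(lapply(names(per_group), function(g)
    paste0(cases$case_id, "@", g)))
  labels <- rep(cases$label, times = length(per_group))
  pooled_cases <- case_set(ids, labels,
                           group = rep(names(per_group),
                                       each = nrow(cases)))
  p <- unlist(lapply(per_group, function(d)
    unname(probs_for(d, cases))))
  if (is.null(kind)) kind <- per_group[[1L]]$kind
  diag <- diagnosis_set(source_id, stats::setNames(p, ids), kind = kind,
                        cases = pooled_cases)
  thr <- lapply(per_group, function(d) attr(d, "threshold"))
  if (!any(vapply(thr, is.null, logical(1L)))) {
    attr(diag, "threshold") <- stats::setNames(
      unlist(lapply(thr, function(x) unname(x[cases$case_id]))), ids)
  }
  list(cases = pooled_cases, diag = diag)
}

#' Average of individual reader metrics
#'
#' The per-reader metric is computed reader by reader and averaged. For
#' panels spanning unequal groups the combined average is reported two
#' ways: `"pooled"` weights every reader equally, `"group_mean"`
#' averages the two group means.
#'
#' @param groups named list of reader panels (lists of `diagnosis_set`).
#' @param cases a `case_set`.
#' @param metric metric name, as in [bootstrap_ci()].
#' @param threshold binarization cutoff for count-based metrics.
#' @param weighting combined-average convention.
#' @return the averaged metric value.
#' @export
individual_average <- function(groups, cases, metric, threshold = 0.5,
                               weighting = c("pooled", "group_mean")) {
  weighting <- match.arg(weighting)
  per_reader <- lapply(groups, function(panel)
    vapply(panel, function(d)
      eval_metric(metric, probs_for(d, cases), cases$label, threshold),
      numeric(1L)))
  if (weighting == "pooled") mean(unlist(per_reader))
  else mean(vapply(per_reader, mean, numeric(1L)))
}

#' Study configuration
#'
#' Bundles every tunable of the pipeline: synthetic-scenario settings,
#' per-source discrimination thresholds, the low-confidence deferral
#' band, bootstrap and sweep settings, and the swarm simulator
#' configuration. All stochastic stages consume seeds derived from the
#' single `seed`, so identical configs yield identical outputs.
#'
#' @param seed master integer seed.
#' @param n,prevalence,n_readers_a,n_readers_b scenario shape.
#' @param reader_op,machine_op [operating_point()]s for the synthetic
#'   sources.
#' @param between_reader_sd per-reader logit jitter sd.
#' @param reader_correlation shared case-difficulty correlation.
#' @param human_threshold,ml_threshold discrimination thresholds.
#' @param band closed low-confidence band `[lo, hi]`.
#' @param n_boot,ci_level metric-table bootstrap settings.
#' @param sweep_n_boot,sweep_level sweep bootstrap settings.
#' @param run_sweep include the deferral sweep in the bundle.
#' @param swarm a [swarm_config()] (its seed field is ignored; session
#'   seeds derive from `seed`).
#' @return a `study_config` list.
#' @export
study_config <- function(seed = 1, n = 50, prevalence = 0.4,
                         n_readers_a = 7, n_readers_b = 6,
                         reader_op = operating_point(0.65, 0.85, 0.5,
                                                     sigma = 1.5),
                         machine_op = operating_point(0.90, 0.767,
                                                      0.04008,
                                                      sigma = 0.8),
                         between_reader_sd = 0.3,
                         reader_correlation = 0.5,
                         human_threshold = 0.5, ml_threshold = 0.04008,
                         band = c(0.025, 0.055),
                         n_boot = 1000, ci_level = 0.95,
                         sweep_n_boot = 1000, sweep_level = 0.90,
                         run_sweep = TRUE, swarm = swarm_config()) {
  stopifnot(band[1L] < band[2L], ci_level > 0, ci_level < 1,
            sweep_level > 0, sweep_level < 1, n_boot >= 1)
  structure(list(seed = seed, n = n, prevalence = prevalence,
                 n_readers_a = n_readers_a, n_readers_b = n_readers_b,
                 reader_op = reader_op, machine_op = machine_op,
                 between_reader_sd = between_reader_sd,
                 reader_correlation = reader_correlation,
                 human_threshold = human_threshold,
                 ml_threshold = ml_threshold, band = band,
                 n_boot = n_boot, ci_level = ci_level,
                 sweep_n_boot = sweep_n_boot, sweep_level = sweep_level,
                 run_sweep = run_sweep, swarm = swarm),
            class = "study_config")
}

#' Run the full study pipeline on a synthetic scenario
#'
#' Orchestrates synthetic generation, one swarm session per group,
#' crowd aggregation, metric tables, human-in-the-loop augmentation and
#' (optionally) the deferral sweep, mirroring the study's analysis
#' sequence. Deterministic given the config.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; reports, the case table and the
#'   sweep are written there (JSON/CSV/markdown).
#' @return a bundle list: `scenario`, `swarm_a`, `swarm_b`, crowd
#'   aggregates, pooled combined sets, `plan`, `augmented`, `report`
#'   (metric table), `sweep` (`NULL` when disabled).
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL) {
  sc <- study_scenario(seed = config$seed, n = config$n,
                       prevalence = config$prevalence,
                       n_readers_a = config$n_readers_a,
                       n_readers_b = config$n_readers_b,
                       reader_op = config$reader_op,
                       machine_op = config$machine_op,
                       between_reader_sd = config$between_reader_sd,
                       reader_correlation = config$reader_correlation)
  swcfg <- config$swarm
  swcfg$seed <- config$seed + 101L
  swarm_a <- run_swarm_session(sc$cases, sc$readers_a, config = swcfg,
                               source_id = "swarm_a")
  swcfg$seed <- config$seed + 202L
  swarm_b <- run_swarm_session(sc$cases, sc$readers_b, config = swcfg,
                               source_id = "swarm_b")

  crowd <- list(
    mean_a = crowd_mean(sc$readers_a, "crowd_mean_a"),
    mean_b = crowd_mean(sc$readers_b, "crowd_mean_b"),
    majority_a = crowd_majority(sc$readers_a,
                                cutoff = config$human_threshold,
                                source_id = "crowd_majority_a"),
    majority_b = crowd_majority(sc$readers_b,
                                cutoff = config$human_threshold,
                                source_id = "crowd_majority_b"))

  combined_swarm <- pool_groups(sc$cases, list(A = swarm_a, B = swarm_b),
                                source_id = "swarm_combined")
  ml_pooled <- pool_groups(sc$cases, list(A = sc$ml, B = sc$ml),
                           source_id = "machine_pooled")$diag

  plan <- route(sc$ml, band = config$band,
                threshold = config$ml_threshold)
  aug_a <- augment(sc$ml, swarm_a, plan,
                   human_threshold = config$human_threshold,
                   source_id = "augmented_a")
  aug_b <- augment(sc$ml, swarm_b, plan,
                   human_threshold = config$human_threshold,
                   source_id = "augmented_b")
  augmented <- pool_groups(sc$cases, list(A = aug_a, B = aug_b),
                           source_id = "augmented")$diag

  thresholds <- c(machine = config$ml_threshold,
                  machine_pooled = config$ml_threshold)
  sources <- c(list(ml = sc$ml, swarm_a = swarm_a, swarm_b = swarm_b),
               crowd,
               list(swarm_combined = combined_swarm$diag,
                    augmented = augmented))
  eval_cases <- list(ml = sc$cases, swarm_a = sc$cases, swarm_b = sc$cases,
                     mean_a = sc$cases, mean_b = sc$cases,
                     majority_a = sc$cases, majority_b = sc$cases,
                     swarm_combined = combined_swarm$cases,
                     augmented = combined_swarm$cases)
  set.seed(config$seed + 303L)
  report <- do.call(rbind, lapply(names(sources), function(nm) {
    metric_table(sources[nm], eval_cases[[nm]], thresholds = thresholds,
                 default_threshold = config$human_threshold,
                 n_boot = config$n_boot, level = config$ci_level)
  }))

  sweep <- NULL
  if (isTRUE(config$run_sweep)) {
    sweep <- sweep_deferral(ml_pooled, combined_swarm$diag,
                            combined_swarm$cases,
                            threshold = config$ml_threshold,
                            human_threshold = config$human_threshold,
                            n_boot = config$sweep_n_boot,
                            level = config$sweep_level,
                            seed = config$seed + 404L)
  }

  bundle <- list(scenario = sc, swarm_a = swarm_a, swarm_b = swarm_b,
                 crowd = crowd, combined_swarm = combined_swarm,
                 ml_pooled = ml_pooled, plan = plan,
                 augmented = augmented, report = report, sweep = sweep,
                 config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_case_table(sc$cases,
                     c(sc$readers_a, sc$readers_b,
                       list(sc$ml, swarm_a, swarm_b)),
                     file.path(out_dir, "case_table.csv"))
    write_report(report, file.path(out_dir, "metric_report"))
    if (!is.null(sweep))
      jsonlite::write_json(as.data.frame(sweep),
                           file.path(out_dir, "sweep.json"), digits = NA)
  }
  bundle
}

#' Replicated accuracy-ordering study
#'
#' Repeats the synthetic scenario end to end — fresh cases, reader
#' panels, machine probabilities, one swarm session per group, and the
#' band-based augmentation — and records the machine-only, pooled
#' swarm-only and augmented accuracies of each replicate. Used to check
#' the headline ordering (augmented above both constituents) under the
#' study-like conditions.
#'
#' @param n_rep number of replicates.
#' @param seed master integer seed; replicate r uses `seed + r`.
#' @param config a [study_config()]; its own seed field is ignored.
#' @return data frame with one row per replicate: `ml_acc`, `swarm_acc`,
#'   `aug_acc` (fractions) and `n_routed`.
#' @export
replicate_accuracy_study <- function(n_rep = 200, seed = 1,
                                     config = study_config()) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- config
    cfg$seed <- seed + r
    sc <- study_scenario(seed = cfg$seed, n = cfg$n,
                         prevalence = cfg$prevalence,
                         n_readers_a = cfg$n_readers_a,
                         n_readers_b = cfg$n_readers_b,
                         reader_op = cfg$reader_op,
                         machine_op = cfg$machine_op,
                         between_reader_sd = cfg$between_reader_sd,
                         reader_correlation = cfg$reader_correlation)
    swcfg <- cfg$swarm
    swcfg$seed <- cfg$seed + 101L
    swarm_a <- run_swarm_session(sc$cases, sc$readers_a, config = swcfg,
                                 source_id = "swarm_a")
    swcfg$seed <- cfg$seed + 202L
    swarm_b <- run_swarm_session(sc$cases, sc$readers_b, config = swcfg,
                                 source_id = "swarm_b")
    plan <- route(sc$ml, band = cfg$band, threshold = cfg$ml_threshold)
    y <- rep(sc$cases$label, 2L)
    p_ml <- probs_for(sc$ml, sc$cases)
    ml_correct <- (p_ml > cfg$ml_threshold) == (sc$cases$label == 1L)
    sw_pred <- c(probs_for(swarm_a, sc$cases),
                 probs_for(swarm_b, sc$cases)) > cfg$human_threshold
    aug_a <- augment(sc$ml, swarm_a, plan,
                     human_threshold = cfg$human_threshold)
    aug_b <- augment(sc$ml, swarm_b, plan,
                     human_threshold = cfg$human_threshold)
    aug_pred <- c(predictions_of(aug_a)[sc$cases$case_id],
                  predictions_of(aug_b)[sc$cases$case_id])
    data.frame(ml_acc = mean(ml_correct),
               swarm_acc = mean(sw_pred == (y == 1L)),
               aug_acc = mean(aug_pred == y),
               n_routed = length(plan$routed))
  })
  do.call(rbind, rows)
}
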