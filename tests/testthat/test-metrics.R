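test_that("count-based metrics match hand-worked confusion matrices", {
  cm <- confusion_matrix(tp = 18, fp = 7, tn = 23, fn = 2)
  expect_equal(percent_correct(cm), 82)
  expect_equal(f1(cm), 0.8)
  cm2 <- confusion_matrix(tp = 35, fp = 4, tn = 56, fn = 5)
  expect_equal(percent_correct(cm2), 91)
  cm3 <- confusion_matrix(tp = 28, fp = 4, tn = 56, fn = 12)
  expect_equal(round(f1(cm3), 3), 0.778)
  expect_equal(percent_correct(confusion_matrix(5, 0, 5, 0)), 100)
  expect_equal(f1(confusion_matrix(5, 0, 5, 0)), 1)

  expect_warning(v <- f1(confusion_matrix(0, 2, 5, 3)), "no true positives")
  expect_equal(v, 0)
  expect_error(f1(confusion_matrix(0, 0, 5, 0)), "undefined")
  expect_error(percent_correct(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("sensitivity and specificity follow their definitions", {
  cm <- confusion_matrix(tp = 14, fp = 2, tn = 28, fn = 6)
  expect_equal(sensitivity(cm), 0.7)
  expect_equal(round(specificity(cm), 3), 0.933)
  expect_equal(sensitivity(confusion_matrix(9, 0, 9, 0)), 1)
  expect_error(sensitivity(confusion_matrix(0, 3, 4, 0)), "no positive")
  expect_error(specificity(confusion_matrix(3, 0, 0, 4)), "no negative")
})

test_that("sens/spec recompose to percent correct via class weights", {
  set.seed(5)
  for (rep in 1:10) {
    cs <- make_cases(c(rep(1, 8), rep(0, 12)))
    d <- make_diag(runif(20), cs)
    cm <- cm_of(d, cs, 0.5)
    expect_equal(percent_correct(cm),
                 100 * (sensitivity(cm) * 8 + specificity(cm) * 12) / 20)
  }
})

test_that("MAE and Brier behave on hand cases and random inputs", {
  cs1 <- make_cases(0)
  expect_equal(mae(make_diag(0.1, cs1), cs1), 0.1)
  expect_equal(brier(make_diag(0.1, cs1), cs1), 0.01)

  cs <- make_cases(c(1, 0, 1))
  exact <- make_diag(c(1, 0, 1), cs)
  expect_equal(mae(exact, cs), 0)
  half <- make_diag(rep(0.5, 3), cs)
  expect_equal(brier(half, cs), 0.25)

  set.seed(13)
  for (rep in 1:25) {
    cs_r <- make_cases(rbinom(12, 1, 0.5))
    p <- runif(12)
    d <- make_diag(p, cs_r)
    expect_equal(mae(d, cs_r), mean(abs(p - cs_r$label)), tolerance = 1e-12)
    expect_lte(brier(d, cs_r), mae(d, cs_r))  # |e| <= 1 so e^2 <= |e|
  }

  # binary probabilities: mae = brier = error fraction
  cs_b <- make_cases(c(1, 1, 0, 0))
  d_b <- make_diag(c(1, 0, 0, 1), cs_b)
  expect_equal(mae(d_b, cs_b), 0.5)
  expect_equal(brier(d_b, cs_b), 0.5)
})

test_that("rank AUC equals brute-force pair counting", {
  cs <- make_cases(c(1, 1, 0, 0))
  d <- make_diag(c(0.9, 0.4, 0.3, 0.5), cs)
  expect_equal(auc(d, cs), 0.75)
  sep <- make_diag(c(0.9, 0.8, 0.1, 0.2), cs)
  expect_equal(auc(sep, cs), 1)
  flat <- make_diag(rep(0.4, 4), cs)
  expect_equal(auc(flat, cs), 0.5)
  expect_error(auc(d, make_cases(c(1, 1, 1, 1))), "single-class")

  set.seed(19)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    cs_r <- make_cases(c(1, 0, rbinom(n - 2, 1, 0.5)))
    p <- round(runif(n), 2)  # coarse grid to exercise ties
    d_r <- make_diag(p, cs_r)
    expect_equal(auc(d_r, cs_r), auc_oracle(p, cs_r$label),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  cs <- make_cases(rep(c(1, 0), each = 25))
  d <- make_diag(runif(50), cs)
  ref <- as.numeric(pROC::auc(pROC::roc(cs$label, unname(probs_for(d, cs)),
                                        quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(auc(d, cs), ref, tolerance = 1e-12)
})

test_that("bootstrap CIs are seeded, ordered, and degenerate when exact", {
  cs <- make_cases(c(rep(1, 10), rep(0, 15)))
  d <- make_diag(ifelse(cs$label == 1, 0.9, 0.1), cs)
  r <- bootstrap_ci(d, cs, "percent_correct", n_boot = 200, seed = 2)
  expect_equal(r$value, 100)
  expect_equal(r$ci_lo, 100)
  expect_equal(r$ci_hi, 100)

  d2 <- make_diag(runif(25), cs, "noisy")
  r1 <- bootstrap_ci(d2, cs, "auc", n_boot = 300, seed = 7)
  r2 <- bootstrap_ci(d2, cs, "auc", n_boot = 300, seed = 7)
  expect_identical(r1, r2)
  expect_lte(r1$ci_lo, r1$value)
  expect_gte(r1$ci_hi, r1$value)

  expect_error(bootstrap_ci(d2, make_cases(rep(1, 25)), "auc"),
               "undefined")
})

test_that("bootstrap CI width shrinks with sample size", {
  op <- operating_point(0.8, 0.8, 0.5, sigma = 1)
  width <- sapply(c(50, 500), function(n) {
    cs <- gen_cases(n, 0.4, seed = 77)
    d <- gen_probs(cs, op, seed = 78)
    r <- bootstrap_ci(d, cs, "percent_correct", n_boot = 400, seed = 79)
    r$ci_hi - r$ci_lo
  })
  expect_lt(width[2], width[1])
})

test_that("stratified resampling preserves class counts", {
  cs <- make_cases(c(rep(1, 5), rep(0, 20)))
  d <- make_diag(runif(25), cs)
  # sensitivity on stratified draws can never hit a single-class resample
  r <- bootstrap_ci(d, cs, "sensitivity", n_boot = 200, seed = 3,
                    stratified = TRUE)
  expect_equal(r$n_redraws, 0L)
})

test_that("paired bootstrap p-values are sane", {
  cs <- make_cases(rep(c(1, 0), 10))
  d <- make_diag(runif(20), cs)
  same <- paired_bootstrap_pvalue(d, d, "brier", cs, n_boot = 100,
                                  seed = 1)
  expect_equal(same$p_value, 1)
  expect_equal(same$observed_diff, 0)

  # a real 0.3 accuracy gap at n = 200 is detected
  set.seed(9)
  cs_big <- make_cases(rep(c(1, 0), each = 100))
  p_ok <- ifelse(cs_big$label == 1, 0.9, 0.1)
  good <- make_diag(ifelse(stats::runif(200) < 0.95, p_ok, 1 - p_ok),
                    cs_big, "good")
  weak <- make_diag(ifelse(stats::runif(200) < 0.65, p_ok, 1 - p_ok),
                    cs_big, "weak")
  pv <- paired_bootstrap_pvalue(good, weak, "percent_correct", cs_big,
                                n_boot = 500, seed = 10)
  expect_lt(pv$p_value, 0.05)
  pv2 <- paired_bootstrap_pvalue(good, weak, "percent_correct", cs_big,
                                 n_boot = 500, seed = 10)
  expect_identical(pv, pv2)
})

test_that("metric tables cover sources x metrics and skip augmented AUC", {
  cs <- make_cases(rep(c(1, 0), each = 5))
  ml <- make_diag(runif(10), cs, "ml", kind = "ml")
  sw <- make_diag(runif(10), cs, "sw", kind = "swarm")
  plan <- route(ml, c(0.2, 0.8), threshold = 0.5)
  aug <- augment(ml, sw, plan)
  tab <- metric_table(list(ml = ml, aug = aug), cs,
                      thresholds = c(ml = 0.5), n_boot = 20, seed = 4)
  expect_setequal(unique(tab$metric[tab$source_id == "ml"]),
                  c("percent_correct", "mae", "brier", "auc", "f1",
                    "sensitivity", "specificity"))
  expect_false("auc" %in% tab$metric[tab$source_id == "augmented"])
  expect_true(all(tab$ci_lo <= tab$value + 1e-9))
  expect_true(all(tab$ci_hi >= tab$value - 1e-9))
})
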