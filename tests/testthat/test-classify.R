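test_that("binarization is strictly above-threshold", {
  expect_equal(binarize(c(a = 0.6, b = 0.4), 0.5), c(a = 1L, b = 0L))
  expect_equal(binarize(c(a = 0.5), 0.5), c(a = 0L))  # boundary negative
  expect_equal(binarize(c(a = 0.041, b = 0.039), 0.04008),
               c(a = 1L, b = 0L))
})

test_that("crowd mean equals the brute-force column mean", {
  cs <- make_cases(rep(c(1, 0), 5))
  expect_equal(crowd_mean(list(make_diag(c(a = 0.2), source_id = "r1"),
                               make_diag(c(a = 0.6), source_id = "r2"))
                          )$probabilities, c(a = 0.4))
  single <- make_diag(runif(10), cs, "solo")
  expect_equal(crowd_mean(list(single))$probabilities,
               single$probabilities)

  set.seed(31)
  panel <- lapply(1:7, function(i) make_diag(runif(10), cs,
                                             paste0("r", i)))
  cm_ <- crowd_mean(panel)
  manual <- sapply(cs$case_id, function(id)
    mean(sapply(panel, function(d) d$probabilities[[id]])))
  expect_equal(cm_$probabilities, manual, tolerance = 1e-12)
  expect_identical(cm_$kind, "crowd_mean")

  mismatched <- make_diag(c(zz = 0.5), source_id = "bad")
  expect_error(crowd_mean(c(panel, list(mismatched))), "different cases")
})

test_that("majority vote needs a strict majority; ties are negative", {
  cs <- make_cases(1)
  seven <- lapply(c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2), function(p)
    make_diag(p, cs))
  expect_equal(unname(crowd_majority(seven)$probabilities), 1)
  six <- lapply(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1), function(p)
    make_diag(p, cs))
  expect_equal(unname(crowd_majority(six)$probabilities), 0)

  set.seed(17)
  cs10 <- make_cases(rbinom(10, 1, 0.5))
  panel <- lapply(1:5, function(i) make_diag(runif(10), cs10,
                                             paste0("r", i)))
  maj <- crowd_majority(panel)
  manual <- sapply(cs10$case_id, function(id) {
    v <- sapply(panel, function(d) d$probabilities[[id]] > 0.5)
    as.numeric(sum(v) > sum(!v))
  })
  expect_equal(maj$probabilities, manual)
})

test_that("odd-panel majority equals binarized crowd median", {
  set.seed(53)
  for (rep in 1:20) {
    cs <- make_cases(rbinom(8, 1, 0.4))
    panel <- lapply(1:7, function(i) make_diag(runif(8), cs,
                                               paste0("r", i)))
    maj <- crowd_majority(panel)$probabilities
    med <- sapply(cs$case_id, function(id)
      stats::median(sapply(panel, function(d) d$probabilities[[id]])))
    expect_equal(unname(maj), unname(as.numeric(med > 0.5)))
  }
})

test_that("Youden threshold maximizes J over observed candidates", {
  cs <- make_cases(c(0, 0, 1, 1))
  d <- make_diag(c(0.1, 0.2, 0.6, 0.8), cs)
  expect_equal(youden_threshold(d, cs), 0.2)  # J = 1 there

  # anti-separated: J <= 0 everywhere, argmax still returned
  d_rev <- make_diag(c(0.8, 0.6, 0.2, 0.1), cs)
  t_rev <- youden_threshold(d_rev, cs)
  expect_true(t_rev %in% d_rev$probabilities)

  # flat probabilities: J = 0
  d_flat <- make_diag(rep(0.3, 4), cs)
  expect_equal(youden_threshold(d_flat, cs), 0.3)

  expect_error(youden_threshold(d, make_cases(c(1, 1, 1, 1))),
               "both classes")

  # brute force over a dense external grid never beats the result
  set.seed(71)
  for (rep in 1:10) {
    cs2 <- make_cases(rbinom(12, 1, 0.5))
    if (n_positive(cs2) == 0 || n_negative(cs2) == 0) next
    d2 <- make_diag(runif(12), cs2)
    jfun <- function(t) {
      pred <- probs_for(d2, cs2) > t
      sum(pred & cs2$label == 1) / n_positive(cs2) +
        sum(!pred & cs2$label == 0) / n_negative(cs2) - 1
    }
    t_star <- youden_threshold(d2, cs2)
    grid_best <- max(sapply(seq(0.001, 0.999, by = 0.001), jfun))
    expect_gte(jfun(t_star) + 1e-9, grid_best)
  }
})

test_that("confusion counts tally against labels", {
  cs <- make_cases(c(rep(1, 20), rep(0, 30)))
  perfect <- stats::setNames(cs$label, cs$case_id)
  cm <- confusion(perfect, cs)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(20L, 30L, 0L, 0L))

  all_neg <- stats::setNames(rep(0L, 50), cs$case_id)
  cm0 <- confusion(all_neg, cs)
  expect_equal(cm0$tp, 0L)
  expect_equal(cm0$fn, 20L)

  set.seed(41)
  pred <- stats::setNames(rbinom(50, 1, 0.5), cs$case_id)
  cm_r <- confusion(pred, cs)
  expect_equal(cm_r$tp, sum(pred == 1 & cs$label == 1))
  expect_equal(cm_r$tn, sum(pred == 0 & cs$label == 0))
  expect_equal(cm_r$tp + cm_r$fn, n_positive(cs))
  expect_equal(cm_r$tn + cm_r$fp, n_negative(cs))

  expect_error(confusion(pred[-1], cs), "missing prediction")
})

test_that("row sums equal class counts across random binarizations", {
  set.seed(61)
  for (rep in 1:20) {
    cs <- make_cases(rbinom(15, 1, 0.4))
    d <- make_diag(runif(15), cs)
    cm <- confusion(binarize(d, runif(1, 0.1, 0.9)), cs)
    expect_equal(cm$tp + cm$fn, n_positive(cs))
    expect_equal(cm$tn + cm$fp, n_negative(cs))
  }
})

test_that("printed operating points invert to integer counts", {
  cm <- confusion_from_rates(0.900, 0.767, 20, 30)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(18L, 2L, 23L, 7L))
  cm2 <- confusion_from_rates(1, 1, 20, 30)
  expect_equal(c(cm2$tp, cm2$tn), c(20L, 30L))
  cm3 <- confusion_from_rates(0.875, 0.933, 40, 60)
  expect_equal(c(cm3$tp, cm3$fn, cm3$tn, cm3$fp), c(35L, 5L, 56L, 4L))
  # half-up, not banker's
  cm4 <- confusion_from_rates(0.25, 0.25, 10, 10)
  expect_equal(cm4$tp, 3L)
})
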