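test_that("routing selects exactly the closed-band cases", {
  ml <- diagnosis_set("ml", c(a = 0.01, b = 0.04, c = 0.9), kind = "ml")
  plan <- route(ml, c(0.025, 0.055), threshold = 0.04008)
  expect_equal(plan$routed, "b")
  expect_equal(plan$neg_pred, "b")  # 0.04 <= threshold
  expect_length(plan$pos_pred, 0)

  none <- route(ml, c(0.45, 0.55), threshold = 0.5)
  expect_length(none$routed, 0)

  all_in <- route(ml, c(0.001, 0.999), threshold = 0.5)
  expect_setequal(all_in$routed, c("a", "b", "c"))

  empty <- diagnosis_set("e", stats::setNames(numeric(0), character(0)),
                         kind = "ml")
  expect_error(route(empty), "empty")
  expect_error(route(ml, c(0.5, 0.4)), "band")
})

test_that("band membership is closed at both edges", {
  ml <- diagnosis_set("ml", c(lo = 0.025, hi = 0.055, mid = 0.04),
                      kind = "ml")
  plan <- route(ml, c(0.025, 0.055))
  expect_setequal(plan$routed, c("lo", "hi", "mid"))
  plan2 <- route(ml, c(0.026, 0.054))  # edges excluded
  expect_setequal(plan2$routed, "mid")
})

test_that("augmentation substitutes swarm probabilities on routed cases", {
  cs <- make_cases(c(0, 0, 1))
  ml <- make_diag(c(0.01, 0.04, 0.9), cs, "ml", kind = "ml")
  sw <- make_diag(c(0.3, 0.1, 0.8), cs, "sw", kind = "swarm")

  empty_plan <- route(ml, c(0.45, 0.55), threshold = 0.04008)
  aug0 <- augment(ml, sw, empty_plan)
  expect_equal(aug0$probabilities, ml$probabilities)
  expect_equal(predictions_of(aug0),
               binarize(ml, 0.04008))

  full_plan <- route(ml, c(0.001, 0.999), threshold = 0.04008)
  aug1 <- augment(ml, sw, full_plan)
  expect_equal(aug1$probabilities, sw$probabilities)
  expect_equal(predictions_of(aug1), binarize(sw, 0.5))

  plan <- route(ml, c(0.025, 0.055), threshold = 0.04008)
  aug <- augment(ml, sw, plan)
  expect_identical(aug$kind, "augmented")
  # b routed (swarm 0.1 at human cutoff -> 0); a, c machine at 0.04008
  expect_equal(predictions_of(aug), c(c01 = 0L, c02 = 0L, c03 = 1L))
  origin <- attr(aug, "origin")
  expect_equal(unname(origin[c("c01", "c02", "c03")]),
               c("ml", "swarm", "ml"))
  # substitution conservation: same cases, each from exactly one source
  expect_setequal(names(aug$probabilities), names(ml$probabilities))
  expect_error(auc(aug, cs), "mix")

  sw_short <- diagnosis_set("sw", c(c01 = 0.3), kind = "swarm")
  expect_error(augment(ml, sw_short, plan), "missing routed case")
})

test_that("sweep endpoints equal the machine-only and swarm-only scores", {
  set.seed(12)
  cs <- make_cases(c(rep(1, 8), rep(0, 12)))
  op_ml <- operating_point(0.9, 0.75, 0.04008, sigma = 0.8)
  ml <- gen_probs(cs, op_ml, source_id = "ml", kind = "ml")
  sw <- gen_probs(cs, operating_point(0.7, 0.9, 0.5, sigma = 1),
                  source_id = "sw", kind = "swarm")
  res <- sweep_deferral(ml, sw, cs, threshold = 0.04008, n_boot = 50,
                        seed = 1)
  ml_acc <- mean(binarize(ml, 0.04008)[cs$case_id] == cs$label)
  sw_acc <- mean(binarize(sw, 0.5)[cs$case_id] == cs$label)
  expect_equal(res$accuracy[1], ml_acc)
  expect_equal(res$accuracy[nrow(res)], sw_acc)
  expect_equal(res$n_routed[1], 0L)
  expect_equal(res$n_routed[nrow(res)], 20L)
  expect_equal(res$delta_vs_ml, res$accuracy - ml_acc)
  # fractions monotone non-decreasing; CI brackets the mean
  expect_true(all(diff(res$n_routed) >= 0))
  expect_true(all(res$ci_lo <= res$accuracy + 1e-9))
  expect_true(all(res$ci_hi >= res$accuracy - 1e-9))
})

test_that("sweep selection is nested and caps one-sided exhaustion", {
  set.seed(30)
  cs <- make_cases(c(rep(1, 6), rep(0, 14)))
  ml <- make_diag(runif(20, 0.01, 0.12), cs, "ml", kind = "ml")
  sw <- make_diag(runif(20), cs, "sw", kind = "swarm")
  t <- 0.04008
  p <- probs_for(ml, cs)
  side_pos <- sum(p > t)
  side_neg <- sum(p <= t)
  res <- sweep_deferral(ml, sw, cs, threshold = t, n_boot = 10, seed = 2)
  expect_true(all(res$n_pos_side <= side_pos))
  expect_true(all(res$n_neg_side <= side_neg))
  # asymmetry is recorded once a side is exhausted
  tail_row <- res[nrow(res), ]
  expect_equal(tail_row$n_pos_side + tail_row$n_neg_side, 20L)
  if (side_pos != side_neg)
    expect_false(tail_row$n_pos_side == tail_row$n_neg_side)
})

test_that("a strictly better swarm makes augmented accuracy non-decreasing", {
  # constructed instance: swarm perfect on every case, machine wrong on
  # the low-confidence ones
  cs <- make_cases(rep(c(1, 0), each = 10))
  p_ml <- c(seq(0.045, 0.06, length.out = 10),     # positives, some below t
            seq(0.03, 0.045, length.out = 10))     # negatives, some above t
  ml <- make_diag(p_ml, cs, "ml", kind = "ml")
  sw <- make_diag(ifelse(cs$label == 1, 0.9, 0.1), cs, "sw",
                  kind = "swarm")
  res <- sweep_deferral(ml, sw, cs, threshold = 0.04008, n_boot = 10,
                        seed = 3)
  expect_true(all(diff(res$accuracy) >= -1e-12))
  expect_equal(res$accuracy[nrow(res)], 1)
})

test_that("label-balanced and logit-distance variants run", {
  set.seed(44)
  cs <- make_cases(rep(c(1, 0), each = 10))
  ml <- gen_probs(cs, operating_point(0.9, 0.75, 0.04008, 0.8),
                  source_id = "ml", kind = "ml")
  sw <- gen_probs(cs, operating_point(0.7, 0.9, 0.5, 1),
                  source_id = "sw", kind = "swarm")
  r1 <- sweep_deferral(ml, sw, cs, n_boot = 10, seed = 5,
                       balance = "label")
  r2 <- sweep_deferral(ml, sw, cs, n_boot = 10, seed = 5,
                       distance = "logit")
  ml_acc <- mean(binarize(ml, 0.04008)[cs$case_id] == cs$label)
  expect_equal(r1$accuracy[1], ml_acc)
  expect_equal(r2$accuracy[1], ml_acc)
  sw_acc <- mean(binarize(sw, 0.5)[cs$case_id] == cs$label)
  expect_equal(r1$accuracy[nrow(r1)], sw_acc)
  expect_equal(r2$accuracy[nrow(r2)], sw_acc)
})
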