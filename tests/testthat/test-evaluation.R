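# Metrics, thresholding, model comparison, bootstrap, published-row
# reconstruction.

test_that("MCC matches hand-verified confusion matrices", {
  expect_equal(round(mcc(confusion_matrix(32, 25, 21, 84)), 3), 0.368)
  expect_equal(mcc(confusion_matrix(53, 0, 0, 109)), 1)
  expect_equal(mcc(confusion_matrix(53, 109, 0, 0)), 0)  # zero marginal
  # invariant under simultaneous class swap
  cm <- confusion_matrix(12, 7, 9, 30)
  expect_equal(mcc(cm), mcc(confusion_matrix(30, 9, 7, 12)))
})

test_that("confusion_from_rates reconstructs the printed operating points", {
  cm <- confusion_from_rates(60.4, 77.1, 53, 109)
  expect_equal(unlist(cm[c("tp", "fn", "tn", "fp")]),
               c(tp = 32, fn = 21, tn = 84, fp = 25))
  r <- cm_rates(cm)
  expect_equal(round(unname(r["ppv"]), 1), 56.1)
  expect_equal(round(unname(r["npv"]), 1), 80.0)

  cm2 <- confusion_from_rates(100, 100, 10, 10)
  expect_equal(cm2$fp + cm2$fn, 0)

  r3 <- cm_rates(confusion_from_rates(66.7, 90.2, 39, 92))
  expect_equal(round(unname(r3["ppv"]), 1), 74.3)
  expect_equal(round(unname(r3["npv"]), 1), 86.5)
})

test_that("published rows reproduce printed MCC/PPV/NPV under rounding", {
  rec <- reconstruct_performance()
  expect_true(all(abs(rec$mcc_recomputed - rec$mcc_printed) < 5e-4))
  expect_true(all(abs(rec$ppv_recomputed - rec$ppv_printed) < 0.051))
  expect_true(all(abs(rec$npv_recomputed - rec$npv_printed) < 0.051))
})

test_that("equal sensitivity-specificity threshold matches a brute-force scan", {
  ps <- prediction_set(c(0.9, 0.7, 0.4, 0.8, 0.3, 0.2),
                       c(1, 1, 1, 0, 0, 0))
  es <- equal_ss_threshold(ps)
  # exhaustive oracle over all candidate midpoints
  u <- sort(unique(ps$probability))
  cand <- c(u[1] - 1e-9, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1e-9)
  dev <- vapply(cand, function(th)
    abs(mean(ps$probability[ps$label == 1] > th) -
        mean(ps$probability[ps$label == 0] <= th)), 0)
  sens <- mean(ps$probability[ps$label == 1] > es$threshold)
  spec <- mean(ps$probability[ps$label == 0] <= es$threshold)
  expect_equal(abs(sens - spec), min(dev), tolerance = 1e-12)

  perfect <- prediction_set(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  rp <- cm_rates(equal_ss_threshold(perfect)$cm)
  expect_equal(unname(rp["sensitivity"]), 100)
  expect_equal(unname(rp["specificity"]), 100)

  same <- prediction_set(rep(0.4, 10), rep(c(0, 1), 5))
  expect_warning(es2 <- equal_ss_threshold(same), "degenerate")
  expect_equal(es2$threshold, 0.5)
})

test_that("rank AUC equals the all-pairs oracle and its invariants hold", {
  pair_oracle <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg)
      s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(3)
  for (k in 1:20) {
    y <- c(rep(1, 7), rep(0, 13))
    p <- round(runif(20), 2)              # induce ties
    ps <- prediction_set(p, y)
    expect_equal(auc(ps), pair_oracle(p, y), tolerance = 1e-12)
    # invariance under a strictly monotone transform
    expect_equal(auc(prediction_set(plogis(5 * p - 2), y)), auc(ps),
                 tolerance = 1e-12)
  }
  expect_equal(auc(prediction_set(c(1, 1, 0, 0), c(1, 1, 0, 0))), 1)
  expect_equal(auc(prediction_set(rep(0.5, 10), rep(c(0, 1), 5))), 0.5)
})

test_that("Hotelling-Williams test behaves at the null and detects gaps", {
  w0 <- williams_test(0.4, 0.4, 0.2, 50)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)

  # antisymmetric in (r1, r2)
  wa <- williams_test(0.6, 0.3, 0.4, 100)
  wb <- williams_test(0.3, 0.6, 0.4, 100)
  expect_equal(wa$t, -wb$t)
  expect_equal(wa$p_value, wb$p_value)

  # reference-cohort-sized comparison: the printed MCC gap is significant
  # for plausible inter-model correlations (kappa between the two models
  # was 0.47; direction/significance check only)
  w <- williams_test(0.513, 0.368, 0.5, 162)
  expect_lt(w$p_value, 0.05)

  expect_error(williams_test(1, 0.5, 0.2, 50), "degenerate")
  expect_error(williams_test(0.4, 0.2, 0.1, 3), "exceed 3")
})

test_that("Cohen's kappa matches the closed form and conventions", {
  expect_equal(cohens_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(0, 0, 1, 1)), -1)
  # 2x2 table a=20 b=5 c=10 d=15 -> hand formula 0.4
  a <- c(rep(1, 25), rep(0, 25))
  b <- c(rep(1, 20), rep(0, 5), rep(1, 10), rep(0, 15))
  expect_equal(cohens_kappa(a, b), 0.4, tolerance = 1e-12)
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1)   # identical constants
})

test_that("stratified bootstrap CI is self-consistent", {
  set.seed(4)
  n <- 60
  y <- rep(c(1, 0), c(20, 40))
  p <- plogis(rnorm(n, mean = 2 * y - 1))
  ps <- prediction_set(p, y)

  # constant metric -> zero-width interval
  ci0 <- bootstrap_ci(ps, function(d) 0.7, n_boot = 50, seed = 1)
  expect_equal(unname(diff(ci0)), 0)

  # point estimate coverage (scaled: 20 seeded runs, 200 resamples)
  mcc_fun <- function(d) mcc(equal_ss_threshold(d)$cm)
  point <- mcc_fun(ps)
  hits <- vapply(1:20, function(s) {
    ci <- bootstrap_ci(ps, mcc_fun, n_boot = 200, seed = s)
    ci[1] <= point && point <= ci[2]
  }, TRUE)
  expect_gte(sum(hits), 18)

  # CI width shrinks with n
  mk <- function(n, seed) {
    set.seed(seed)
    y <- rbinom(n, 1, 1 / 3)
    prediction_set(plogis(rnorm(n, 2 * y - 1)), y)
  }
  w50 <- diff(bootstrap_ci(mk(50, 5), auc, n_boot = 300, seed = 6))
  w500 <- diff(bootstrap_ci(mk(500, 7), auc, n_boot = 300, seed = 8))
  expect_lt(w500, w50)
})

test_that("metric_report assembles the full row", {
  set.seed(9)
  y <- rep(c(1, 0), c(15, 30))
  ps <- prediction_set(plogis(rnorm(45, 2.5 * y - 1)), y)
  rep <- metric_report(ps, n_boot = 200, seed = 1)
  expect_true(rep$mcc_ci[1] <= rep$mcc && rep$mcc <= rep$mcc_ci[2])
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  expect_true(all(c(rep$sensitivity, rep$specificity, rep$ppv, rep$npv)
                  >= 0))
})
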