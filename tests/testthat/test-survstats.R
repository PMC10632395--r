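test_that("AUROC matches brute-force pair counting and pROC", {
  withr::with_seed(51, {
    scores <- c(rnorm(30, 1), rnorm(30))
    labels <- rep(c("high", "low"), each = 30)
  })
  est <- auroc(scores, labels)
  expect_equal(est$value, oracle_auroc(scores, labels), tolerance = 1e-12)
  expect_equal(est$value,
               as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("low", "high"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  # tied scores still match the half-credit convention
  tied <- round(scores)
  expect_equal(auroc(tied, labels)$value, oracle_auroc(tied, labels),
               tolerance = 1e-12)
})

test_that("AUROC extremes and error contract behave", {
  expect_equal(auroc(c(2, 3, 0, 1), c("high", "high", "low", "low"))$value, 1)
  est <- auroc(rep(1, 10), rep(c("high", "low"), 5))
  expect_equal(est$value, 0.5)
  expect_equal(est$p_value, 1)
  expect_error(auroc(1:3, c("high", "high", "high")), "both classes")
})

test_that("AUROC p-value agrees with the tie-corrected rank-sum test", {
  withr::with_seed(52, {
    scores <- c(rnorm(25, 0.7), rnorm(35))
    labels <- rep(c("high", "low"), c(25, 35))
  })
  est <- auroc(scores, labels)
  wt <- wilcox.test(scores[labels == "high"], scores[labels == "low"],
                    correct = FALSE, exact = FALSE)
  expect_equal(est$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("balanced accuracy averages sensitivity and specificity", {
  expect_equal(balanced_accuracy(c("high", "low"), c("high", "low")), 1)
  expect_equal(balanced_accuracy(rep("high", 6), rep(c("high", "low"), 3)), 0.5)
  # TP=3 FN=1 TN=2 FP=2 -> (0.75 + 0.5)/2
  pred <- c("high", "high", "high", "low", "low", "low", "high", "high")
  true <- c("high", "high", "high", "high", "low", "low", "low", "low")
  expect_equal(balanced_accuracy(pred, true), 0.625)
})

test_that("concordance index matches hand enumeration on the censored fixture", {
  expect_equal(concordance_index(c(3, 2, 1), c(3, 5, 7), c(1, 1, 1))$value, 1)
  # times (5,3,7), events (0,1,1), scores (1,3,2): two comparable pairs
  est <- concordance_index(c(1, 3, 2), c(5, 3, 7), c(0, 1, 1))
  expect_equal(est$value, 1)
  expect_equal(est$n, 2)
  expect_error(concordance_index(c(1, 2), c(5, 3), c(0, 0)), "comparable")
})

test_that("concordance index equals the O(n^2) oracle on censored data", {
  withr::with_seed(53, {
    n <- 200
    scores <- rnorm(n)
    times <- round(rexp(n, exp(0.4 * scores) / 500) + 1)
    events <- as.integer(runif(n) < 0.7)
  })
  est <- concordance_index(scores, times, events)
  o <- oracle_cindex(scores, times, events)
  expect_equal(est$value, o$c)
  expect_equal(est$n, o$n_comp)
  # cross-check against the survival package on tie-free data
  cfit <- survival::concordance(survival::Surv(times + runif(200) * 1e-6,
                                               events) ~ scores, reverse = TRUE)
  expect_equal(est$value, unname(cfit$concordance), tolerance = 0.01)
})

test_that("concordance and AUROC are invariant to monotone score transforms", {
  withr::with_seed(54, {
    scores <- runif(60); times <- rexp(60, 1 / 400) + 1
    events <- rbinom(60, 1, 0.8); labels <- rep(c("high", "low"), 30)
  })
  f <- function(x) exp(3 * x) - 1
  expect_equal(auroc(f(scores), labels)$value, auroc(scores, labels)$value)
  expect_equal(concordance_index(f(scores), times, events)$value,
               concordance_index(scores, times, events)$value)
})

test_that("with complete event data the C-index reduces to pairwise ordering", {
  withr::with_seed(55, {
    scores <- rnorm(40); times <- rexp(40) + 0.1
  })
  est <- concordance_index(scores, times, rep(1, 40))
  # oracle: fraction of pairs where shorter time has higher score
  o <- oracle_cindex(scores, times, rep(1, 40))
  expect_equal(est$value, o$c)
  expect_equal(est$n, choose(40, 2))
})

test_that("D-index conventions: constant scores and score reversal", {
  times <- rexp(50, 1 / 300) + 1; events <- rbinom(50, 1, 0.8)
  d0 <- d_index(rep(0.5, 50), times, events)
  expect_equal(d0$value, 1)
  expect_true(is.na(d0$se))

  withr::with_seed(56, scores <- rnorm(50))
  d_fwd <- d_index(scores, times, events)
  d_rev <- d_index(-scores, times, events)
  expect_lt(abs(log(d_fwd$value) + log(d_rev$value)), 1e-8)
})

test_that("D-index recovers a planted rankit effect and is null-calibrated", {
  # survival with hazard exp(0.5 z) on the scaled rankit of the score
  withr::with_seed(57, {
    n <- 2000
    scores <- rnorm(n)
    r <- rank(scores)
    z <- qnorm((r - 3 / 8) / (n + 1 / 4)) / sqrt(8 / pi)
    times <- rexp(n, exp(0.5 * z) / 500)
  })
  est <- d_index(scores, times, rep(1, n))
  expect_lt(abs(est$value - exp(0.5)) / exp(0.5), 0.10)

  # independent scores: log D within 3 se of zero; a single 3-sigma bound
  # fails by chance ~0.3% of the time, so assert it over a replicate panel
  ok <- vapply(1:5, function(rep) {
    withr::with_seed(580 + rep, {
      times0 <- rexp(n, 1 / 500); scores0 <- rnorm(n)
    })
    est0 <- d_index(scores0, times0, rep(1, n))
    abs(log(est0$value)) < 3 * est0$se
  }, logical(1))
  expect_gte(sum(ok), 4)
})

test_that("Kaplan-Meier estimator and median follow product-limit arithmetic", {
  km <- km_curve(1:5, rep(1, 5))
  expect_equal(km$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$times, 1:5)
  expect_equal(km$median, 3)
  expect_true(all(diff(km$survival) <= 0))

  km_c <- km_curve(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km_c$survival == 1))
  expect_true(is.na(km_c$median))
})

test_that("log-rank test is null on identical groups and detects separation", {
  times <- c(1:10, 1:10); events <- rep(1, 20)
  grp <- rep(c("a", "b"), each = 10)
  lr <- logrank_test(times, events, grp)
  expect_equal(lr$chi2, 0)
  expect_equal(lr$p, 1)
  lr2 <- logrank_test(c(1:10, 101:110), rep(1, 20), grp)
  expect_lt(lr2$p, 0.001)
  expect_error(logrank_test(1:3, rep(1, 3), c("a", "b", "c")), "two groups")
})

test_that("median split sends ties at the median to the low-risk group", {
  expect_equal(median_split(c(0.1, 0.2, 0.9, 1.0)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(0, 0.5, 0.5, 1)), c("low", "low", "low", "high"))
  expect_equal(median_split(c(0.1, 0.5, 0.9)), c("low", "low", "high"))
  expect_error(median_split(rep(0.3, 4)), "degenerate")
})
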