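mk_clin <- function(n, seed, p_event = 0.5, beta_age = 0, beta_stage = 0) {
  withr::with_seed(seed, {
    age <- rnorm(n, 60, 10)
    stage <- sample(1:4, n, replace = TRUE)
    lp <- qlogis(p_event) + beta_age * (age - 60) + beta_stage * (stage - 2.5)
    y <- runif(n) < plogis(lp)
    data.frame(sample_id = sprintf("s%04d", 1:n),
               label = ifelse(y, "high", "low"),
               age = age, figo_stage = stage, stringsAsFactors = FALSE)
  })
}

test_that("clinical logistic fit satisfies its likelihood equations", {
  clin <- mk_clin(1000, seed = 71, p_event = 0.3)
  fit <- fit_clinical_model(clin)
  expect_true(fit$converged)
  # score equation: mean fitted probability equals the event fraction
  expect_equal(mean(fitted(fit$fit)), mean(clin$label == "high"),
               tolerance = 1e-8)
  # outcome independent of covariates: slopes within 3 se of zero
  sm <- summary(fit$fit)$coefficients
  for (cv in c("age", "figo_stage"))
    expect_lt(abs(sm[cv, "Estimate"]), 3 * sm[cv, "Std. Error"])
  # 30% events: intercept near log(3/7) once slopes are null
  expect_lt(abs(sm["(Intercept)", "Estimate"] - qlogis(0.3)), 1)
})

test_that("clinical fit drops incomplete records and flags separation", {
  clin <- mk_clin(200, seed = 72)
  clin$age[1:15] <- NA
  fit <- fit_clinical_model(clin)
  expect_equal(fit$n, 185)
  expect_equal(fit$n_dropped, 15)

  # perfectly separating covariate -> non-converged flag
  sep <- mk_clin(60, seed = 73)
  sep$age <- ifelse(sep$label == "high", 80, 40)
  fit_sep <- fit_clinical_model(sep)
  expect_false(fit_sep$converged)

  few <- mk_clin(12, seed = 74)
  expect_error(fit_clinical_model(few), "at least 10")
})

test_that("univariable screen has one row per usable covariate and finds strong effects", {
  # constant covariate is excluded with a warning
  clin <- mk_clin(300, seed = 75)
  clin$age <- 60
  expect_warning(tab <- univariable_screen(clin), "constant")
  expect_equal(tab$covariate, "figo_stage")

  # simulated stage effect (OR 2 per stage) is detected in >= 9/10 seeds
  hits <- 0
  for (s in 1:10) {
    cl <- mk_clin(800, seed = 760 + s, beta_stage = log(2))
    tab <- univariable_screen(cl)
    hits <- hits + (tab$p[tab$covariate == "figo_stage"] < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("signature score matches its weighted-average definition", {
  expr <- rand_expr(8, 40, seed = 77)
  # single gene, weight 1: score is the rescaled gene within [-1, 1]
  s1 <- signature_score(expr, c(g01 = 1))
  expect_gte(min(s1$scores), -1); expect_lte(max(s1$scores), 1)
  qs <- quantile(expr["g01", ], c(0.025, 0.975), names = FALSE)
  resc <- 2 * (pmin(pmax(expr["g01", ], qs[1]), qs[2]) - qs[1]) /
    (qs[2] - qs[1]) - 1
  expect_equal(unname(s1$scores), unname(resc), tolerance = 1e-12)

  # equal and opposite weights on identical rows cancel to zero
  dup <- rbind(expr, gDUP = expr["g01", ])
  s0 <- signature_score(dup, c(g01 = 1, gDUP = -1))
  expect_equal(unname(s0$scores), rep(0, 40), tolerance = 1e-12)

  # random 5-gene weights equal an independently coded oracle
  w <- withr::with_seed(78, setNames(rnorm(5), rownames(expr)[1:5]))
  got <- signature_score(expr, w)$scores
  oracle <- {
    num <- rep(0, ncol(expr))
    for (g in names(w)) {
      qs <- quantile(expr[g, ], c(0.025, 0.975), names = FALSE)
      x <- pmin(pmax(expr[g, ], qs[1]), qs[2])
      num <- num + w[[g]] * (2 * (x - qs[1]) / (qs[2] - qs[1]) - 1)
    }
    num / sum(abs(w))
  }
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)

  # invariant to adding unweighted genes; absent genes dropped with a note
  expect_equal(signature_score(dup, w)$scores, got)
  expect_message(s_m <- signature_score(expr, c(w, gZZ = 2)), "gZZ")
  expect_equal(s_m$missing_genes, "gZZ")
  expect_error(signature_score(expr, c(gZZ = 1)), "no weighted genes")
})

test_that("reduction sweep reports pair budgets consistently", {
  st <- small_study(seed = 79, effect_delta = 0.8)
  tc <- list(B = 4, resample_fraction = 0.8, m = 20)
  sw <- reduction_sweep(st$training, st$validation, sizes = c(1, 3, 5),
                        train_config = tc, seed = 80)
  expect_equal(nrow(sw), 3)
  # greedy selections are nested across budgets, so gene counts grow
  expect_true(all(diff(sw$distinct_genes) >= 0))
  expect_true(all(diff(sw$distinct_pairs) >= 0))
  expect_true(sw$within_tolerance[3])             # full row trivially flagged
  # full-budget row equals an independent run of the same configuration
  ens_full <- train_ensemble(st$training, B = 4, m = 20, k_grid = 5,
                             cv_folds = 1, seed = 80)
  ev <- lapply(st$validation, function(co) {
    fc <- filter_for_binary_eval(co)
    auroc(score_ensemble(ens_full, fc$expression), fc$clinical$label, co$name)
  })
  expect_equal(sw$meta_auroc[3], pool_random_effects(ev)$value,
               tolerance = 1e-12)
  # a budget that keeps only the strongest (planted) pairs performs within
  # 0.05 of the full model
  expect_gte(sw$meta_auroc[2], sw$meta_auroc[3] - 0.05)
})

test_that("hypergeometric enrichment matches exact enumeration for small universes", {
  # closed-form corner: signature of 5, set of 5, universe of 10, overlap 5
  uni <- paste0("u", 1:10)
  res <- hypergeometric_enrichment(uni[1:5], list(hit = uni[1:5]), uni)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  # exhaustive combn oracle over every configuration with |universe| <= 12
  for (cfg in list(c(N = 8, K = 3, n = 4), c(N = 10, K = 5, n = 5),
                   c(N = 12, K = 6, n = 4), c(N = 12, K = 4, n = 7))) {
    N <- cfg[["N"]]; K <- cfg[["K"]]; n <- cfg[["n"]]
    uni <- paste0("g", seq_len(N))
    gset <- uni[seq_len(K)]
    sig <- withr::with_seed(81 + N + K + n, sample(uni, n))
    ov <- length(intersect(sig, gset))
    draws <- combn(N, n)
    tail_exact <- mean(apply(draws, 2, function(ix)
      length(intersect(uni[ix], gset)) >= ov))
    got <- hypergeometric_enrichment(sig, list(s = gset), uni)
    expect_equal(got$p, tail_exact, tolerance = 1e-12)
  }

  # overlap 0 has tail probability 1; BH over all-ones stays 1
  res0 <- hypergeometric_enrichment(paste0("g", 1:3),
                                    list(a = "g9", b = "g10"),
                                    paste0("g", 1:10))
  expect_true(all(res0$p == 1))
  expect_true(all(res0$fdr == 1))
  expect_error(hypergeometric_enrichment("g1", list(a = "g1"), character(0)),
               "empty universe")
})

test_that("GMT collections round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
})
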