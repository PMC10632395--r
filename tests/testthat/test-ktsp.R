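test_that("pair scoring matches per-sample counting exactly", {
  expr <- rand_expr(6, 20, seed = 31)
  labels <- withr::with_seed(32, sample(c(TRUE, FALSE), 20, replace = TRUE))
  tab <- pair_score_table(expr, labels)
  for (r in seq_len(nrow(tab))) {
    o <- oracle_pair_stats(expr, labels, tab$gene_i[r], tab$gene_j[r])
    expect_equal(tab$delta[r], o$delta)
    expect_equal(tab$orientation[r], o$orientation)
    expect_equal(tab$gamma[r], o$gamma)
    ps <- pair_score(expr, labels, tab$gene_i[r], tab$gene_j[r])
    expect_equal(ps$delta, o$delta)
    expect_equal(ps$gamma, o$gamma)
  }
})

test_that("pair score hits its extremes", {
  # perfect pair: Xi < Xj in every high sample, never in low
  expr <- rbind(gA = c(1, 1, 3, 3), gB = c(2, 2, 2, 2))
  colnames(expr) <- paste0("s", 1:4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  ps <- pair_score(expr, labels, "gA", "gB")
  expect_equal(ps$delta, 1.0)
  expect_true(ps$orientation)
  expect_gt(ps$gamma, 0)
  # indistinguishable orderings: delta 0
  expr2 <- rbind(gA = c(1, 3, 1, 3), gB = c(2, 2, 2, 2))
  colnames(expr2) <- paste0("s", 1:4)
  expect_equal(pair_score(expr2, labels, "gA", "gB")$delta, 0)
  expect_error(pair_score(expr, c(TRUE, TRUE, TRUE, TRUE), "gA", "gB"),
               "non-empty")
})

test_that("rank-sum filter agrees with a direct computation", {
  expr <- rand_expr(10, 30, seed = 33)
  labels <- rep(c(TRUE, FALSE), c(14, 16))
  n <- 30; n1 <- 14; n0 <- 16
  z_direct <- apply(expr, 1, function(x) {
    r <- rank(x)
    (sum(r[labels]) - n1 * (n + 1) / 2) / sqrt(n1 * n0 * (n + 1) / 12)
  })
  ord <- order(-abs(z_direct), rownames(expr))
  for (m in c(1, 4, 10))
    expect_identical(wilcoxon_filter(expr, labels, m),
                     rownames(expr)[ord][seq_len(m)])
  expect_error(wilcoxon_filter(expr, labels, 0), "positive")
})

test_that("rank-sum filter ranks degenerate and separated genes correctly", {
  expr <- rand_expr(5, 20, seed = 34)
  labels <- rep(c(TRUE, FALSE), each = 10)
  expr["g01", ] <- 7                             # identical in both classes
  expr["g02", ] <- ifelse(labels, 10, -10)       # complete separation
  kept <- wilcoxon_filter(expr, labels, 5)
  expect_equal(kept[1], "g02")
  expect_equal(kept[5], "g01")
})

test_that("training selects a planted perfect pair with correct orientation", {
  expr <- rand_expr(8, 30, seed = 35)
  labels <- rep(c(TRUE, FALSE), each = 15)
  expr["g03", ] <- ifelse(labels, 0, 2)   # Xi < Xj exactly in class high
  expr["g07", ] <- 1
  mod <- train_ktsp(expr, labels, m = 8, k_grid = 1)
  expect_equal(mod$k, 1)
  expect_setequal(c(mod$pairs$gene_i, mod$pairs$gene_j), c("g03", "g07"))
  expect_equal(mod$pairs$delta, 1)
  # oriented so that the rule votes high
  pred <- predict_model(mod, expr)
  expect_equal(unname(pred), ifelse(labels, "high", "low"))
})

test_that("selected pairs equal exhaustive enumeration under the stated ordering", {
  for (seed in c(41, 42, 43)) {
    expr <- rand_expr(8, 30, seed = seed)
    labels <- withr::with_seed(seed + 100,
                               sample(rep(c(TRUE, FALSE), each = 15)))
    mod <- train_ktsp(expr, labels, m = 8, k_grid = 3)
    # oracle: score all 28 pairs by counting, order, greedy disjoint
    gn <- rownames(expr)
    rows <- list()
    for (i in 1:7) for (j in (i + 1):8) {
      o <- oracle_pair_stats(expr, labels, gn[i], gn[j])
      rows[[length(rows) + 1]] <- data.frame(
        gene_i = gn[i], gene_j = gn[j], delta = o$delta, gamma = o$gamma,
        pair_id = paste(gn[i], gn[j], sep = "|"), stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(-tab$delta, -tab$gamma, tab$pair_id), ]
    used <- character(0); picked <- character(0)
    for (r in seq_len(nrow(tab))) {
      if (length(picked) == 3) break
      if (tab$gene_i[r] %in% used || tab$gene_j[r] %in% used) next
      picked <- c(picked, tab$pair_id[r])
      used <- c(used, tab$gene_i[r], tab$gene_j[r])
    }
    expect_identical(mod$pairs$pair_id, picked)
  }
})

test_that("barcode bits implement the strict-less rule including ties", {
  expr <- rbind(gA = c(1, 2, 2), gB = c(2, 1, 2))
  colnames(expr) <- paste0("s", 1:3)
  pairs <- data.frame(gene_i = "gA", gene_j = "gB")
  expect_equal(as.vector(barcode_transform(expr, pairs)), c(1, 0, 0))
  expect_error(barcode_transform(expr, data.frame(gene_i = "gA", gene_j = "gZ")),
               "gZ")
})

test_that("barcodes are invariant to within-sample monotone transforms", {
  expr <- abs(rand_expr(6, 10, seed = 36)) + 0.5    # all positive
  pairs <- data.frame(gene_i = c("g01", "g03"), gene_j = c("g02", "g05"))
  b <- barcode_transform(expr, pairs)
  expect_identical(barcode_transform(log2(expr), pairs), b)
  expect_identical(barcode_transform(apply(expr, 2, rank), pairs), b)
  expect_identical(barcode_transform(3 * expr + 7, pairs), b)
})

test_that("majority vote and ensemble score follow their definitions", {
  # k=3 with oriented votes (1,1,0) -> high
  expr <- rbind(g1 = 1, g2 = 2, g3 = 1, g4 = 2, g5 = 2, g6 = 1)
  colnames(expr) <- "s1"
  pairs <- data.frame(gene_i = c("g1", "g3", "g5"),
                      gene_j = c("g2", "g4", "g6"),
                      orientation = c(TRUE, TRUE, TRUE),
                      delta = 1, gamma = 1,
                      pair_id = c("g1|g2", "g3|g4", "g5|g6"),
                      stringsAsFactors = FALSE)
  mod <- structure(list(pairs = pairs, k = 3, training_meta = list()),
                   class = "ktsp_model")
  expect_equal(unname(predict_model(mod, expr)), "high")

  # B=4 members voting high,high,low,low -> score 0.5
  flip <- pairs; flip$orientation <- c(FALSE, FALSE, FALSE)
  mod_lo <- structure(list(pairs = flip, k = 3, training_meta = list()),
                      class = "ktsp_model")
  ens <- structure(list(models = list(mod, mod, mod_lo, mod_lo),
                        gene_universe = rownames(expr), meta = list(B = 4)),
                   class = "ktsp_ensemble")
  expect_equal(unname(score_ensemble(ens, expr)), 0.5)
})

test_that("a B=1 ensemble reduces to the single model", {
  st <- small_study(seed = 14)
  ens <- train_ensemble(st$training, B = 1, m = 20, k_grid = 3, seed = 3)
  co <- st$validation[[1]]
  sc <- score_ensemble(ens, co$expression)
  expect_true(all(sc %in% c(0, 1)))
  expect_equal(sc == 1,
               predict_model(ens$models[[1]], co$expression) == "high")
})

test_that("ensemble training enforces disjointness and reuses genes across members", {
  st <- small_study(seed = 15)
  ens <- train_ensemble(st$training, B = 10, m = 20, k_grid = 3, seed = 4)
  for (mo in ens$models) {
    genes <- c(mo$pairs$gene_i, mo$pairs$gene_j)
    expect_equal(anyDuplicated(genes), 0)      # no gene in two pairs
    expect_equal(mo$k, nrow(mo$pairs))
    expect_equal(mo$k %% 2, 1)
  }
  # pair overlap across members: distinct genes < 2 * distinct pairs would
  # only fail if every pair across all members were unique AND gene-disjoint
  expect_lte(length(ens$distinct_genes), 2 * length(ens$distinct_pairs))
  expect_lt(length(ens$distinct_pairs), 10 * 3)  # members share pairs
})

test_that("ensemble risk scores are identical across platform transforms", {
  st <- small_study(seed = 16)
  ens <- train_ensemble(st$training, B = 5, m = 20, k_grid = 3, seed = 5)
  co <- st$validation[[1]]
  sc <- score_ensemble(ens, co$expression)
  # per-sample monotone transforms: log2 (positive shift), affine, ranks
  pos <- apply(co$expression, 2, function(x) x - min(x) + 1)
  dimnames(pos) <- dimnames(co$expression)
  expect_identical(score_ensemble(ens, log2(pos)), sc)
  expect_identical(score_ensemble(ens, 0.3 * co$expression - 11), sc)
  rk <- apply(co$expression, 2, rank); dimnames(rk) <- dimnames(co$expression)
  expect_identical(score_ensemble(ens, rk), sc)
})

test_that("model JSON round-trips pairs, orientations and predictions", {
  st <- small_study(seed = 17)
  ens <- train_ensemble(st$training, B = 3, m = 20, k_grid = 3, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(ens, path)
  ens2 <- read_model_json(path)
  expect_equal(length(ens2$models), 3)
  expect_equal(ens2$distinct_pairs, ens$distinct_pairs)
  co <- st$validation[[2]]
  expect_equal(score_ensemble(ens2, co$expression),
               score_ensemble(ens, co$expression))
  # determinism: retraining with the same seed is byte-identical JSON
  ens3 <- train_ensemble(st$training, B = 3, m = 20, k_grid = 3, seed = 6)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(ens3, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("planted pairs dominate selection when the signal is strong", {
  st <- small_study(seed = 18, effect_delta = 0.9, n_genes = 40,
                    n_signal_pairs = 2)
  ens <- train_ensemble(st$training, B = 8, m = 20, k_grid = 3, seed = 7)
  truth_ids <- pair_ids_of(st$truth$pairs)
  expect_gte(sum(truth_ids %in% ens$distinct_pairs), 1)
})
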