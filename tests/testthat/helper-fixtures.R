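# Fixture builders shared across test files.  Everything is generated in
# code under fixed seeds; nothing is read from disk.

# genes x samples matrix of standard normals with stable dimnames
rand_expr <- function(n_genes, n_samples, seed) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    m
  })
}

# clinical table with n samples matching expression colnames
rand_clinical <- function(sample_ids, seed, censor_frac = 0.2) {
  withr::with_seed(seed, {
    n <- length(sample_ids)
    data.frame(sample_id = sample_ids,
               dfs_time_days = round(rexp(n, 1 / 700) + 1),
               dfs_event = as.integer(runif(n) > censor_frac),
               age = round(rnorm(n, 60, 10), 1),
               figo_stage = sample(2:4, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

# cohort layout a quarter the default size, for fast pipeline/null tests:
# dual-platform training of 30 patients, two validation cohorts of 40
small_specs <- function() {
  data.frame(
    name = c("train_seq", "train_array", "W1", "W2"),
    n_samples = c(30, 30, 40, 40),
    platform = c("sequencing", "array", "sequencing", "array"),
    transform = c("identity", "quantile_rankscale", "log2", "affine"),
    affine_a = c(1, 1, 1, 2),
    affine_b = c(0, 0, 0, 5),
    batch_shift = c(0, 0, 1, -1),
    role = c("train", "train", "validate", "validate"),
    stringsAsFactors = FALSE)
}

small_study <- function(seed = 11, effect_delta = 0.6, n_genes = 60,
                        n_signal_pairs = 3) {
  simulate_study(simulation_config(
    n_genes = n_genes, n_signal_pairs = n_signal_pairs,
    effect_delta = effect_delta, cohort_specs = small_specs(), seed = seed))
}

small_train_config <- list(B = 3, resample_fraction = 0.8, m = 20,
                           k_grid = 3, cv_folds = 3)

pair_ids_of <- function(truth_pairs) {
  apply(cbind(truth_pairs$gene_i, truth_pairs$gene_j), 1,
        function(r) paste(sort(r), collapse = "|"))
}

# independent brute-force TSP statistics for one pair: per-sample counting
oracle_pair_stats <- function(expr, labels, gi, gj) {
  labels <- if (is.logical(labels)) labels else labels == "high"
  cnt_h <- cnt_l <- n_h <- n_l <- 0
  for (s in seq_len(ncol(expr))) {
    less <- expr[gi, s] < expr[gj, s]
    if (labels[s]) { n_h <- n_h + 1; cnt_h <- cnt_h + less }
    else { n_l <- n_l + 1; cnt_l <- cnt_l + less }
  }
  p_h <- cnt_h / n_h; p_l <- cnt_l / n_l
  rk <- apply(expr, 2, rank)
  gap_h <- gap_l <- c()
  for (s in seq_len(ncol(expr))) {
    gp <- rk[gj, s] - rk[gi, s]
    if (labels[s]) gap_h <- c(gap_h, gp) else gap_l <- c(gap_l, gp)
  }
  # exact half-integer sums, one division each: comparable bit-for-bit
  list(delta = abs(p_h - p_l), orientation = p_h >= p_l,
       gamma = abs(sum(gap_h) / n_h - sum(gap_l) / n_l))
}
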