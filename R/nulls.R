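# Shared evaluation used by the pipeline and both permutation tests:
# score every validation cohort with the ensemble, compute per-cohort
# AUROC on binary-evaluable samples, pool by random effects, and compute
# balanced accuracy over the concatenated validation samples (ensemble
# label = risk score > 0.5).  An AUROC se of exactly 0 (perfect
# separation on a tiny cohort) is floored at 1/(n1*n0) here so pooling
# stays defined inside permutation replicates.
eval_validation_auroc <- function(ensemble, validation) {
  ests <- list()
  pred_all <- character(0); truth_all <- character(0)
  for (co in validation) {
    fc <- filter_for_binary_eval(co)
    sc <- score_ensemble(ensemble, fc$expression)
    est <- auroc(sc, fc$clinical$label, cohort = co$name)
    if (!is.finite(est$se) || est$se <= 0) {
      lab <- fc$clinical$label == "high"
      est$se <- 1 / (sum(lab) * sum(!lab))
    }
    ests[[co$name]] <- est
    pred_all <- c(pred_all, ifelse(sc > 0.5, "high", "low"))
    truth_all <- c(truth_all, fc$clinical$label)
  }
  meta <- if (length(ests) >= 2) pool_random_effects(ests) else ests[[1]]
  list(meta = meta, value = meta$value, estimates = ests,
       bac = balanced_accuracy(pred_all, truth_all))
}

#' Permutation-result container
#'
#' @keywords internal
permutation_result <- function(observed, null_values, test, seed,
                               observed_bac = NA_real_, null_bac = NULL) {
  p <- (1 + sum(null_values >= observed)) / (length(null_values) + 1)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, test = test, seed = seed,
                 observed_bac = observed_bac, null_bac = null_bac),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s: observed = %.4f, B_perm = %d, p = %.4g\n",
              x$test, x$observed, length(x$null_values), x$p_value))
  invisible(x)
}

#' Label-shuffle permutation test of the trained pipeline
#'
#' Repeatedly permutes the training labels at the patient level (the
#' dual-platform pairing of instances stays intact and class prevalence
#' is preserved exactly), retrains the full ensemble with the identical
#' configuration, and records the validation meta-AUROC of each null
#' model.  The p-value uses greater-or-equal counting with +1 smoothing,
#' \eqn{p = (1 + \#\{null \ge observed\})/(B_{perm} + 1)}, so it is never
#' zero.
#'
#' @param training,validation lists of [cohort_profile()]s.
#' @param train_config list with elements \code{B},
#'   \code{resample_fraction}, \code{m}, \code{k_grid}, \code{cv_folds}
#'   (missing entries take [train_ensemble()] defaults).
#' @param B_perm number of permutations (>= 1).
#' @param seed root seed; replicate r uses a derived substream.
#' @return a \code{permutation_result}; \code{null_bac} carries the null
#'   models' balanced accuracies.
#' @export
label_shuffle_test <- function(training, validation, train_config = list(),
                               B_perm = 1000, seed = 1) {
  stop_if(B_perm < 1, "B_perm must be >= 1")
  if (inherits(training, "cohort_profile")) training <- list(training)
  tc <- modifyList(list(B = 512, resample_fraction = 0.8, m = 200,
                        k_grid = seq(3, 25, by = 2), cv_folds = 5),
                   train_config)
  fit_eval <- function(cohorts, fit_seed) {
    ens <- train_ensemble(cohorts, B = tc$B,
                          resample_fraction = tc$resample_fraction,
                          m = tc$m, k_grid = tc$k_grid,
                          cv_folds = tc$cv_folds, seed = fit_seed)
    eval_validation_auroc(ens, validation)
  }
  obs <- fit_eval(training, substream(seed, 0))

  labels <- training[[1]]$clinical$label
  nulls <- numeric(B_perm); null_bac <- numeric(B_perm)
  for (r in seq_len(B_perm)) {
    sr <- substream(seed, r)
    perm <- with_seed(sr, sample(labels))
    shuffled <- lapply(training, function(co) {
      co$clinical$label <- perm
      co
    })
    res <- fit_eval(shuffled, sr)
    nulls[r] <- res$value
    null_bac[r] <- res$bac
  }
  permutation_result(obs$value, nulls, "label_shuffle", seed,
                     observed_bac = obs$bac, null_bac = null_bac)
}

#' Random-gene permutation test of a trained ensemble
#'
#' Keeps the trained ensemble's architecture fixed (same number of
#' models, same k per model, same orientation flags) but replaces every
#' model's gene pairs with disjoint pairs sampled uniformly from the
#' training gene universe, isolating gene identity as the tested factor.
#' Each null ensemble is evaluated by validation meta-AUROC.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param validation list of [cohort_profile()]s.
#' @param B_perm number of null ensembles.
#' @param seed root seed.
#' @return a \code{permutation_result} with \code{null_bac}.
#' @export
random_gene_test <- function(ensemble, validation, B_perm = 1000, seed = 1) {
  stop_if(B_perm < 1, "B_perm must be >= 1")
  universe <- ensemble$gene_universe
  stop_if(length(universe) <= length(ensemble$distinct_genes),
          "gene universe must exceed the ensemble's distinct gene count")
  obs <- eval_validation_auroc(ensemble, validation)

  nulls <- numeric(B_perm); null_bac <- numeric(B_perm)
  for (r in seq_len(B_perm)) {
    sr <- substream(seed, r)
    rand_ens <- with_seed(sr, {
      models <- lapply(ensemble$models, function(mo) {
        k <- mo$k
        g <- sample(universe, 2 * k)
        pr <- data.frame(gene_i = g[seq_len(k)],
                         gene_j = g[k + seq_len(k)],
                         delta = NA_real_,
                         orientation = mo$pairs$orientation,
                         gamma = NA_real_,
                         stringsAsFactors = FALSE)
        pr$pair_id <- paste(pr$gene_i, pr$gene_j, sep = "|")
        structure(list(pairs = pr, k = k, training_meta = mo$training_meta),
                  class = "ktsp_model")
      })
      structure(list(models = models, gene_universe = universe,
                     meta = ensemble$meta),
                class = "ktsp_ensemble")
    })
    res <- eval_validation_auroc(rand_ens, validation)
    nulls[r] <- res$value
    null_bac[r] <- res$bac
  }
  permutation_result(obs$value, nulls, "random_genes", seed,
                     observed_bac = obs$bac, null_bac = null_bac)
}
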