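#' Evaluate a trained ensemble on a list of cohorts
#'
#' For every cohort: scores all samples, computes AUROC and balanced
#' accuracy on the binary-evaluable subset (undefined labels excluded),
#' the C-index and D-index on the full censored survival data, and a
#' within-cohort median split of the risk score with Kaplan-Meier group
#' medians and the log-rank test.
#'
#' @param ensemble a [train_ensemble()] result.
#' @param cohorts list of [cohort_profile()]s.
#' @return list with \code{table} (one row per cohort), and the
#'   per-cohort estimate lists \code{auroc}, \code{cindex}, \code{dindex},
#'   \code{km} (per-group curves) and \code{scores}.
#' @export
evaluate_ensemble <- function(ensemble, cohorts) {
  au <- ci <- di <- km <- scores <- list()
  rows <- list()
  for (co in cohorts) {
    sc <- score_ensemble(ensemble, co$expression)
    scores[[co$name]] <- sc
    fc <- filter_for_binary_eval(co)
    sc_bin <- sc[fc$clinical$sample_id]
    a <- auroc(sc_bin, fc$clinical$label, cohort = co$name)
    bac <- balanced_accuracy(ifelse(sc_bin > 0.5, "high", "low"),
                             fc$clinical$label)
    tt <- co$clinical$dfs_time_days; ev <- co$clinical$dfs_event
    cc <- concordance_index(sc, tt, ev, cohort = co$name)
    dd <- d_index(sc, tt, ev, cohort = co$name)

    split <- tryCatch(median_split(sc), error = function(e) NULL)
    if (!is.null(split)) {
      lr <- logrank_test(tt, ev, split)
      km_hi <- km_curve(tt[split == "high"], ev[split == "high"])
      km_lo <- km_curve(tt[split == "low"], ev[split == "low"])
      med_gap <- km_lo$median - km_hi$median
    } else {
      lr <- list(chi2 = NA_real_, p = NA_real_)
      km_hi <- km_lo <- NULL
      med_gap <- NA_real_
    }
    au[[co$name]] <- a; ci[[co$name]] <- cc; di[[co$name]] <- dd
    km[[co$name]] <- list(high = km_hi, low = km_lo, logrank = lr,
                          split = split)
    rows[[co$name]] <- data.frame(
      cohort = co$name, platform = co$platform, n = ncol(co$expression),
      n_binary = ncol(fc$expression),
      auroc = a$value, auroc_p = a$p_value, bac = bac,
      cindex = cc$value, cindex_p = cc$p_value,
      dindex = dd$value, dindex_p = dd$p_value,
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      median_dfs_low = if (is.null(km_lo)) NA_real_ else km_lo$median,
      median_dfs_high = if (is.null(km_hi)) NA_real_ else km_hi$median,
      median_dfs_gap = med_gap,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       auroc = au, cindex = ci, dindex = di, km = km, scores = scores)
}

#' Run the full pipeline end-to-end
#'
#' Trains the pair-rule ensemble on the (possibly dual-platform) training
#' cohort, scores every validation cohort, computes per-cohort AUROC,
#' C-index, D-index, median-split Kaplan-Meier and log-rank statistics,
#' pools each statistic by random-effects meta-analysis with
#' leave-one-out sensitivity, fits and compares the clinicopathologic
#' logistic baseline, optionally runs both permutation tests, and writes
#' all artifacts under \code{out_dir}.  Identical inputs and seed produce
#' byte-identical outputs.
#'
#' @param training list of 1-2 [cohort_profile()]s (same patients when 2).
#' @param validation list of [cohort_profile()]s (>= 1).
#' @param out_dir output directory (created).
#' @param train_config list overriding \code{B}, \code{resample_fraction},
#'   \code{m}, \code{k_grid}, \code{cv_folds}.
#' @param B_perm permutations for the two null tests; 0 skips them.
#' @param seed root seed for every random stage.
#' @return invisibly, a report list with the ensemble, per-cohort
#'   evaluation, meta-estimates, clinical comparison and permutation
#'   results.
#' @export
run_all <- function(training, validation, out_dir,
                    train_config = list(), B_perm = 0, seed = 1) {
  if (inherits(training, "cohort_profile")) training <- list(training)
  stop_if(length(validation) < 1, "need at least one validation cohort")
  tc <- modifyList(list(B = 512, resample_fraction = 0.8, m = 200,
                        k_grid = seq(3, 25, by = 2), cv_folds = 5),
                   train_config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("ktspmeta %s", as.character(utils::packageVersion("ktspmeta"))),
                 sprintf("seed: %d", seed),
                 sprintf("train_config: B=%d m=%d k_grid=%s cv_folds=%d resample_fraction=%g",
                         tc$B, tc$m, paste(tc$k_grid, collapse = ","),
                         tc$cv_folds, tc$resample_fraction))

  stage <- function(what, code) {
    tryCatch(code, error = function(e)
      stop(sprintf("[stage: %s] %s", what, conditionMessage(e)), call. = FALSE))
  }

  ens <- stage("train", train_ensemble(
    training, B = tc$B, resample_fraction = tc$resample_fraction,
    m = tc$m, k_grid = tc$k_grid, cv_folds = tc$cv_folds, seed = seed))
  write_model_json(ens, file.path(out_dir, "model.json"))
  log_lines <- c(log_lines,
                 sprintf("ensemble: %d distinct pairs, %d distinct genes",
                         length(ens$distinct_pairs), length(ens$distinct_genes)))

  ev <- stage("evaluate", evaluate_ensemble(ens, validation))
  utils::write.csv(ev$table, file.path(out_dir, "per_cohort_performance.csv"),
                   row.names = FALSE)

  metas <- list()
  loo <- list()
  for (st in c("auroc", "cindex", "dindex")) {
    ests <- ev[[st]]
    if (length(ests) >= 2) {
      metas[[st]] <- stage(paste0("meta_", st), pool_random_effects(ests))
      utils::write.csv(forest_data(metas[[st]]),
                       file.path(out_dir, paste0("forest_", st, ".csv")),
                       row.names = FALSE)
      if (length(ests) >= 3)
        loo[[st]] <- leave_one_out(ests)
    }
  }

  clinical <- NULL
  clin_train <- training[[1]]$clinical
  clinical_ok <- all(c("age", "figo_stage") %in% names(clin_train)) &&
    sum(stats::complete.cases(clin_train[, c("age", "figo_stage")]) &
          clin_train$label == "high") >= 10 &&
    sum(stats::complete.cases(clin_train[, c("age", "figo_stage")]) &
          clin_train$label == "low") >= 10
  if (clinical_ok) {
    clinical <- stage("clinical", {
      cm <- fit_clinical_model(clin_train)
      ci_cl <- di_cl <- list()
      for (co in validation) {
        pr <- predict_clinical(cm, co$clinical)
        ok <- !is.na(pr)
        if (sum(ok) >= 10 && sum(co$clinical$dfs_event[ok]) >= 2 &&
            length(unique(pr[ok])) > 1) {
          ci_cl[[co$name]] <- concordance_index(pr[ok],
                                                co$clinical$dfs_time_days[ok],
                                                co$clinical$dfs_event[ok],
                                                cohort = co$name)
          di_cl[[co$name]] <- d_index(pr[ok], co$clinical$dfs_time_days[ok],
                                      co$clinical$dfs_event[ok],
                                      cohort = co$name)
        }
      }
      comp <- NULL
      if (length(ci_cl) >= 2 && length(ev$cindex) >= 2) {
        meta_ci_cl <- pool_random_effects(ci_cl)
        comp <- compare_meta(metas$cindex, meta_ci_cl)
        utils::write.csv(
          data.frame(statistic = "cindex",
                     pair_model = metas$cindex$value,
                     clinical_model = meta_ci_cl$value,
                     z = comp$z, p_one_sided = comp$p_one_sided),
          file.path(out_dir, "clinical_comparison.csv"), row.names = FALSE)
      }
      list(model = cm, cindex = ci_cl, dindex = di_cl, comparison = comp)
    })
  }

  perms <- NULL
  if (B_perm > 0) {
    perms <- stage("permutation", list(
      label_shuffle = label_shuffle_test(training, validation, tc,
                                         B_perm = B_perm,
                                         seed = substream(seed, 101)),
      random_genes = random_gene_test(ens, validation, B_perm = B_perm,
                                      seed = substream(seed, 202))))
    utils::write.csv(data.frame(null_meta_auroc = perms$label_shuffle$null_values),
                     file.path(out_dir, "null_label_shuffle.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(null_meta_auroc = perms$random_genes$null_values),
                     file.path(out_dir, "null_random_genes.csv"),
                     row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("label_shuffle p = %.4g; random_genes p = %.4g",
                           perms$label_shuffle$p_value,
                           perms$random_genes$p_value))
  }

  for (st in names(metas))
    log_lines <- c(log_lines,
                   sprintf("meta-%s = %.4f (p = %.3g, tau2 = %.4g)", st,
                           metas[[st]]$value, metas[[st]]$p_value,
                           metas[[st]]$tau2))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(ensemble = ens, evaluation = ev, meta = metas,
                 leave_one_out = loo, clinical = clinical,
                 permutation = perms, config = tc, seed = seed))
}
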