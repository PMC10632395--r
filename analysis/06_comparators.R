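#!/usr/bin/env Rscript

# Stage 6: comparators and auxiliary analyses.
#  - clinicopathologic baseline: logistic model of early relapse on age
#    and ordinal FIGO stage, fitted on the training cohort and compared
#    to the pair-rule ensemble's pooled C-index;
#  - univariable covariate screen;
#  - weighted gene-signature comparator (synthetic demonstration weights
#    on six genes of the simulated universe);
#  - model-size reduction sweep over pair budgets;
#  - hypergeometric gene-set enrichment of the ensemble's signature genes
#    against a synthetic GMT collection built over the gene universe.

suppressPackageStartupMessages(library(ktspmeta))

dat <- "scratch/cohorts"
ens <- read_model_json("results/model.json")
specs <- read.csv(file.path(dat, "truth_cohorts.csv"))
val_names <- setdiff(specs$cohort, c("train_seq", "train_array"))
validation <- lapply(val_names, function(nm) {
  clin <- read.csv(file.path(dat, paste0(nm, "_clinical.csv")), na.strings = "")
  load_cohort(file.path(dat, paste0(nm, "_expression.tsv")),
              file.path(dat, paste0(nm, "_clinical.csv")),
              platform = clin$platform[1])
})
training <- list(
  load_cohort(file.path(dat, "train_seq_expression.tsv"),
              file.path(dat, "train_seq_clinical.csv"), "sequencing"),
  load_cohort(file.path(dat, "train_array_expression.tsv"),
              file.path(dat, "train_array_clinical.csv"), "array"))

# -- clinicopathologic baseline ------------------------------------------
cm <- fit_clinical_model(training[[1]]$clinical)
print(cm)
print(univariable_screen(training[[1]]$clinical))

ev <- evaluate_ensemble(ens, validation)
ci_clin <- list()
for (co in validation) {
  pr <- predict_clinical(cm, co$clinical)
  ok <- !is.na(pr)
  ci_clin[[co$name]] <- concordance_index(pr[ok],
                                          co$clinical$dfs_time_days[ok],
                                          co$clinical$dfs_event[ok], co$name)
}
meta_pairs <- pool_random_effects(ev$cindex)
meta_clin <- pool_random_effects(ci_clin)
cmp <- compare_meta(meta_pairs, meta_clin)
cat(sprintf("\npair-rule meta-C %.3f vs clinical meta-C %.3f: z = %.2f, one-sided p = %.4g\n",
            meta_pairs$value, meta_clin$value, cmp$z, cmp$p_one_sided))
write.csv(data.frame(model = c("pair_rule", "clinical"),
                     meta_cindex = c(meta_pairs$value, meta_clin$value),
                     z = cmp$z, p_one_sided = cmp$p_one_sided),
          "results/clinical_comparison.csv", row.names = FALSE)

# -- weighted-signature comparator (demonstration weights) ---------------
sig_genes <- head(ens$distinct_genes, 6)
weights <- setNames(rep(c(1, -1), 3), sig_genes)
sig_ci <- list()
for (co in validation) {
  sc <- signature_score(co$expression, weights)$scores
  sig_ci[[co$name]] <- concordance_index(sc, co$clinical$dfs_time_days,
                                         co$clinical$dfs_event, co$name)
}
cat(sprintf("signature-score meta-C: %.3f\n",
            pool_random_effects(sig_ci)$value))

# -- reduction sweep over pair budgets -----------------------------------
sw <- reduction_sweep(training, validation, sizes = c(1, 3, 5, 9),
                      train_config = list(B = 10, m = 200), seed = 3)
print(sw)
write.csv(sw, "results/reduction_sweep.csv", row.names = FALSE)
smallest <- sw[sw$within_tolerance, ][1, ]
cat(sprintf("smallest budget within 0.01 AUROC of full: k = %d (%d genes)\n",
            smallest$k_budget, smallest$distinct_genes))

# -- enrichment demo over a synthetic GMT collection ---------------------
universe <- ens$gene_universe
gmt <- "results/demo_sets.gmt"
set.seed(4)
sets <- c(list(planted_rich = unique(c(ens$distinct_genes[1:8],
                                       sample(universe, 12)))),
          lapply(1:5, function(i) sample(universe, 20)))
names(sets)[-1] <- paste0("random_set_", 1:5)
writeLines(vapply(names(sets), function(nm)
  paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), ""), gmt)
enr <- hypergeometric_enrichment(ens$distinct_genes, read_gmt(gmt), universe)
print(enr)
write.csv(enr, "results/enrichment.csv", row.names = FALSE)
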