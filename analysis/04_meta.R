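#!/usr/bin/env Rscript

# Stage 4: pool the per-cohort estimates by DerSimonian-Laird
# random-effects meta-analysis (AUROC and C-index on the raw scale,
# D-index on the log scale), write forest-plot data, and assess
# leave-one-out sensitivity of each pooled statistic.

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
ev <- evaluate_ensemble(ens, validation)

loo_rows <- list()
for (st in c("auroc", "cindex", "dindex")) {
  meta <- pool_random_effects(ev[[st]])
  cat(sprintf("meta-%s: %.4f (95%% CI %.4f-%.4f, p = %.3g, tau2 = %.4g)\n",
              st, meta$value, meta$ci95[1], meta$ci95[2], meta$p_value,
              meta$tau2))
  write.csv(forest_data(meta), sprintf("results/forest_%s.csv", st),
            row.names = FALSE)
  for (nm in names(leave_one_out(ev[[st]]))) {
    m1 <- leave_one_out(ev[[st]])[[nm]]
    loo_rows[[paste(st, nm)]] <- data.frame(
      statistic = st, omitted = nm, pooled = m1$value,
      lo = m1$ci95[1], hi = m1$ci95[2], p = m1$p_value)
  }
}
loo <- do.call(rbind, c(loo_rows, list(make.row.names = FALSE)))
write.csv(loo, "results/leave_one_out.csv", row.names = FALSE)
cat("\nleave-one-out sensitivity written to results/leave_one_out.csv\n")
print(loo)
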