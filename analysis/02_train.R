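#!/usr/bin/env Rscript

# Stage 2: reload the simulated cohorts from disk (exercising the same
# I/O path real data would take) and train the pair-rule ensemble on the
# dual-platform training profiles.  B = 25 members, each a k-TSP model
# fitted to a class-balanced 80% resample of the training instances with
# a 200-gene rank-sum filter and k chosen from {3, 5, 7, 9} by 3-fold
# cross-validated balanced accuracy.

suppressPackageStartupMessages(library(ktspmeta))

dat <- "scratch/cohorts"
dir.create("results", showWarnings = FALSE)

training <- list(
  load_cohort(file.path(dat, "train_seq_expression.tsv"),
              file.path(dat, "train_seq_clinical.csv"), "sequencing"),
  load_cohort(file.path(dat, "train_array_expression.tsv"),
              file.path(dat, "train_array_clinical.csv"), "array"))

ens <- train_ensemble(training, B = 25, m = 200, k_grid = c(3, 5, 7, 9),
                      cv_folds = 3, seed = 2)
write_model_json(ens, "results/model.json")

truth <- read.csv(file.path(dat, "truth_pairs.csv"))
truth_ids <- apply(cbind(truth$gene_i, truth$gene_j), 1,
                   function(r) paste(sort(r), collapse = "|"))

print(ens)
cat(sprintf("planted pairs among selected: %d of %d\n",
            sum(truth_ids %in% ens$distinct_pairs), length(truth_ids)))
cat("model written to results/model.json\n")
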