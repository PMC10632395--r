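#!/usr/bin/env Rscript

# Stage 5: the two permutation null tests.  The label-shuffle test
# permutes training labels at the patient level and retrains the whole
# pipeline per replicate, so it runs here with a reduced training
# configuration (B = 3 members, 50-gene filter, k = 3) and 49
# permutations; the random-gene test keeps the trained ensemble's
# architecture and resamples only the gene identities, which is cheap
# enough for 199 replicates.

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

shuffle <- label_shuffle_test(training, validation,
                              list(B = 3, m = 50, k_grid = 3),
                              B_perm = 49, seed = 51)
randgene <- random_gene_test(ens, validation, B_perm = 199, seed = 52)

write.csv(data.frame(null_meta_auroc = shuffle$null_values),
          "results/null_label_shuffle.csv", row.names = FALSE)
write.csv(data.frame(null_meta_auroc = randgene$null_values),
          "results/null_random_genes.csv", row.names = FALSE)

print(shuffle)
print(randgene)
cat(sprintf("observed meta-AUROC %.3f vs label-shuffle null mean %.3f\n",
            shuffle$observed, mean(shuffle$null_values)))
cat(sprintf("observed meta-AUROC %.3f vs random-gene null mean %.3f\n",
            randgene$observed, mean(randgene$null_values)))
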