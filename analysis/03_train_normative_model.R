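#!/usr/bin/env Rscript
# Stage 3 — fit the normative autoencoder.
#
# Standardizes every feature with the healthy-training-set mean and
# population SD (training subjects only — no leakage), trains the
# 91-46-13-46-91 autoencoder for 1000 epochs, and reports per-subject
# reconstruction error (MSE_s) for every set. Ten-fold cross-validation
# of the training pool (stratified by a simulated site label) reports
# the two model-selection metrics: mean of per-fold median train MSE_s
# and the train-validation gap.
#
# Reads results/features.tsv + results/cohort/manifest.tsv (stages 1-2);
# writes results/mse_s.tsv, results/training_history.tsv,
# results/cv_report.tsv. The cross-validation block retrains the model
# ten times and dominates the runtime (a few minutes).

suppressPackageStartupMessages(library(normfc))

manifest <- read.delim("results/cohort/manifest.tsv")
features <- as.matrix(read.delim("results/features.tsv", row.names = 1))
train <- manifest$group == "H-Train"

std <- fit_standardizer(features[train, ])
z <- apply_standardizer(std, features)
spec <- autoencoder_spec(seed = 2L)
model <- train_autoencoder(spec, z[train, ], standardizer = std)
rec <- reconstruct(model, z)

dir.create("results", showWarnings = FALSE)
write.table(data.frame(subject_id = manifest$subject_id,
                       group = manifest$group, mse_s = rec$mse_s),
            "results/mse_s.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(epoch = seq_along(model$history),
                       loss = model$history),
            "results/training_history.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("final training loss:", round(tail(model$history, 1), 4), "\n")
cat("median MSE_s by group:\n")
print(round(sapply(split(rec$mse_s, manifest$group), median), 4))

# two simulated acquisition sites for the stratification protocol
site <- rep(c("siteA", "siteB"), length.out = sum(train))
cv <- cross_validate(spec, features[train, ], site, fold_count = 10)
write.table(cv$fold, "results/cv_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\ncross-validation: mean train median =",
    round(cv$mean_train_median, 4),
    "; train-validation gap =", round(cv$gap, 4), "\n")
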