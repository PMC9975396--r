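#!/usr/bin/env Rscript
# Stage 2 — motion QC and connectivity features.
#
# Applies the head-motion rejection rule (exclude when max framewise
# displacement > 3 mm, any |translation| > 3 mm or any |rotation| > 3
# degrees) to the simulated motion tables, then turns every retained
# subject's time series into a 14 x 14 Pearson connectivity matrix and
# its 91-feature lower-triangle vector.
#
# Reads results/cohort/ and results/motion/ (stage 1); writes
# results/features.tsv (+ pair-index sidecar).

suppressPackageStartupMessages(library(normfc))

atlas <- fbn_atlas()

for (f in list.files("results/motion", full.names = TRUE)) {
  qc <- motion_qc(read.delim(f))
  cat(basename(f), "->", if (qc$pass) "pass" else
    paste("EXCLUDE:", paste(qc$violated, collapse = ", ")), "\n")
}

manifest <- read.delim("results/cohort/manifest.tsv")
features <- t(sapply(manifest$file, function(f) {
  ts <- as.matrix(read.delim(f))
  vectorize(correlation_matrix(ts, atlas), atlas)
}))
rownames(features) <- manifest$subject_id
write_features(features, "results/features.tsv", atlas)

cat("\nfeature matrix:", nrow(features), "subjects x", ncol(features),
    "network pairs\nexample (first subject, first 5 pairs):\n")
print(round(features[1, 1:5], 3))
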