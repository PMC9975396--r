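#!/usr/bin/env Rscript
# Stage 5 — generalization to an independent cohort.
#
# Trains the normative model on cohort 1 (default conditions), then
# scores a second, independently simulated cohort (new healthy and
# schizophrenia-like groups, same injected pairs) with the stored model,
# standardizer and binarization threshold. Compares the two patient
# groups' nine worst-reconstructed pairs — the analogue of testing a
# trained model on a second public dataset.
#
# Writes results/generalization/ edge lists for both cohorts.

suppressPackageStartupMessages(library(normfc))

cfg <- run_config(seed = 1L, condition_b = FALSE)
rep <- run_pipeline(cfg)

gen <- independent_cohort_overlap(rep, cfg, "SCZ-Test-U",
                                  seed = 500001L)

dir.create("results/generalization", recursive = TRUE,
           showWarnings = FALSE)
write_edge_list(rep$top_pairs_before[["SCZ-Test-U"]],
                "results/generalization/top_pairs_cohort1.tsv")
write_edge_list(gen$top_independent,
                "results/generalization/top_pairs_cohort2.tsv")

cat("cohort 1 top-9 pairs:",
    paste(rep$top_pairs_before[["SCZ-Test-U"]]$pair, collapse = ", "),
    "\n")
cat("cohort 2 top-9 pairs:",
    paste(gen$top_independent$pair, collapse = ", "), "\n")
cat("shared:", gen$shared, "of", gen$n_top, "\n")
cat("\nmedian MSE_s, independent cohort:\n")
print(round(sapply(gen$scored$mse_by_group, median), 4))
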