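#!/usr/bin/env Rscript
# Stage 2 — clean the raw cohort.
#
# Recode questionnaire special codes, drop rows with more than 20% missing
# cells, impute the rest (mode / mean / least-frequent-binary), z-score the
# design, remove structural outliers flagged beyond the 95th percentile of
# per-cluster centroid distance in a 2-D embedding, and balance the healthy
# group down to the case count.

source("analysis/00_config.R")
cfg <- analysis_config()

mani <- run_pipeline(cfg, stages = "preprocess")

counts <- mani$stages$preprocess$rows
cat("Rows in:", counts[["input"]],
    "| after cleaning:", counts[["after_clean"]],
    "| after outlier removal:", counts[["after_outliers"]],
    "| balanced:", counts[["balanced"]], "\n")
rep_ <- jsonlite::read_json(file.path(cfg$out_dir, "outlier_report.json"))
cat("Embedding clusters selected: k =", rep_$k_selected,
    "| rows flagged:", length(rep_$flagged_rows), "\n")
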