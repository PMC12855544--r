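# Shared configuration for the numbered analysis scripts.  Each script runs
# one pipeline stage against the same run directory, so any stage can be
# re-run from its predecessor's files.
library(behavnet)

analysis_config <- function() {
  pipeline_config(
    out_dir = "results/study",
    n_per_group = 1500,       # analytic scale: two matched groups of 1,500
    seed = 20260927L,
    missing_row_fraction = 0.08,
    missing_cell_rate = 0.02,
    outlier_fraction = 0.03,
    embedding = "tsne",       # 2-D embedding for the outlier stage
    tsne_iter = 1000,
    ann_runs = 2, ann_folds = 3,
    ann_epochs = 60, ann_patience = 10)
}
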