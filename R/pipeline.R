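#' Pipeline configuration
#'
#' One JSON-serializable document holding every stage parameter of the
#' simulate -> preprocess -> survival -> influence -> network pipeline.
#' Unknown keys are rejected.
#'
#' @param out_dir Run directory for all stage artifacts.
#' @param n_per_group Participants per cohort in the simulated study.
#' @param seed Master seed; per-stage seeds derive from it.
#' @param missing_row_fraction,missing_cell_rate,outlier_fraction Generator
#'   injection rates.
#' @param embedding `"tsne"` or `"pca"` for the outlier stage.
#' @param perplexity,tsne_iter Embedding parameters.
#' @param l2 Ridge penalty for the multivariate Cox fit.
#' @param cv_folds Folds for the C-index cross-validation.
#' @param ann_runs,ann_folds Influence-ensemble design.
#' @param ann_epochs,ann_patience Training length and early-stopping patience
#'   for each ensemble member.
#' @param influence_variables Schema variables included in the influence
#'   stage (default: all 18; smaller sets speed up demo runs).
#' @param edge_threshold Minimum median influence for a network edge.
#' @param role_alpha Significance level for role classification.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            n_per_group = 600,
                            seed = 1L,
                            missing_row_fraction = 0.05,
                            missing_cell_rate = 0.02,
                            outlier_fraction = 0.02,
                            embedding = "pca",
                            perplexity = 40,
                            tsne_iter = 1000,
                            l2 = 0.01,
                            cv_folds = 10,
                            ann_runs = 2,
                            ann_folds = 3,
                            ann_epochs = 60,
                            ann_patience = 10,
                            influence_variables = names(default_schema()),
                            edge_threshold = 0,
                            role_alpha = 0.05) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param cfg A `pipeline_config`.
#' @param path JSON path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the config (unknown keys error).
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Map Cox design terms to influence-network nodes
#'
#' Terms matching a node name map to themselves; dummy terms whose parent
#' variable is a node (e.g. smoking-status levels, top-band meat terms) map
#' to the parent.
#'
#' @param terms Character vector of hazard-term names.
#' @param nodes Character vector of network node names.
#' @return Named character vector term -> node (unmappable terms dropped).
#' @export
default_node_map <- function(terms, nodes) {
  map <- vapply(terms, function(tm) {
    if (tm %in% nodes) return(tm)
    parent <- sub("\\.[^.]+$", "", tm)
    if (parent %in% nodes) return(parent)
    NA_character_
  }, character(1))
  map[!is.na(map)]
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess -> survival -> influence -> network,
#' writing each stage's artifacts under `cfg$out_dir` and a `manifest.json`
#' recording the config checksum, per-stage row counts, seeds and artifact
#' checksums.  Stages communicate only through files, so any suffix of the
#' stage list can be re-run against existing artifacts.
#'
#' @param cfg A [pipeline_config()].
#' @param stages Which stages to run (default: all, in order).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "preprocess",
                                         "survival", "influence",
                                         "network")) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(cfg$out_dir, ...)
  schema <- default_schema()
  manifest <- list(stages = list(), seed = cfg$seed)
  write_pipeline_config(cfg, pth("config.json"))
  manifest$config_md5 <- unname(tools::md5sum(pth("config.json")))
  ok <- function(stage, files, counts) {
    manifest$stages[[stage]] <<- list(
      rows = counts, files = as.list(tools::md5sum(pth(files))))
    manifest$last_good_stage <<- stage
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }

  if ("simulate" %in% stages) {
    gcfg <- generator_config(
      n_per_group = cfg$n_per_group,
      missing_row_fraction = cfg$missing_row_fraction,
      missing_cell_rate = cfg$missing_cell_rate,
      outlier_fraction = cfg$outlier_fraction,
      seed = cfg$seed)
    cohort <- simulate_cohort(gcfg, schema)
    cohort <- inject_missingness(cohort, gcfg, schema)
    inj <- inject_outliers(cohort, gcfg, schema)
    write_cohort_csv(inj$cohort, pth("raw_cohort.csv"), schema)
    writeLines(as.character(inj$outlier_rows), pth("true_outlier_rows.txt"))
    ok("simulate", c("raw_cohort.csv", "true_outlier_rows.txt"),
       c(raw = nrow(inj$cohort)))
  }

  if ("preprocess" %in% stages) {
    raw <- read_cohort_csv(pth("raw_cohort.csv"))
    cl <- clean_cohort(raw, schema)
    Z <- standardize(cl$table, schema)
    rep_ <- detect_outliers(Z, perplexity = cfg$perplexity,
                            n_iter = cfg$tsne_iter, seed = cfg$seed + 1L,
                            method = cfg$embedding)
    write_outlier_report(rep_, pth("outlier_report.json"))
    kept <- cl$table[setdiff(seq_len(nrow(cl$table)), rep_$flagged_rows), ]
    groups <- split(kept, kept$cohort_label)
    if (nrow(groups$healthy) >= nrow(groups$t2dm)) {
      bal <- balance_downsample(groups$healthy, groups$t2dm,
                                seed = cfg$seed + 2L)
    } else {
      bal <- list(healthy = groups$healthy,
                  t2dm = groups$t2dm[sort(sample.int(nrow(groups$t2dm),
                                                     nrow(groups$healthy))), ])
    }
    clean <- rbind(bal$healthy, bal$t2dm)
    write_cohort_csv(clean, pth("clean_cohort.csv"), schema)
    ok("preprocess", c("clean_cohort.csv", "outlier_report.json"),
       c(input = nrow(raw), after_clean = nrow(cl$table),
         after_outliers = nrow(kept), balanced = nrow(clean)))
  }

  if ("survival" %in% stages) {
    clean <- read_cohort_csv(pth("clean_cohort.csv"))
    X <- cox_design_matrix(clean, schema)
    time <- clean$follow_up_years; event <- clean$event
    uni <- univariate_screen(X, time, event)
    cand <- uni$term[uni$retained]
    cand <- low_variance_filter(X[, cand, drop = FALSE], event)
    cand <- vif_filter(X[, cand, drop = FALSE])
    fit <- fit_multivariate_cox(X[, cand, drop = FALSE], time, event,
                                l2 = cfg$l2)
    ph <- test_proportional_hazards(fit)
    fit <- ph$fit
    cv <- cross_validate_cindex(fit$X, time, event, folds = cfg$cv_folds,
                                l2 = cfg$l2, seed = cfg$seed + 3L)
    ht <- hazard_table(fit)
    utils::write.csv(ht, pth("hazard_table.csv"), row.names = FALSE)
    betas <- stats::setNames(
      fit$terms$beta[!grepl(":time$", fit$terms$name)],
      fit$terms$name[!grepl(":time$", fit$terms$name)])
    scores <- risk_score(betas, clean, schema)
    strat <- derive_strata(scores, event, seed = cfg$seed + 4L)
    labels <- assign_stratum(scores, strat)
    km <- km_validation(time, event, labels, label_order = strat$labels)
    jsonlite::write_json(
      list(cutpoints = strat$cutpoints, labels = strat$labels,
           cindex_cv = list(mean = cv$mean, sd = cv$sd)),
      pth("strata.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(km$curves, pth("km_curves.csv"), row.names = FALSE)
    utils::write.csv(km$pairwise_tests, pth("km_logrank.csv"),
                     row.names = FALSE)
    utils::write.csv(km$percentiles, pth("km_percentiles.csv"),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(participant_id = clean$participant_id, score = scores,
                 stratum = labels),
      pth("risk_scores.csv"), row.names = FALSE)
    ok("survival",
       c("hazard_table.csv", "strata.json", "km_curves.csv",
         "km_logrank.csv", "km_percentiles.csv", "risk_scores.csv"),
       c(rows = nrow(clean), terms = nrow(fit$terms)))
  }

  if ("influence" %in% stages) {
    clean <- read_cohort_csv(pth("clean_cohort.csv"))
    arch <- network_architecture(epochs = cfg$ann_epochs,
                                 patience = cfg$ann_patience)
    mats <- lapply(c(healthy = "healthy", t2dm = "t2dm"), function(lab) {
      sub <- clean[clean$cohort_label == lab, , drop = FALSE]
      m <- build_influence_matrix(sub, schema, arch,
                                  runs = cfg$ann_runs, folds = cfg$ann_folds,
                                  seed = cfg$seed + 5L,
                                  variables = cfg$influence_variables)
      m$cohort_label <- lab
      utils::write.csv(influence_long(m),
                       pth(paste0("influence_", lab, ".csv")),
                       row.names = FALSE)
      m
    })
    dm <- difference_matrix(mats$t2dm, mats$healthy)
    idx <- which(!is.na(dm$difference), arr.ind = TRUE)
    utils::write.csv(
      data.frame(input = rownames(dm$difference)[idx[, 1]],
                 target = colnames(dm$difference)[idx[, 2]],
                 difference = dm$difference[idx],
                 absolute = dm$absolute[idx],
                 sign_reversal = dm$sign_reversal[idx]),
      pth("influence_difference.csv"), row.names = FALSE)
    ok("influence",
       c("influence_healthy.csv", "influence_t2dm.csv",
         "influence_difference.csv"),
       c(nodes = length(mats$healthy$nodes)))
  }

  if ("network" %in% stages) {
    mats <- lapply(c(healthy = "healthy", t2dm = "t2dm"), function(lab) {
      long <- utils::read.csv(pth(paste0("influence_", lab, ".csv")),
                              stringsAsFactors = FALSE)
      nodes <- sort(unique(c(long$input, long$target)))
      med <- matrix(NA_real_, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
      med[cbind(match(long$input, nodes), match(long$target, nodes))] <-
        long$median
      influence_matrix_from_values(med, cohort_label = lab)
    })
    profs <- lapply(mats, function(m) {
      g <- build_network(m, threshold = cfg$edge_threshold)
      centrality_profile(g)
    })
    deltas <- centrality_deltas(profs$healthy, profs$t2dm)
    shift <- vector_shift(profs$healthy, profs$t2dm)
    ht <- utils::read.csv(pth("hazard_table.csv"), stringsAsFactors = FALSE)
    ht <- ht[!grepl(":time$", ht$name), ]
    node_map <- default_node_map(ht$name, deltas$node)
    roles <- classify_roles(deltas, ht[ht$name %in% names(node_map), ],
                            node_map = node_map, alpha = cfg$role_alpha)
    utils::write.csv(deltas, pth("centrality_deltas.csv"), row.names = FALSE)
    utils::write.csv(shift, pth("vector_shift.csv"), row.names = FALSE)
    utils::write.csv(roles, pth("roles.csv"), row.names = FALSE)
    ok("network", c("centrality_deltas.csv", "vector_shift.csv", "roles.csv"),
       c(nodes = nrow(deltas)))
  }

  invisible(manifest)
}

#' Render a plain-markdown summary of a pipeline run
#'
#' Assembles the stage artifacts in `run_dir` into a single report;
#' missing artifacts produce a notice instead of an error.  Regeneration is
#' byte-identical for identical inputs.
#'
#' @param run_dir A completed (or partial) pipeline run directory.
#' @param path Output markdown path (default `report.md` in `run_dir`).
#' @return `path`, invisibly.
#' @export
render_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  sec <- function(title, file, fmt) {
    f <- file.path(run_dir, file)
    if (!file.exists(f))
      return(c(paste("##", title), "", paste0("*missing artifact: ", file,
                                              "*"), ""))
    c(paste("##", title), "", fmt(f), "")
  }
  as_md_table <- function(f, n = 15) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    df <- utils::head(df, n)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    header <- paste("|", paste(names(df), collapse = " | "), "|")
    rule <- paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|")
    rows <- apply(df, 1, function(r) paste("|", paste(r, collapse = " | "),
                                           "|"))
    c(header, rule, rows)
  }
  lines <- c("# Behavioral T2DM risk pipeline report", "",
             sec("Hazard table", "hazard_table.csv", as_md_table),
             sec("Risk strata", "strata.json",
                 function(f) paste0("```json\n",
                                    paste(readLines(f), collapse = "\n"),
                                    "\n```")),
             sec("Survival percentiles by stratum", "km_percentiles.csv",
                 as_md_table),
             sec("Pairwise log-rank tests", "km_logrank.csv", as_md_table),
             sec("Influence difference (largest shifts)",
                 "influence_difference.csv",
                 function(f) {
                   df <- utils::read.csv(f, stringsAsFactors = FALSE)
                   df <- df[order(-df$absolute), ][1:min(15, nrow(df)), ]
                   tf <- tempfile(fileext = ".csv")
                   utils::write.csv(df, tf, row.names = FALSE)
                   as_md_table(tf)
                 }),
             sec("Centrality shifts", "centrality_deltas.csv", as_md_table),
             sec("Intervention roles", "roles.csv", as_md_table))
  writeLines(lines, path)
  invisible(path)
}
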