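#' Recode questionnaire special codes
#'
#' "Don't know" / "prefer not to answer" style codes become missing (`NA`);
#' order-breaking negative codes (e.g. -7 for "none of the above") are
#' re-mapped to the schema-consistent level given in `special_code_map`.
#'
#' @param tab Cohort or covariate data frame.
#' @param schema List of [variable_spec()] objects.
#' @param special_code_map Named list: code (as character, e.g. `"-7"`) to
#'   replacement level label, or `NA` to treat the code as missing.
#' @param na_codes Codes always treated as missing.
#' @return List with `table` (recoded) and `n_recoded` (cells changed).
#' @export
recode_special_values <- function(tab, schema,
                                  special_code_map = list("-7" = "never"),
                                  na_codes = c("-1", "-3")) {
  stopifnot_schema(schema)
  n_changed <- 0L
  for (sp in schema) {
    if (sp$scale == "continuous") next
    v <- as.character(tab[[sp$name]])
    for (code in names(special_code_map)) {
      repl <- special_code_map[[code]]
      # a mapped level that does not exist on this column (e.g. "none of
      # the above" on a binary flag) degrades to missing
      if (!is.na(repl) && !repl %in% sp$levels) repl <- NA_character_
      hit <- which(!is.na(v) & v == code)
      if (length(hit) > 0) {
        v[hit] <- repl
        n_changed <- n_changed + length(hit)
      }
    }
    for (code in na_codes) {
      hit <- which(!is.na(v) & v == code)
      if (length(hit) > 0) {
        v[hit] <- NA_character_
        n_changed <- n_changed + length(hit)
      }
    }
    bad <- which(!is.na(v) & !v %in% sp$levels)
    if (length(bad) > 0)
      stop("column '", sp$name, "' contains unmapped codes: ",
           paste(unique(v[bad]), collapse = ", "))
    tab[[sp$name]] <- v
  }
  list(table = tab, n_recoded = n_changed)
}

#' Drop rows with excessive missingness
#'
#' A row is removed when its share of missing cells, computed over the
#' schema columns only (ids and outcome columns do not count), is strictly
#' greater than `threshold`.
#'
#' @param tab Cohort data frame.
#' @param schema List of [variable_spec()] objects.
#' @param threshold Missing-share cutoff in (0, 1); default 0.20.
#' @return List with `table` (kept rows) and `n_removed`.
#' @export
filter_missing_rows <- function(tab, schema, threshold = 0.20) {
  stopifnot_schema(schema)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  vars <- names(schema)
  miss_share <- rowMeans(is.na(tab[, vars, drop = FALSE]))
  keep <- miss_share <= threshold
  list(table = tab[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Single-value imputation by variable type
#'
#' Categorical (ordinal / nominal) columns are imputed with the observed
#' mode, continuous columns with the mean, and binary columns with the least
#' frequent observed category (ties impute "0").  Never invents unseen
#' levels.
#'
#' @param tab Cohort data frame.
#' @param schema List of [variable_spec()] objects.
#' @return The completed data frame.
#' @export
impute <- function(tab, schema) {
  stopifnot_schema(schema)
  for (sp in schema) {
    v <- tab[[sp$name]]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss)) stop("column '", sp$name, "' is entirely missing")
    if (sp$scale == "continuous") {
      v[miss] <- mean(as.numeric(v), na.rm = TRUE)
    } else if (sp$scale == "binary") {
      tb <- table(factor(v[!miss], levels = sp$levels))
      least <- if (tb[["1"]] < tb[["0"]]) "1" else "0"   # tie -> "0"
      v[miss] <- least
    } else {
      tb <- table(v[!miss])
      v[miss] <- names(tb)[which.max(tb)]
    }
    tab[[sp$name]] <- v
  }
  tab
}

#' Column-standardize the Cox design of a cohort
#'
#' Encodes the covariates per their Cox encodings and z-scores every column
#' (mean 0, SD 1).  Zero-variance columns are passed through as zeros.
#'
#' @param tab Complete cohort data frame.
#' @param schema List of [variable_spec()] objects.
#' @return Numeric matrix with attributes `center` and `scale` so the
#'   transform can be inverted.
#' @export
standardize <- function(tab, schema) {
  X <- cox_design_matrix(tab, schema)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv_safe <- ifelse(sdv < 1e-12, 1, sdv)
  Z <- sweep(sweep(X, 2, mu), 2, sdv_safe, "/")
  Z[, sdv < 1e-12] <- 0
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sdv
  Z
}

#' Balance cohorts by down-sampling the larger (healthy) group
#'
#' Random sampling without replacement, unconditional on covariates, so the
#' healthy group matches the T2DM group size.
#'
#' @param healthy,t2dm Cohort data frames; `nrow(healthy) >= nrow(t2dm)`.
#' @param seed Integer seed.
#' @return List with `healthy` (subsampled) and `t2dm` (unchanged).
#' @export
balance_downsample <- function(healthy, t2dm, seed = 1L) {
  if (nrow(healthy) < nrow(t2dm))
    stop("healthy group is smaller than t2dm group; ",
         "balancing down-samples the healthy group only")
  if (nrow(healthy) > nrow(t2dm)) {
    set.seed(as.integer(seed))
    keep <- sort(sample.int(nrow(healthy), nrow(t2dm)))
    healthy <- healthy[keep, , drop = FALSE]
  }
  list(healthy = healthy, t2dm = t2dm)
}

#' Run the full cleaning chain on a raw cohort
#'
#' recode special codes -> row-missingness filter -> typed imputation,
#' returning the cleaned table plus stage row counts for audit.
#'
#' @param tab Raw cohort data frame.
#' @param schema List of [variable_spec()] objects.
#' @param special_code_map See [recode_special_values()].
#' @param threshold See [filter_missing_rows()].
#' @return List with `table`, `n_recoded`, `n_removed`, `counts` (per-stage
#'   row counts).
#' @export
clean_cohort <- function(tab, schema,
                         special_code_map = list("-7" = "never"),
                         threshold = 0.20) {
  n0 <- nrow(tab)
  rc <- recode_special_values(tab, schema, special_code_map)
  fl <- filter_missing_rows(rc$table, schema, threshold)
  out <- impute(fl$table, schema)
  list(table = out, n_recoded = rc$n_recoded, n_removed = fl$n_removed,
       counts = c(input = n0, after_filter = nrow(fl$table),
                  after_impute = nrow(out)))
}
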