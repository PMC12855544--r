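#' Generator configuration for synthetic survival cohorts
#'
#' Bundles everything the synthetic-cohort generator needs: the per-term
#' log-hazard coefficients, the Weibull baseline hazard, censoring and
#' follow-up settings, missingness and outlier injection rates, and the seed.
#'
#' Event times follow a proportional-hazards model
#' \eqn{h(t \mid x) = h_0(t)\exp(\sum_j \beta_j x_j)} with a Weibull baseline
#' \eqn{h_0(t) = (a/b)(t/b)^{a-1}} (shape \eqn{a}, scale \eqn{b}), sampled by
#' inverse transform.  The default shape 1.2 gives a gently rising hazard;
#' the default scale is calibrated so that roughly half of the high-risk tail
#' (90th percentile of the linear predictor under the default schema and
#' coefficients) has experienced the event by the 17-year administrative
#' cutoff.
#'
#' @param n_per_group Target number of participants per cohort
#'   (healthy / t2dm).
#' @param betas Named numeric vector mapping Cox design terms (see
#'   [cox_term_names()]) to log-hazard coefficients.
#' @param baseline List with Weibull `shape` and `scale` (both > 0).
#' @param max_follow Administrative censoring horizon in years.
#' @param censoring `"uniform"` (default) adds an independent
#'   Uniform(1, max_follow) censoring time so censored follow-up varies over
#'   the full 1--17 year range; `"administrative"` censors only at
#'   `max_follow`.
#' @param missing_row_fraction Fraction of rows given heavy (>20%% of cells)
#'   missingness, to exercise the row filter.
#' @param missing_cell_rate Sparse cell-level missingness rate for the
#'   remaining rows.
#' @param special_code_map Named list mapping integer special codes to level
#'   labels (e.g. `list("-7" = "never")`): a share of categorical missing
#'   cells is written as the code instead of `NA`.
#' @param outlier_fraction Fraction of rows turned into ground-truth
#'   multivariate outliers.
#' @param outlier_scale Shift applied to continuous fields of outlier rows,
#'   in standard deviations.
#' @param seed Integer seed; identical configs produce identical cohorts.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 1000,
                             betas = default_betas(),
                             baseline = list(shape = 1.2, scale = 280),
                             max_follow = 17,
                             censoring = c("uniform", "administrative"),
                             missing_row_fraction = 0,
                             missing_cell_rate = 0,
                             special_code_map = list("-7" = "never"),
                             outlier_fraction = 0,
                             outlier_scale = 8,
                             seed = 1L) {
  censoring <- match.arg(censoring)
  props <- c(missing_row_fraction, missing_cell_rate, outlier_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  if (baseline$shape <= 0 || baseline$scale <= 0)
    stop("baseline shape and scale must be positive")
  structure(
    list(n_per_group = n_per_group, betas = betas, baseline = baseline,
         max_follow = max_follow, censoring = censoring,
         missing_row_fraction = missing_row_fraction,
         missing_cell_rate = missing_cell_rate,
         special_code_map = special_code_map,
         outlier_fraction = outlier_fraction, outlier_scale = outlier_scale,
         seed = as.integer(seed)),
    class = "generator_config")
}

#' Default generator coefficients
#'
#' Log-hazard coefficients for the default schema, echoing the direction and
#' magnitude of the behavioral effects the package models: psychosocial
#' strain, short or irregular sleep and smoking raise the hazard, 7-8 h
#' sleep and high-fiber cereals lower it, refined bread and high meat
#' frequencies raise it, and risk rises with age and BMI.
#'
#' @return Named numeric vector of coefficients on Cox design terms.
#' @export
default_betas <- function() {
  c(loneliness_isolation = 0.13,
    seen_psychiatrist = 0.16,
    sleeplessness_insomnia = 0.06,
    fed_up_feelings = 0.08,
    tense_highly_strung = 0.15,
    sleep_duration_7_8h = -0.13,
    nap_during_day = 0.09,
    difficulty_getting_up = 0.04,
    plays_computer_games = 0.04,
    current_tobacco_smoking = 0.29,
    smoking_status.previous = 0.12,
    smoking_status.current = 0.17,
    salt_added_to_food = 0.04,
    bread_type.brown = 0.16,
    bread_type.white = 0.26,
    bread_type.other = 0.11,
    cereal_type.biscuit = 0.10,
    cereal_type.oat = -0.23,
    cereal_type.muesli = -0.55,
    cereal_type.sugary = 0.10,
    processed_meat.five_to_six_week = 0.17,
    beef_intake.five_to_six_week = 0.16,
    age = 0.02,
    bmi = 0.03)
}

#' Draw covariates from a schema
#'
#' Marginal distributions follow each variable's `gen_params` (level
#' probabilities for categorical scales, uniform over the range for
#' continuous).  By default the joint distribution carries a latent
#' two-factor Gaussian-copula dependence — one psychosocial/sleep factor and
#' one dietary/demographic factor — so that behavioral profiles cohere the
#' way questionnaire data do, while every marginal stays exactly as
#' specified.  `correlation = "independent"` draws every variable
#' independently.
#'
#' @param schema List of [variable_spec()] objects.
#' @param n Number of rows (> 0).
#' @param seed Integer seed.
#' @param correlation `"factor"` (default) or `"independent"`.
#' @param loading Factor loading on the latent normals in (0, 1); the
#'   implied within-factor latent correlation is `loading^2`.
#' @return Data frame with one column per variable; categorical columns are
#'   character, continuous numeric.
#' @export
simulate_covariates <- function(schema, n, seed = 1L,
                                correlation = c("factor", "independent"),
                                loading = 0.7) {
  stopifnot_schema(schema)
  correlation <- match.arg(correlation)
  if (n <= 0) stop("n must be positive")
  set.seed(as.integer(seed))
  p <- length(schema)
  if (correlation == "factor") {
    themes <- default_theme_map()
    fac <- ifelse(themes[names(schema)] %in% c("psychological", "sleep"),
                  1L, 2L)
    fac[is.na(fac)] <- 2L
    F <- matrix(stats::rnorm(n * 2), n, 2)
    U <- vapply(seq_len(p), function(j) {
      z <- loading * F[, fac[j]] + sqrt(1 - loading^2) * stats::rnorm(n)
      stats::pnorm(z)
    }, numeric(n))
  } else {
    U <- matrix(stats::runif(n * p), n, p)
  }
  out <- lapply(seq_len(p), function(j) {
    sp <- schema[[j]]
    if (sp$scale == "continuous") {
      sp$gen_params[1] + U[, j] * diff(sp$gen_params)
    } else {
      br <- c(0, cumsum(sp$gen_params))
      br[length(br)] <- 1
      sp$levels[findInterval(U[, j], br, rightmost.closed = TRUE,
                             all.inside = TRUE)]
    }
  })
  names(out) <- names(schema)
  as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
}

#' Simulate proportional-hazards survival times for a covariate table
#'
#' Event times are drawn by inverse transform from the Weibull-baseline
#' proportional-hazards survival function
#' \eqn{S(t \mid x) = \exp\{-(t/b)^a e^{\beta'x}\}}, i.e.
#' \eqn{T = b\,(-\log U / e^{\beta'x})^{1/a}}.  Follow-up is the minimum of
#' the event time, the administrative cutoff and (optionally) an independent
#' uniform censoring time; the event indicator is 1 iff the event time is
#' smallest.  Times below 1 year are resampled so the generated range
#' matches the 1--17 year follow-up window the pipeline assumes
#' (conditioning on \eqn{T \ge 1} leaves the hazard beyond year 1, and hence
#' Cox estimation, unchanged).
#'
#' @param covariates Data frame from [simulate_covariates()].
#' @param config A [generator_config()]. Every name in `config$betas` must
#'   resolve against the Cox design of `covariates`.
#' @param schema Schema used to encode `covariates`.
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return A `cohort` data frame: `participant_id`, the covariates,
#'   `event`, `follow_up_years` and `cohort_label`
#'   (`"t2dm"` for event rows, `"healthy"` for censored rows).
#' @export
simulate_survival <- function(covariates, config, schema = default_schema(),
                              seed = config$seed) {
  X <- cox_design_matrix(covariates, schema)
  unknown <- setdiff(names(config$betas), colnames(X))
  if (length(unknown) > 0)
    stop("betas reference unknown design terms: ",
         paste(unknown, collapse = ", "))
  lp <- as.numeric(X[, names(config$betas), drop = FALSE] %*% config$betas)
  n <- nrow(covariates)
  # decouple the event-time stream from the covariate stream so passing the
  # same seed to both stages cannot correlate times with covariates
  set.seed(scramble_seed(seed))
  a <- config$baseline$shape; b <- config$baseline$scale
  draw <- function(m, lp_m) b * (-log(stats::runif(m)) / exp(lp_m))^(1 / a)
  t_event <- draw(n, lp)
  # resample sub-year event times (equivalent to conditioning on T >= 1)
  for (iter in 1:1000) {
    idx <- which(t_event < 1)
    if (length(idx) == 0) break
    t_event[idx] <- draw(length(idx), lp[idx])
  }
  t_event[t_event < 1] <- 1
  t_cens <- rep(config$max_follow, n)
  if (config$censoring == "uniform")
    t_cens <- pmin(t_cens, stats::runif(n, 1, config$max_follow))
  event <- as.integer(t_event <= t_cens)
  follow <- pmin(t_event, t_cens)
  out <- cbind(
    data.frame(participant_id = seq_len(n)),
    covariates,
    data.frame(event = event, follow_up_years = follow,
               cohort_label = ifelse(event == 1, "t2dm", "healthy"),
               stringsAsFactors = FALSE))
  class(out) <- c("cohort", class(out))
  out
}

#' Simulate a two-cohort study population
#'
#' Draws covariates and survival outcomes until the requested number of
#' event (t2dm) and censored (healthy) participants is reached, mirroring a
#' cohort in which incident cases and disease-free participants are analyzed
#' as two equal groups.
#'
#' @param config A [generator_config()].
#' @param schema Schema (defaults to [default_schema()]).
#' @return A `cohort` data frame with `config$n_per_group` rows per label.
#' @export
simulate_cohort <- function(config, schema = default_schema()) {
  n_goal <- config$n_per_group
  got <- list(healthy = NULL, t2dm = NULL)
  batch_seed <- config$seed
  rate <- 0.12                       # running estimate of the rarer group's share
  for (round in 1:20) {
    need <- max(n_goal - ifelse(is.null(got$healthy), 0, nrow(got$healthy)),
                n_goal - ifelse(is.null(got$t2dm), 0, nrow(got$t2dm)))
    if (need <= 0) break
    m <- max(ceiling(1.2 * need / rate), 200L)
    cov <- simulate_covariates(schema, m, seed = batch_seed)
    ch <- simulate_survival(cov, config, schema, seed = batch_seed + 1L)
    for (lab in c("healthy", "t2dm")) {
      take <- ch[ch$cohort_label == lab, , drop = FALSE]
      got[[lab]] <- rbind(got[[lab]], take)
    }
    rate <- max(min(mean(ch$event), 1 - mean(ch$event)), 0.01)
    batch_seed <- batch_seed + 101L
  }
  if (nrow(got$healthy) < n_goal || nrow(got$t2dm) < n_goal)
    stop("could not reach n_per_group; adjust baseline scale or follow-up")
  out <- rbind(utils::head(got$healthy, n_goal), utils::head(got$t2dm, n_goal))
  out$participant_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("cohort", class(out))
  out
}

#' Inject missing cells and special codes into a cohort
#'
#' A designated fraction of rows receives heavy missingness (a random >20%
#' subset of schema columns blanked) so the downstream row filter has work
#' to do; the remaining rows receive sparse cell-level missingness.  Part of
#' the categorical missing cells are written as integer special codes (e.g.
#' -7 for "none of the above") instead of `NA`, as questionnaire exports do.
#'
#' @param cohort A `cohort` data frame.
#' @param config A [generator_config()]; uses `missing_row_fraction`,
#'   `missing_cell_rate`, `special_code_map`, `seed`.
#' @param schema Schema describing the covariate columns.
#' @param special_code_share Share of categorical missing cells written as a
#'   special code rather than `NA`.
#' @return The cohort with missing cells injected.
#' @export
inject_missingness <- function(cohort, config, schema = default_schema(),
                               special_code_share = 0.15) {
  set.seed(config$seed + 7L)
  vars <- names(schema)
  n <- nrow(cohort); p <- length(vars)
  n_heavy <- round(config$missing_row_fraction * n)
  heavy_rows <- if (n_heavy > 0) sample.int(n, n_heavy) else integer()
  # heavy rows: blank strictly more than 20% of schema columns
  k_heavy <- max(ceiling(0.2 * p) + 1L, 2L)
  for (i in heavy_rows) {
    cols <- sample(vars, k_heavy)
    for (v in cols) cohort[[v]][i] <- NA
  }
  if (config$missing_cell_rate > 0) {
    light_rows <- setdiff(seq_len(n), heavy_rows)
    for (v in vars) {
      hit <- light_rows[stats::runif(length(light_rows)) < config$missing_cell_rate]
      cohort[[v]][hit] <- NA
    }
  }
  # rewrite a share of categorical missing cells as special codes
  codes <- names(config$special_code_map)
  if (length(codes) > 0 && special_code_share > 0) {
    cat_vars <- vars[vapply(schema, function(sp) sp$scale != "continuous", TRUE)]
    for (v in cat_vars) {
      miss <- which(is.na(cohort[[v]]))
      hit <- miss[stats::runif(length(miss)) < special_code_share]
      if (length(hit) > 0)
        cohort[[v]][hit] <- sample(codes, length(hit), replace = TRUE)
    }
  }
  cohort
}

#' Inject ground-truth multivariate outliers
#'
#' Selected rows become structurally inconsistent profiles: every continuous
#' field is shifted by `outlier_scale` population standard deviations in a
#' random per-row, per-field direction (with a random 50-150% magnitude
#' jitter), and categorical fields are re-drawn uniformly over their levels,
#' producing improbable covariate combinations.  Directions are randomized
#' per row so the injected outliers scatter around the data margins instead
#' of forming their own cluster.  The altered indices are returned as ground
#' truth for evaluating the unsupervised outlier-detection pipeline.
#'
#' @param cohort A `cohort` data frame.
#' @param config A [generator_config()]; uses `outlier_fraction`,
#'   `outlier_scale`, `seed`.
#' @param schema Schema describing the covariate columns.
#' @return List with `cohort` (modified) and `outlier_rows` (integer index).
#' @export
inject_outliers <- function(cohort, config, schema = default_schema()) {
  set.seed(config$seed + 13L)
  n <- nrow(cohort)
  k <- round(config$outlier_fraction * n)
  if (k == 0) return(list(cohort = cohort, outlier_rows = integer()))
  rows <- sort(sample.int(n, k))
  cont <- names(schema)[vapply(schema, function(sp)
    sp$scale == "continuous", TRUE)]
  if (length(cont) > 0) {
    # per-row random direction on the outlier_scale-SD sphere of the
    # standardized continuous subspace, so outliers scatter instead of
    # piling up in a few corners
    U <- matrix(stats::rnorm(k * length(cont)), k, length(cont))
    U <- U / sqrt(rowSums(U^2))
    for (ci in seq_along(cont)) {
      sp <- schema[[cont[ci]]]
      pop_sd <- diff(sp$gen_params) / sqrt(12)  # SD of the uniform generator
      cohort[[cont[ci]]][rows] <- as.numeric(cohort[[cont[ci]]][rows]) +
        U[, ci] * config$outlier_scale * pop_sd
    }
  }
  # improbable categorical combinations: every categorical field re-drawn
  # uniformly over its levels, independently per outlier row
  for (sp in schema) {
    if (sp$scale != "continuous")
      cohort[[sp$name]][rows] <- sample(sp$levels, k, replace = TRUE)
  }
  list(cohort = cohort, outlier_rows = rows)
}

#' Write / read a cohort as CSV with a JSON schema sidecar
#'
#' Special codes are preserved as-is in the CSV; missing cells are empty.
#'
#' @param cohort A `cohort` data frame.
#' @param path CSV path.
#' @param schema Optional schema; when given, written next to `path` with
#'   extension `.schema.json`.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path, schema = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  if (!is.null(schema))
    write_schema_json(schema, sub("\\.csv$", ".schema.json", path))
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = "", colClasses = NA)
  class(out) <- c("cohort", class(out))
  out
}
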