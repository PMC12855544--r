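#' @useDynLib behavnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom survival coxph Surv cox.zph concordance ridge
NULL

# internal: fit a Cox model on a design matrix, optionally ridge-penalized.
# Returns coefficients, standard errors, Wald p-values and the penalized
# partial log-likelihood.  Penalty is applied on the standardized scale
# (scale = TRUE) so it is comparable across terms; coefficients come back on
# the original scale.
fit_cox_raw <- function(X, time, event, l2 = 0) {
  X <- as.matrix(X)
  if (l2 > 0) {
    fit <- survival::coxph(survival::Surv(time, event) ~
                             ridge(X, theta = l2, scale = TRUE))
  } else {
    fit <- survival::coxph(survival::Surv(time, event) ~ X,
                           ties = "efron")
  }
  beta <- as.numeric(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  names(beta) <- colnames(X)
  names(se) <- colnames(X)
  p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  ll <- fit$loglik[length(fit$loglik)]
  if (!is.null(fit$penalty)) ll <- ll - fit$penalty[2]
  list(beta = beta, se = se, p = p, loglik = ll, model = fit)
}

#' Univariate Cox screen
#'
#' Fits one single-term Cox model per design column and retains terms with
#' Wald p below `alpha`.  Non-convergent terms are dropped with a warning.
#'
#' @param X Cox design matrix (see [cox_design_matrix()]).
#' @param time,event Follow-up years and event indicator.
#' @param alpha Retention threshold (default 0.05).
#' @return Data frame with `term`, `beta`, `p`, `retained`.
#' @export
univariate_screen <- function(X, time, event, alpha = 0.05) {
  X <- as.matrix(X)
  rows <- lapply(colnames(X), function(nm) {
    res <- tryCatch(
      fit_cox_raw(X[, nm, drop = FALSE], time, event),
      error = function(e) NULL,
      warning = function(w) {
        f <- suppressWarnings(fit_cox_raw(X[, nm, drop = FALSE], time, event))
        if (any(!is.finite(f$se))) NULL else f
      })
    if (is.null(res) || !is.finite(res$p[1])) {
      warning("term '", nm, "' did not converge in the univariate screen; dropped")
      return(data.frame(term = nm, beta = NA_real_, p = NA_real_,
                        retained = FALSE))
    }
    data.frame(term = nm, beta = res$beta[1], p = res$p[1],
               retained = res$p[1] < alpha)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Iterative variance-inflation-factor filter
#'
#' Computes VIF_j = 1 / (1 - R^2_j) for each column regressed on the rest
#' and repeatedly removes the largest-VIF column exceeding `threshold`
#' until all remaining columns pass.
#'
#' @param X Complete numeric design matrix.
#' @param threshold VIF cutoff (default 10).
#' @return Character vector of retained column names.
#' @export
vif_filter <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (ncol(X) < 2) return(colnames(X))
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(keep, function(nm) {
      y <- X[, nm]
      Z <- X[, setdiff(keep, nm), drop = FALSE]
      fit <- stats::lm.fit(cbind(1, Z), y)
      r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
    worst <- which.max(vifs)
    if (vifs[worst] <= threshold) break
    keep <- setdiff(keep, names(vifs)[worst])
  }
  keep
}

#' Low-variance indicator filter
#'
#' Drops indicator columns whose minority-class frequency falls below
#' `min_level_freq` overall or within either event stratum; continuous
#' columns (more than two distinct values) are only checked for zero
#' variance.
#'
#' @param X Design matrix.
#' @param event Event indicator aligned to rows.
#' @param min_level_freq Minimum minority frequency (default 0.01).
#' @return Character vector of retained column names.
#' @export
low_variance_filter <- function(X, event, min_level_freq = 0.01) {
  X <- as.matrix(X)
  ok <- vapply(colnames(X), function(nm) {
    v <- X[, nm]
    vals <- unique(v)
    if (length(vals) <= 2) {
      groups <- list(v, v[event == 1], v[event == 0])
      all(vapply(groups, function(g) {
        if (length(g) == 0) return(FALSE)
        f <- mean(g == max(vals))
        min(f, 1 - f) >= min_level_freq
      }, TRUE))
    } else {
      stats::sd(v) > 1e-12
    }
  }, TRUE)
  colnames(X)[ok]
}

#' Fit the multivariate Cox model with iterative backward refinement
#'
#' All candidate terms enter jointly; terms are then removed one at a time
#' when they carry no independent explanatory value: the removal candidate
#' is the largest-p term with p >= `p_keep` whose deletion changes every
#' remaining coefficient by less than `beta_tol` (relative) and costs less
#' than `loglik_tol` in penalized partial log-likelihood.  The model is
#' refit after every removal so reported estimates always come from the
#' final term set.
#'
#' @param X Design matrix of screened candidates.
#' @param time,event Follow-up years and event indicator.
#' @param l2 L2 (ridge) penalty on standardized covariates (default 0.01).
#' @param stepwise Run backward refinement (default TRUE).
#' @param p_keep Significance level below which a term is never removed.
#' @param beta_tol Maximum tolerated relative change in remaining
#'   coefficients on removal (default 0.10).
#' @param loglik_tol Maximum tolerated penalized log-likelihood loss per
#'   removal (default 2).
#' @param conf_level Confidence level for HR intervals.
#' @return A `cox_fit` object: `terms` data frame (name, beta, se, hr,
#'   hr_pct, ci_low, ci_high, p), `removed`, `l2`, `loglik`, plus the data
#'   (`X`, `time`, `event`) needed by downstream diagnostics.
#' @export
fit_multivariate_cox <- function(X, time, event, l2 = 0.01, stepwise = TRUE,
                                 p_keep = 0.05, beta_tol = 0.10,
                                 loglik_tol = 2, conf_level = 0.95) {
  X <- as.matrix(X)
  keep <- colnames(X)
  fit <- fit_cox_raw(X[, keep, drop = FALSE], time, event, l2)
  removed <- character()
  while (stepwise && length(keep) > 1) {
    cand <- keep[order(fit$p[keep], decreasing = TRUE)]
    cand <- cand[fit$p[cand] >= p_keep]
    if (length(cand) == 0) break
    removed_this_round <- FALSE
    for (nm in cand) {
      sub <- setdiff(keep, nm)
      refit <- fit_cox_raw(X[, sub, drop = FALSE], time, event, l2)
      rel <- abs(refit$beta[sub] - fit$beta[sub]) /
        pmax(abs(fit$beta[sub]), 0.05)
      if (max(rel) < beta_tol && (fit$loglik - refit$loglik) < loglik_tol) {
        keep <- sub
        fit <- refit
        removed <- c(removed, nm)
        removed_this_round <- TRUE
        break
      }
    }
    if (!removed_this_round) break
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    name = keep,
    beta = as.numeric(fit$beta[keep]),
    se = as.numeric(fit$se[keep]),
    hr = exp(as.numeric(fit$beta[keep])),
    hr_pct = (exp(as.numeric(fit$beta[keep])) - 1) * 100,
    ci_low = exp(as.numeric(fit$beta[keep]) - z * as.numeric(fit$se[keep])),
    ci_high = exp(as.numeric(fit$beta[keep]) + z * as.numeric(fit$se[keep])),
    p = as.numeric(fit$p[keep]),
    stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(
    list(terms = terms, removed = removed, l2 = l2, loglik = fit$loglik,
         time_interactions = character(),
         X = X[, keep, drop = FALSE], time = time, event = event),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d terms, l2=%g, loglik=%.2f\n",
              nrow(x$terms), x$l2, x$loglik))
  print(x$terms, digits = 3)
  invisible(x)
}

#' Schoenfeld-residual proportional-hazards diagnostics
#'
#' Tests each term's scaled Schoenfeld residuals against time (identity
#' transform).  Terms violating proportionality at `alpha` get a
#' covariate-by-time interaction and the model is refit (unpenalized) with
#' those interactions included.
#'
#' @param fit A `cox_fit`.
#' @param alpha Per-term significance level (default 0.05).
#' @return List with `zph` (data frame: term, chisq, p, violates) and
#'   `fit` (the input fit, or the refit with `time_interactions` set and
#'   interaction rows appended to `terms`).
#' @export
test_proportional_hazards <- function(fit, alpha = 0.05) {
  base <- survival::coxph(survival::Surv(fit$time, fit$event) ~ fit$X,
                          ties = "efron")
  zph <- survival::cox.zph(base, transform = "identity", global = FALSE)
  tab <- as.data.frame(zph$table)
  term <- colnames(fit$X)
  out <- data.frame(term = term, chisq = tab$chisq, p = tab$p,
                    violates = tab$p < alpha, stringsAsFactors = FALSE)
  if (!any(out$violates)) return(list(zph = out, fit = fit))

  flagged <- term[out$violates]
  Xf <- fit$X[, flagged, drop = FALSE]
  Xm <- fit$X
  tfit <- survival::coxph(
    survival::Surv(fit$time, fit$event) ~ Xm + tt(Xf),
    tt = function(x, t, ...) x * t, ties = "efron")
  beta <- stats::coef(tfit)
  se <- sqrt(diag(stats::vcov(tfit)))
  nm <- c(colnames(Xm), paste0(flagged, ":time"))
  z <- stats::qnorm(0.975)
  terms <- data.frame(
    name = nm, beta = as.numeric(beta), se = as.numeric(se),
    hr = exp(as.numeric(beta)), hr_pct = (exp(as.numeric(beta)) - 1) * 100,
    ci_low = exp(as.numeric(beta) - z * as.numeric(se)),
    ci_high = exp(as.numeric(beta) + z * as.numeric(se)),
    p = stats::pchisq((as.numeric(beta) / as.numeric(se))^2, 1,
                      lower.tail = FALSE),
    stringsAsFactors = FALSE)
  newfit <- fit
  newfit$terms <- terms
  newfit$time_interactions <- paste0(flagged, ":time")
  list(zph = out, fit = newfit)
}

#' Cross-validated concordance index
#'
#' Stratified k-fold cross-validation preserving the event/censoring mix per
#' fold: the model is fit on k-1 folds, the held-out linear predictor is
#' scored with Harrell's C, and mean and SD over folds are returned.
#'
#' @param X,time,event Design matrix and outcomes.
#' @param folds Number of folds (default 10, >= 2).
#' @param l2 Ridge penalty passed to the per-fold fits.
#' @param seed Integer seed for fold assignment.
#' @return List with `mean`, `sd`, `per_fold`.
#' @export
cross_validate_cindex <- function(X, time, event, folds = 10, l2 = 0.01,
                                  seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  X <- as.matrix(X)
  n <- nrow(X)
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (g in c(0, 1)) {        # stratified assignment
    idx <- which(event == g)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cidx <- vapply(seq_len(folds), function(k) {
    tr <- fold != k; te <- !tr
    if (sum(event[te]) == 0)
      stop("a fold has no events; use fewer folds")
    f <- fit_cox_raw(X[tr, , drop = FALSE], time[tr], event[tr], l2)
    lp <- as.numeric(X[te, , drop = FALSE] %*% f$beta)
    cf <- survival::concordance(survival::Surv(time[te], event[te]) ~ lp,
                                reverse = TRUE)
    as.numeric(cf$concordance)
  }, numeric(1))
  list(mean = mean(cidx), sd = stats::sd(cidx), per_fold = cidx)
}

#' Printed-style hazard table
#'
#' Formats a fitted model the way epidemiological hazard tables are printed:
#' beta to 2 decimals, HR = exp(beta) to 2 decimals, HR% derived from the
#' *rounded* HR under the default `"table_match"` policy (so the HR% column
#' is always consistent with the printed HR column), confidence bounds to 2
#' decimals.  The `"exact"` policy reports (exp(beta) - 1) * 100 unrounded.
#'
#' @param fit A `cox_fit`, or a data frame with columns `name` and `beta`
#'   (printed coefficient sets can be fed straight in).  An `hr` column, when
#'   present, is taken as the printed hazard ratio — published tables carry
#'   HRs computed from unrounded coefficients, so exp(printed beta) cannot
#'   always reproduce them — and HR% derives from it.
#' @param policy `"table_match"` (default) or `"exact"`.
#' @return Data frame with `name`, `beta`, `hr`, `hr_pct`, `ci_low`,
#'   `ci_high`, `p` (CI/p columns NA when not available).
#' @export
hazard_table <- function(fit, policy = c("table_match", "exact")) {
  policy <- match.arg(policy)
  tr <- if (inherits(fit, "cox_fit")) fit$terms else as.data.frame(fit)
  if (!all(c("name", "beta") %in% names(tr)))
    stop("need columns 'name' and 'beta'")
  beta <- round(tr$beta, 2)
  hr <- if ("hr" %in% names(tr)) round(tr$hr, 2) else round(exp(tr$beta), 2)
  hr_pct <- if (policy == "table_match") round((hr - 1) * 100, 2)
            else (exp(tr$beta) - 1) * 100
  data.frame(
    name = tr$name, beta = beta, hr = hr, hr_pct = hr_pct,
    ci_low = if ("ci_low" %in% names(tr)) round(tr$ci_low, 2) else NA_real_,
    ci_high = if ("ci_high" %in% names(tr)) round(tr$ci_high, 2) else NA_real_,
    p = if ("p" %in% names(tr)) tr$p else NA_real_,
    stringsAsFactors = FALSE)
}

#' Cox linear-predictor risk score
#'
#' The risk score of participant i is the linear predictor
#' \eqn{\sum_j \beta_j x_{ij}} over the final-model terms, with reference
#' levels contributing zero.
#'
#' @param betas Named coefficient vector (or a `cox_fit`, whose final terms
#'   are used).
#' @param newdata Data frame of covariates.
#' @param schema Schema used to encode `newdata`.
#' @return Numeric vector of scores.
#' @export
risk_score <- function(betas, newdata, schema = default_schema()) {
  if (inherits(betas, "cox_fit"))
    betas <- stats::setNames(betas$terms$beta, betas$terms$name)
  X <- cox_design_matrix(newdata, schema)
  unknown <- setdiff(names(betas), colnames(X))
  if (length(unknown) > 0)
    stop("unknown terms in coefficient vector: ",
         paste(unknown, collapse = ", "))
  as.numeric(X[, names(betas), drop = FALSE] %*% betas)
}
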