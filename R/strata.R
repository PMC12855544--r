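#' Risk-stratification object
#'
#' Holds the four ascending cutpoints that partition the continuous risk
#' score into five ordered strata.  Can be built directly from cutpoints or
#' from printed per-stratum score ranges (`label -> c(lo, hi)`), in which
#' case cutpoints are placed at the midpoint of each between-range gap so
#' every real score maps to exactly one stratum.
#'
#' @param cutpoints Ascending numeric vector (length `n_labels - 1`).
#' @param labels Stratum labels, low risk to high risk.
#' @param ranges Optional named list of `c(lo, hi)` printed ranges; used to
#'   derive `cutpoints` when those are missing, and kept for reporting.
#' @return An object of class `risk_stratification`.
#' @export
risk_stratification <- function(cutpoints = NULL,
                                labels = c("very_low", "low", "moderate",
                                           "high", "very_high"),
                                ranges = NULL) {
  if (is.null(cutpoints)) {
    if (is.null(ranges)) stop("need cutpoints or ranges")
    ranges <- ranges[labels]
    his <- vapply(ranges, `[`, numeric(1), 2)
    los <- vapply(ranges, `[`, numeric(1), 1)
    cutpoints <- (his[-length(his)] + los[-1]) / 2
  }
  cutpoints <- as.numeric(cutpoints)
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("cutpoints must be strictly ascending")
  if (length(cutpoints) != length(labels) - 1)
    stop("need one fewer cutpoint than labels")
  span <- if (!is.null(ranges))
    c(min(vapply(ranges, `[`, numeric(1), 1)),
      max(vapply(ranges, `[`, numeric(1), 2)))
  else c(-Inf, Inf)
  structure(list(cutpoints = unname(cutpoints), labels = labels,
                 ranges = ranges, span = span),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat("<risk_stratification>\n  cutpoints:",
      paste(signif(x$cutpoints, 4), collapse = ", "), "\n  labels:   ",
      paste(x$labels, collapse = " < "), "\n")
  invisible(x)
}

#' Derive score strata with a leaf-capped decision tree
#'
#' Trains a single-feature classification tree (Gini impurity) of observed
#' incidence on the risk score, grown without complexity penalty and pruned
#' back to at most `n_leaves` leaves; the split thresholds are extracted,
#' sorted and frozen as the stratum cutpoints.  K-fold refits are used only
#' to *report* split stability (SD of the nearest refit threshold per
#' cutpoint), never to re-select the cuts.
#'
#' @param scores Numeric risk scores (finite).
#' @param events Binary event indicator.
#' @param n_leaves Maximum leaves (default 5).
#' @param folds Cross-validation folds for the stability report (default 10).
#' @param seed Integer seed.
#' @param labels Stratum labels (length `n_leaves`).
#' @return A `risk_stratification` with extra fields `stability`
#'   (per-cutpoint SD across fold refits) and `n_leaves_grown`.
#' @export
derive_strata <- function(scores, events, n_leaves = 5, folds = 10,
                          seed = 1L,
                          labels = c("very_low", "low", "moderate", "high",
                                     "very_high")[seq_len(n_leaves)]) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(scores)) < n_leaves)
    stop("need at least ", n_leaves, " distinct scores")
  cuts_for <- function(sc, ev, k_leaves) {
    # variance splitting on the 0/1 incidence: node impurity n*p*(1-p) is
    # proportional to the Gini index for a binary outcome, and (unlike
    # rpart's classification risk, which only counts majority flips) its
    # complexity sequence ranks splits by incidence improvement
    df <- data.frame(score = sc, event = as.numeric(ev))
    # each stratum must hold at least 5% of participants, so leaf incidence
    # estimates are stable enough to rank
    mb <- max(7, ceiling(0.05 * length(sc)))
    fit <- rpart::rpart(event ~ score, data = df, method = "anova",
                        control = rpart::rpart.control(
                          cp = 0, minsplit = 2 * mb, minbucket = mb,
                          maxcompete = 0, maxsurrogate = 0, xval = 0))
    # prune back to exactly k_leaves leaves (when the grown tree allows) by
    # repeatedly snipping the terminal split with the smallest impurity
    # reduction
    repeat {
      fr <- fit$frame
      if (sum(fr$var == "<leaf>") <= k_leaves) break
      nn <- as.integer(rownames(fr))
      is_split <- which(fr$var != "<leaf>")
      term <- is_split[vapply(is_split, function(i) {
        kids <- match(c(2L * nn[i], 2L * nn[i] + 1L), nn)
        all(fr$var[kids] == "<leaf>")
      }, TRUE)]
      red <- vapply(term, function(i) {
        kids <- match(c(2L * nn[i], 2L * nn[i] + 1L), nn)
        fr$dev[i] - sum(fr$dev[kids])
      }, numeric(1))
      fit <- rpart::snip.rpart(fit, toss = nn[term[which.min(red)]])
    }
    sp <- fit$splits
    if (is.null(sp) || nrow(sp) == 0) return(numeric())
    sort(unique(sp[, "index"]))
  }
  cutpoints <- cuts_for(scores, events, n_leaves)
  if (length(cutpoints) != n_leaves - 1)
    warning("tree grew ", length(cutpoints) + 1, " leaves instead of ",
            n_leaves)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(folds), length(scores)))
  refits <- lapply(seq_len(folds), function(k)
    cuts_for(scores[fold != k], events[fold != k], n_leaves))
  stability <- vapply(cutpoints, function(cp) {
    nearest <- vapply(refits, function(cs)
      if (length(cs) == 0) NA_real_ else cs[which.min(abs(cs - cp))],
      numeric(1))
    stats::sd(nearest, na.rm = TRUE)
  }, numeric(1))
  out <- risk_stratification(cutpoints = cutpoints,
                             labels = labels[seq_len(length(cutpoints) + 1)])
  out$stability <- stability
  out$n_leaves_grown <- length(cutpoints) + 1
  out
}

#' Assign scores to risk strata
#'
#' A score falls in stratum k when it lies at or above the (k-1)-th cutpoint
#' and below the k-th; scores exactly on a cutpoint go to the higher
#' stratum.  Scores outside the stratification's known span (when built from
#' printed ranges) are clamped to the end strata with a warning.
#'
#' @param score Numeric vector of risk scores.
#' @param stratification A [risk_stratification()].
#' @return Character vector of stratum labels.
#' @export
assign_stratum <- function(score, stratification) {
  if (any(score < stratification$span[1] | score > stratification$span[2]))
    warning("scores outside the stratification span; clamped to end strata")
  idx <- vapply(score, function(s) sum(s >= stratification$cutpoints) + 1L,
                integer(1))
  stratification$labels[idx]
}

#' Kaplan-Meier validation of risk strata
#'
#' Product-limit survival curves per stratum, all pairwise log-rank tests,
#' and 25/50/75% event-time percentiles with an `Inf` sentinel where the
#' curve never falls below the threshold ("not reached").
#'
#' @param time,event Follow-up years and event indicator.
#' @param labels Stratum label per row.
#' @param label_order Display order of strata (low to high risk); defaults
#'   to sorted unique labels.
#' @return A `km_validation` list: `curves` (per-stratum data frame of
#'   time / survival / at-risk), `pairwise_tests` (pair, chi2, p),
#'   `percentiles` (stratum, p25, p50, p75).
#' @export
km_validation <- function(time, event, labels,
                          label_order = sort(unique(labels))) {
  counts <- table(factor(labels, levels = label_order))
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0) {
    warning("excluding empty strata: ", paste(empty, collapse = ", "))
    label_order <- setdiff(label_order, empty)
  }
  if (length(label_order) < 2) stop("need at least 2 non-empty strata")
  keep <- labels %in% label_order
  time <- time[keep]; event <- event[keep]
  grp <- factor(labels[keep], levels = label_order)

  sf <- survival::survfit(survival::Surv(time, event) ~ grp)
  sfs <- summary(sf)
  strat <- sub("^grp=", "", as.character(sfs$strata))
  curves <- data.frame(stratum = strat, time = sfs$time,
                       survival = sfs$surv, n_risk = sfs$n.risk,
                       stringsAsFactors = FALSE)

  pairs <- utils::combn(label_order, 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- grp %in% pr
    sd <- survival::survdiff(
      survival::Surv(time[sel], event[sel]) ~ droplevels(grp[sel]))
    data.frame(pair = paste(pr, collapse = " vs "),
               chi2 = as.numeric(sd$chisq),
               p = stats::pchisq(as.numeric(sd$chisq), df = 1,
                                 lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))

  qs <- stats::quantile(sf, probs = c(0.25, 0.5, 0.75))$quantile
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 1)
  qs[is.na(qs)] <- Inf                     # "not reached" sentinel
  percentiles <- data.frame(stratum = label_order,
                            p25 = qs[, 1], p50 = qs[, 2], p75 = qs[, 3],
                            stringsAsFactors = FALSE)
  rownames(percentiles) <- NULL
  structure(list(curves = curves, pairwise_tests = pairwise,
                 percentiles = percentiles),
            class = "km_validation")
}

#' @export
print.km_validation <- function(x, ...) {
  cat("<km_validation>\n")
  print(x$percentiles, digits = 3)
  invisible(x)
}
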