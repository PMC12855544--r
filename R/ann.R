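#' Feedforward network architecture for influence analysis
#'
#' Two ReLU hidden layers (64 and 32 units by default) with an L2 penalty on
#' the weights entering the second hidden layer; the output head is chosen
#' per target scale (sigmoid + cross-entropy for binary, linear + squared
#' error for continuous, softmax + cross-entropy for categorical).  Trained
#' with Adam on mini-batches; early stopping monitors the held-out fold.
#'
#' @param hidden_sizes Two hidden-layer widths.
#' @param l2_on_second_hidden L2 coefficient on the first-to-second hidden
#'   weight matrix.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @return A `network_architecture` list.
#' @export
network_architecture <- function(hidden_sizes = c(64, 32),
                                 l2_on_second_hidden = 1e-4,
                                 epochs = 200, batch_size = 64,
                                 learning_rate = 1e-3, patience = 20) {
  if (length(hidden_sizes) != 2) stop("exactly two hidden layers")
  structure(list(hidden_sizes = hidden_sizes,
                 l2_on_second_hidden = l2_on_second_hidden,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, patience = patience),
            class = "network_architecture")
}

#' Encode a cohort for the neural influence analysis
#'
#' Continuous and ordinal-numeric variables are min-max scaled to [0, 1];
#' six-level intake frequencies are collapsed to a binary indicator of the
#' top intake band (the highest categories against all lower levels);
#' smoking history collapses to ever/never; nominal variables (bread,
#' cereal) are one-hot encoded.  Outcome and follow-up columns are never
#' encoded.
#'
#' @param cohort Cohort (or covariate) data frame, already preprocessed.
#' @param schema List of [variable_spec()] objects.
#' @return List with `features` (numeric matrix), `groups` (per variable:
#'   column indices, output head, class count), `nodes` (feature column
#'   names; one-hot levels are separate nodes).
#' @export
encode_for_ann <- function(cohort, schema) {
  stopifnot_schema(schema)
  cols <- list(); groups <- list()
  for (sp in schema) {
    v <- cohort[[sp$name]]
    if (is.null(v)) stop("column '", sp$name, "' missing")
    enc <- sp$ann_encoding
    if (enc == "binary_indicator") {
      m <- matrix(as.numeric(as.character(v)), ncol = 1,
                  dimnames = list(NULL, sp$name))
      head <- "binary"
    } else if (enc == "minmax_continuous") {
      x <- if (sp$scale == "ordinal")
        as.numeric(match(as.character(v), sp$levels)) - 1
      else as.numeric(v)
      rng <- range(x)
      if (diff(rng) < 1e-12) rng <- rng + c(0, 1)
      m <- matrix((x - rng[1]) / (rng[2] - rng[1]), ncol = 1,
                  dimnames = list(NULL, sp$name))
      head <- "continuous"
    } else if (enc == "top_category") {
      top <- sp$levels[seq_along(sp$levels) >= length(sp$levels) - 1]
      m <- matrix(as.numeric(as.character(v) %in% top), ncol = 1,
                  dimnames = list(NULL, sp$name))
      head <- "binary"
    } else if (enc == "ever_never") {
      m <- matrix(as.numeric(as.character(v) != sp$reference_level), ncol = 1,
                  dimnames = list(NULL, sp$name))
      head <- "binary"
    } else if (enc == "one_hot") {
      m <- vapply(sp$levels, function(l) as.numeric(as.character(v) == l),
                  numeric(length(v)))
      m <- matrix(m, ncol = length(sp$levels),
                  dimnames = list(NULL, paste(sp$name, sp$levels, sep = ".")))
      head <- "categorical"
    } else stop("unknown ann_encoding: ", enc)
    groups[[sp$name]] <- list(cols = integer(), head = head,
                              n_class = ncol(m))
    cols[[sp$name]] <- m
  }
  features <- do.call(cbind, cols)
  start <- 1L
  for (nm in names(cols)) {
    k <- ncol(cols[[nm]])
    groups[[nm]]$cols <- seq.int(start, length.out = k)
    start <- start + k
  }
  list(features = features, groups = groups, nodes = colnames(features))
}

relu <- function(x) (x + abs(x)) / 2

mlp_init <- function(n_in, hidden, n_out, seed) {
  set.seed(as.integer(seed))
  he <- function(fan_in, fan_out)
    matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)),
           fan_in, fan_out)
  list(W1 = he(n_in, hidden[1]), b1 = rep(0, hidden[1]),
       W2 = he(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
       W3 = he(hidden[2], n_out), b3 = rep(0, n_out))
}

mlp_forward <- function(w, X) {
  H1 <- relu(sweep(X %*% w$W1, 2, w$b1, "+"))
  H2 <- relu(sweep(H1 %*% w$W2, 2, w$b2, "+"))
  Z <- sweep(H2 %*% w$W3, 2, w$b3, "+")
  list(H1 = H1, H2 = H2, Z = Z)
}

mlp_loss <- function(w, X, y, head, l2) {
  Z <- mlp_forward(w, X)$Z
  base <- switch(head,
    binary = {
      p <- 1 / (1 + exp(-Z[, 1]))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    },
    continuous = mean((Z[, 1] - y)^2),
    categorical = {
      Zs <- Z - apply(Z, 1, max)
      lse <- log(rowSums(exp(Zs)))
      -mean(Zs[cbind(seq_along(y), y)] - lse)
    })
  base + l2 * sum(w$W2^2)
}

#' Train one feedforward network
#'
#' @param X Feature matrix (target's own columns excluded).
#' @param y Target: 0/1 for binary, numeric for continuous, integer class
#'   (1..K) for categorical heads.
#' @param head `"binary"`, `"continuous"` or `"categorical"`.
#' @param arch A [network_architecture()].
#' @param seed Integer seed (initialization and batch order).
#' @param X_val,y_val Optional validation split for early stopping.
#' @return A `weight_set`: matrices `W1`, `W2`, `W3` (and biases), the head,
#'   and the best validation loss.
#' @export
mlp_fit <- function(X, y, head, arch = network_architecture(), seed = 1L,
                    X_val = NULL, y_val = NULL) {
  X <- as.matrix(X)
  n_out <- if (head == "categorical") max(y) else 1L
  w <- mlp_init(ncol(X), arch$hidden_sizes, n_out, seed)
  m <- lapply(w, function(z) z * 0); v <- m   # Adam moments
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- arch$learning_rate; lam <- arch$l2_on_second_hidden
  n <- nrow(X)
  best <- list(w = w, loss = Inf, epoch = 0L)
  have_val <- !is.null(X_val)
  step <- 0L
  for (epoch in seq_len(arch$epochs)) {
    ord <- sample.int(n)
    for (bs in split(ord, ceiling(seq_along(ord) / arch$batch_size))) {
      Xb <- X[bs, , drop = FALSE]
      fw <- mlp_forward(w, Xb)
      nb <- length(bs)
      dZ <- switch(head,
        binary = matrix((1 / (1 + exp(-fw$Z[, 1])) - y[bs]) / nb, ncol = 1),
        continuous = matrix(2 * (fw$Z[, 1] - y[bs]) / nb, ncol = 1),
        categorical = {
          Zs <- fw$Z - apply(fw$Z, 1, max)
          P <- exp(Zs) / rowSums(exp(Zs))
          P[cbind(seq_len(nb), y[bs])] <- P[cbind(seq_len(nb), y[bs])] - 1
          P / nb
        })
      g <- list()
      g$W3 <- crossprod(fw$H2, dZ); g$b3 <- colSums(dZ)
      dH2 <- (dZ %*% t(w$W3)) * (fw$H2 > 0)
      g$W2 <- crossprod(fw$H1, dH2) + 2 * lam * w$W2; g$b2 <- colSums(dH2)
      dH1 <- (dH2 %*% t(w$W2)) * (fw$H1 > 0)
      g$W1 <- crossprod(Xb, dH1); g$b1 <- colSums(dH1)
      step <- step + 1L
      for (nm in names(w)) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    mon <- if (have_val) mlp_loss(w, X_val, y_val, head, lam)
           else mlp_loss(w, X, y, head, lam)
    if (!is.finite(mon)) break
    if (mon < best$loss - 1e-7) {
      best <- list(w = w, loss = mon, epoch = epoch)
    } else if (epoch - best$epoch >= arch$patience) break
  }
  out <- best$w
  out$head <- head
  out$val_loss <- best$loss
  class(out) <- "weight_set"
  out
}

#' Effective input-to-output weights of a trained network
#'
#' Sums, over every pair of hidden units, the product of the connection
#' weights along each input -> hidden1 -> hidden2 -> output path:
#' \eqn{W^{eff}_{i,o} = \sum_{h_1}\sum_{h_2} w_{i,h_1} w_{h_1,h_2} w_{h_2,o}},
#' which equals the entries of the ordered product of the three weight
#' matrices.  Biases are excluded.
#'
#' @param weight_set A `weight_set` (or any list with `W1`, `W2`, `W3`).
#' @return Numeric matrix, inputs x outputs.
#' @export
effective_weights <- function(weight_set) {
  with(weight_set, {
    if (ncol(W1) != nrow(W2) || ncol(W2) != nrow(W3))
      stop("weight matrices are not conformable")
    W1 %*% W2 %*% W3
  })
}

#' Train the cross-validated network ensemble for one target
#'
#' Training is repeated over `runs` independent fold shuffles of `folds`-fold
#' cross-validation, yielding `runs * folds` trained networks; each member
#' trains on its k-1 folds with the held-out fold driving early stopping.
#' Member seeds derive deterministically from `(seed, run, fold)`.  A member
#' whose loss turns non-finite is re-initialized once, then skipped with a
#' warning.
#'
#' @param features Encoded feature matrix *without* the target's columns.
#' @param y,head Target vector and output head (see [mlp_fit()]).
#' @param arch A [network_architecture()].
#' @param runs,folds Ensemble design (default 10 x 5 = 50 networks).
#' @param seed Integer seed.
#' @return List of `weight_set`s (length `runs * folds` minus skips).
#' @export
train_target_networks <- function(features, y, head,
                                  arch = network_architecture(),
                                  runs = 10, folds = 5, seed = 1L) {
  n <- nrow(features)
  members <- vector("list", runs * folds)
  i <- 0L
  for (run in seq_len(runs)) {
    set.seed(scramble_seed(seed, run))
    fold <- sample(rep_len(seq_len(folds), n))
    for (k in seq_len(folds)) {
      i <- i + 1L
      tr <- fold != k
      mseed <- scramble_seed(seed, run * 1000 + k)
      fit <- mlp_fit(features[tr, , drop = FALSE], subset_y(y, tr), head,
                     arch, seed = mseed,
                     X_val = features[!tr, , drop = FALSE],
                     y_val = subset_y(y, !tr))
      if (!is.finite(fit$val_loss)) {
        fit <- mlp_fit(features[tr, , drop = FALSE], subset_y(y, tr), head,
                       arch, seed = mseed + 1L,
                       X_val = features[!tr, , drop = FALSE],
                       y_val = subset_y(y, !tr))
        if (!is.finite(fit$val_loss)) {
          warning("ensemble member (run ", run, ", fold ", k,
                  ") diverged; skipped")
          next
        }
      }
      members[[i]] <- fit
    }
  }
  members[!vapply(members, is.null, TRUE)]
}

subset_y <- function(y, idx) if (is.matrix(y)) y[idx, , drop = FALSE] else y[idx]

#' Aggregate ensemble effective weights into an influence estimate
#'
#' The influence score is the median effective weight over ensemble members;
#' sign stability is the percentage of members with each sign (exact zeros
#' count toward the smaller sign class), and the stability tier applies the
#' thresholds: >= 70% highly stable, 60-69% moderately stable, < 60% low
#' stability, with an approximately even split (< 55%) labelled unstable.
#'
#' @param samples Numeric vector of effective weights over the ensemble
#'   (>= 2 members).
#' @return List: `median_weight`, `pct_positive`, `pct_negative`, `tier`.
#' @export
aggregate_influence <- function(samples) {
  if (length(samples) < 2) stop("need >= 2 ensemble members")
  n <- length(samples)
  np <- sum(samples > 0); nn <- sum(samples < 0); nz <- n - np - nn
  if (nz > 0) {                       # zeros join the smaller class
    if (np <= nn) np <- np + nz else nn <- nn + nz
  }
  pct_pos <- 100 * np / n; pct_neg <- 100 * nn / n
  consistency <- max(pct_pos, pct_neg)
  tier <- if (consistency < 55) "unstable"
          else if (consistency < 60) "low_stability"
          else if (consistency < 70) "moderately_stable"
          else "highly_stable"
  list(median_weight = stats::median(samples),
       pct_positive = pct_pos, pct_negative = pct_neg, tier = tier)
}

#' Build the directed influence matrix for one cohort
#'
#' Every variable is held out in turn as the prediction target of its own
#' network ensemble, with all other variables' encoded columns as inputs.
#' Effective weights are aggregated over the ensemble into median influence,
#' sign-stability percentages and tiers.  Network nodes are the encoded
#' features, so each one-hot level (e.g. each bread type) is its own node,
#' and a categorical target contributes one node per class through the
#' per-class columns of its softmax head.
#'
#' @param cohort Preprocessed single-cohort data frame (covariates only are
#'   used; outcome and follow-up columns are ignored).
#' @param schema List of [variable_spec()] objects.
#' @param arch A [network_architecture()].
#' @param runs,folds Ensemble design.
#' @param seed Integer seed.
#' @param variables Optional subset of schema variable names to include.
#' @return An `influence_matrix`: `nodes`, square matrices `median`,
#'   `pct_positive`, `pct_negative`, `tier` (NA diagonal / within-variable
#'   blocks), `cohort_label`.
#' @export
build_influence_matrix <- function(cohort, schema,
                                   arch = network_architecture(),
                                   runs = 10, folds = 5, seed = 1L,
                                   variables = names(schema)) {
  schema <- schema[variables]
  enc <- encode_for_ann(cohort, schema)
  # canonicalize the feature-column order so results do not depend on the
  # ordering of `variables` (only on the selected set)
  ord <- order(enc$nodes)
  enc$features <- enc$features[, ord, drop = FALSE]
  remap <- match(seq_along(enc$nodes), ord)
  enc$groups <- lapply(enc$groups, function(g) {
    g$cols <- remap[g$cols]
    g
  })
  enc$nodes <- enc$nodes[ord]
  nodes <- enc$nodes
  p <- length(nodes)
  med <- matrix(NA_real_, p, p, dimnames = list(nodes, nodes))
  pp <- med; pn <- med
  tier <- matrix(NA_character_, p, p, dimnames = list(nodes, nodes))
  for (vi in seq_along(variables)) {
    vname <- variables[vi]
    g <- enc$groups[[vname]]
    target_cols <- g$cols
    input_cols <- setdiff(seq_len(p), target_cols)
    y <- switch(g$head,
      binary = as.numeric(enc$features[, target_cols[1]]),
      continuous = as.numeric(enc$features[, target_cols[1]]),
      categorical = max.col(enc$features[, target_cols, drop = FALSE]))
    # per-target seed keyed to the variable name, so the grid is invariant
    # to the ordering of `variables`
    vseed <- scramble_seed(seed, sum(utf8ToInt(vname))) %% 1000000L
    members <- train_target_networks(
      enc$features[, input_cols, drop = FALSE], y, g$head, arch,
      runs = runs, folds = folds, seed = vseed)
    # effective weights: members x inputs x outputs
    effs <- lapply(members, effective_weights)
    n_out <- ncol(effs[[1]])
    for (oc in seq_len(n_out)) {
      node_o <- if (g$head == "categorical") nodes[target_cols[oc]]
                else nodes[target_cols[1]]
      for (ic in seq_along(input_cols)) {
        node_i <- nodes[input_cols[ic]]
        smp <- vapply(effs, function(E) E[ic, oc], numeric(1))
        ag <- aggregate_influence(smp)
        med[node_i, node_o] <- ag$median_weight
        pp[node_i, node_o] <- ag$pct_positive
        pn[node_i, node_o] <- ag$pct_negative
        tier[node_i, node_o] <- ag$tier
      }
    }
  }
  structure(list(nodes = nodes, median = med, pct_positive = pp,
                 pct_negative = pn, tier = tier,
                 cohort_label = unique(as.character(
                   cohort$cohort_label))[1] %||% NA_character_),
            class = "influence_matrix")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d nodes, cohort=%s\n",
              length(x$nodes), x$cohort_label))
  invisible(x)
}

#' Construct an influence matrix from known values
#'
#' Used to assemble matrices from externally reported influence scores (for
#' arithmetic-consistency checks) or in tests.
#'
#' @param median Square numeric matrix with dimnames.
#' @param pct_positive,pct_negative Optional matching matrices.
#' @param cohort_label Cohort tag.
#' @return An `influence_matrix`.
#' @export
influence_matrix_from_values <- function(median, pct_positive = NULL,
                                         pct_negative = NULL,
                                         cohort_label = NA_character_) {
  nodes <- rownames(median)
  structure(list(nodes = nodes, median = median,
                 pct_positive = pct_positive, pct_negative = pct_negative,
                 tier = NULL, cohort_label = cohort_label),
            class = "influence_matrix")
}

#' Difference matrix between cohort influence structures
#'
#' Elementwise T2DM-minus-Healthy median influence, with the absolute
#' difference and flags for sign reversals (entries whose medians have
#' strictly opposite signs in the two cohorts).
#'
#' @param t2dm_matrix,healthy_matrix `influence_matrix` objects over the
#'   same node set and ordering.
#' @return List with `difference`, `absolute`, `sign_reversal` matrices.
#' @export
difference_matrix <- function(t2dm_matrix, healthy_matrix) {
  if (!identical(t2dm_matrix$nodes, healthy_matrix$nodes))
    stop("influence matrices cover different variable sets")
  d <- t2dm_matrix$median - healthy_matrix$median
  rev <- (t2dm_matrix$median * healthy_matrix$median) < 0
  list(difference = d, absolute = abs(d), sign_reversal = rev)
}

#' Export an influence matrix as a long-format data frame
#'
#' One row per directed input -> target pair (NA cells dropped), with
#' median influence, sign-stability percentages and tier.
#'
#' @param x An `influence_matrix`.
#' @return Data frame: input, target, median, pct_positive, pct_negative,
#'   tier, cohort.
#' @export
influence_long <- function(x) {
  idx <- which(!is.na(x$median), arr.ind = TRUE)
  data.frame(
    input = x$nodes[idx[, 1]], target = x$nodes[idx[, 2]],
    median = x$median[idx],
    pct_positive = if (!is.null(x$pct_positive)) x$pct_positive[idx] else NA,
    pct_negative = if (!is.null(x$pct_negative)) x$pct_negative[idx] else NA,
    tier = if (!is.null(x$tier)) x$tier[idx] else NA,
    cohort = x$cohort_label, stringsAsFactors = FALSE)
}
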