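#' Two-dimensional embedding of a standardized matrix
#'
#' The default method is an exact t-SNE (Gaussian input kernel calibrated to
#' the requested perplexity, Student-t output kernel, momentum gradient
#' descent with early exaggeration), implemented in compiled code.  A PCA
#' method is available for small fixtures and for speed comparisons; it
#' ignores `perplexity` and `n_iter`.
#'
#' @param mat Standardized numeric matrix (rows = participants).
#' @param method `"tsne"` (default) or `"pca"`.
#' @param perplexity t-SNE perplexity; must satisfy `3 * perplexity < n - 1`.
#' @param n_iter Number of gradient-descent iterations.
#' @param seed Integer seed (t-SNE initialization is random).
#' @return n x 2 numeric matrix of embedding coordinates.
#' @export
embed_2d <- function(mat, method = c("tsne", "pca"),
                     perplexity = 40, n_iter = 5000, seed = 1L) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (method == "pca") {
    p <- stats::prcomp(mat, center = FALSE, scale. = FALSE)
    k <- min(2L, ncol(p$x))
    out <- matrix(0, nrow(mat), 2)
    out[, seq_len(k)] <- p$x[, seq_len(k)]
    return(out)
  }
  if (nrow(mat) - 1 < 3 * perplexity)
    stop("perplexity ", perplexity, " is too large for ", nrow(mat),
         " rows; lower the perplexity (need 3*perplexity < n-1)")
  set.seed(as.integer(seed))
  .tsne_embed_cpp(mat, perplexity, as.integer(n_iter))
}

#' Unsupervised outlier detection on a 2-D embedding
#'
#' The cleaning pipeline's structural-outlier stage: (1) embed the
#' standardized matrix in 2-D; (2) pick the cluster count k by maximum
#' average silhouette width over `k_range` (ties broken toward the smallest
#' k), clustering the embedding with Ward's linkage; (3) cut the Ward tree at
#' the selected k; (4) compute each point's Euclidean distance to its cluster
#' centroid; (5) flag points beyond the `percentile`-th percentile of those
#' distances (per cluster by default).
#'
#' @param mat Standardized numeric matrix.
#' @param perplexity,n_iter,seed,method Passed to [embed_2d()].
#' @param k_range Candidate cluster counts; default 2:10.
#' @param percentile Flagging percentile (default 95).
#' @param per_cluster If `TRUE` (default) the percentile threshold is
#'   computed within each cluster; otherwise globally over all distances.
#' @return An `outlier_report` list: `embedding`, `k_selected`,
#'   `silhouette_by_k`, `cluster_labels`, `centroid_distances`, `threshold`
#'   (per cluster), `flagged_rows`.
#' @export
detect_outliers <- function(mat, perplexity = 40, n_iter = 5000,
                            k_range = 2:10, percentile = 95, seed = 1L,
                            method = c("tsne", "pca"), per_cluster = TRUE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n <= max(k_range)) stop("need more rows than max(k_range)")
  emb <- embed_2d(mat, method = method, perplexity = perplexity,
                  n_iter = n_iter, seed = seed)
  d <- stats::dist(emb)
  hc <- stats::hclust(d, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    lab <- stats::cutree(hc, k = k)
    if (length(unique(lab)) < 2) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- as.character(k_range)
  k_selected <- k_range[which.max(sil)]   # which.max takes the first (smallest k) on ties
  labels <- stats::cutree(hc, k = k_selected)

  centroids <- t(vapply(sort(unique(labels)), function(cl)
    colMeans(emb[labels == cl, , drop = FALSE]), numeric(2)))
  cd <- sqrt(rowSums((emb - centroids[labels, , drop = FALSE])^2))

  if (per_cluster) {
    thr <- vapply(sort(unique(labels)), function(cl)
      stats::quantile(cd[labels == cl], percentile / 100, names = FALSE),
      numeric(1))
    flagged <- which(cd > thr[labels])
  } else {
    thr <- stats::quantile(cd, percentile / 100, names = FALSE)
    flagged <- which(cd > thr)
  }
  structure(
    list(embedding = emb, k_selected = k_selected, silhouette_by_k = sil,
         cluster_labels = labels, centroid_distances = cd, threshold = thr,
         flagged_rows = flagged),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> n=%d, k=%d, flagged=%d\n",
              length(x$cluster_labels), x$k_selected, length(x$flagged_rows)))
  invisible(x)
}

#' Serialize an outlier report as JSON
#'
#' @param report An `outlier_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path) {
  x <- list(k_selected = report$k_selected,
            silhouette_by_k = as.list(report$silhouette_by_k),
            threshold = as.numeric(report$threshold),
            flagged_rows = as.integer(report$flagged_rows))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
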