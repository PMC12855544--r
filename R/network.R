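#' Build a directed influence network
#'
#' One node per variable; a directed edge input -> target is kept when the
#' median influence exceeds `threshold` (default: strictly positive, the
#' positive-influence convention), with the median magnitude as edge weight.
#' An optional stability gate drops edges below a minimum sign-stability
#' tier.
#'
#' @param influence An `influence_matrix`.
#' @param threshold Minimum median influence for an edge (default 0,
#'   strict).
#' @param min_tier Optional stability gate: `"moderately_stable"` keeps
#'   moderately and highly stable edges, `"highly_stable"` only the latter.
#' @return An [igraph::graph] with vertex attribute `name` and edge
#'   attribute `weight`.
#' @export
build_network <- function(influence, threshold = 0, min_tier = NULL) {
  med <- influence$median
  keep <- !is.na(med) & med > threshold
  if (!is.null(min_tier) && !is.null(influence$tier)) {
    ok_tiers <- switch(min_tier,
      highly_stable = "highly_stable",
      moderately_stable = c("highly_stable", "moderately_stable"),
      stop("min_tier must be 'moderately_stable' or 'highly_stable'"))
    keep <- keep & !is.na(influence$tier) & influence$tier %in% ok_tiers
  }
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0)
    warning("no edges survive the threshold; returning an empty graph")
  edges <- data.frame(from = influence$nodes[idx[, 1]],
                      to = influence$nodes[idx[, 2]],
                      weight = abs(med[idx]), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = influence$nodes))
}

#' Five-metric centrality profile of a directed network
#'
#' Normalized in- and out-degree (incident edges over n-1), eigenvector
#' centrality in the prestige convention (a node is central when pointed to
#' by central nodes; max-normalized to 1), betweenness on shortest paths
#' with distances = 1/weight (stronger influence = shorter path), and
#' PageRank with damping 0.85.
#'
#' @param graph Directed igraph with >= 2 nodes.
#' @param weighted_betweenness Use 1/weight distances (default TRUE); FALSE
#'   gives the unweighted variant.
#' @return Data frame: node, in_degree, out_degree, eigenvector,
#'   betweenness, pagerank.
#' @export
centrality_profile <- function(graph, weighted_betweenness = TRUE) {
  n <- igraph::vcount(graph)
  if (n < 2) stop("need at least 2 nodes")
  indeg <- igraph::degree(graph, mode = "in") / (n - 1)
  outdeg <- igraph::degree(graph, mode = "out") / (n - 1)
  eig <- tryCatch(
    igraph::eigen_centrality(graph, directed = TRUE,
                             weights = igraph::E(graph)$weight)$vector,
    warning = function(w)
      igraph::eigen_centrality(graph, directed = TRUE,
                               weights = igraph::E(graph)$weight)$vector,
    error = function(e) {
      warning("directed eigenvector centrality failed to converge; ",
              "falling back to the undirected variant")
      igraph::eigen_centrality(graph, directed = FALSE,
                               weights = igraph::E(graph)$weight)$vector
    })
  dist_w <- if (weighted_betweenness && igraph::ecount(graph) > 0)
    1 / igraph::E(graph)$weight else NA
  btw <- igraph::betweenness(graph, directed = TRUE, weights = dist_w,
                             normalized = TRUE)
  pr <- igraph::page_rank(graph, damping = 0.85,
                          weights = igraph::E(graph)$weight)$vector
  data.frame(node = igraph::V(graph)$name,
             in_degree = as.numeric(indeg), out_degree = as.numeric(outdeg),
             eigenvector = as.numeric(eig), betweenness = as.numeric(btw),
             pagerank = as.numeric(pr), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Healthy-to-disease centrality deltas
#'
#' Per node and metric, the T2DM value minus the Healthy value, rounded to
#' 2 decimals for reporting alongside the raw difference.
#'
#' @param healthy_profiles,t2dm_profiles Data frames from
#'   [centrality_profile()] over the same node set.
#' @param digits Reporting precision (default 2).
#' @return Data frame with node, per-metric healthy / t2dm / delta columns.
#' @export
centrality_deltas <- function(healthy_profiles, t2dm_profiles, digits = 2) {
  if (!setequal(healthy_profiles$node, t2dm_profiles$node))
    stop("node sets differ between profiles")
  t2 <- t2dm_profiles[match(healthy_profiles$node, t2dm_profiles$node), ]
  metrics <- c("in_degree", "out_degree", "eigenvector", "betweenness",
               "pagerank")
  out <- data.frame(node = healthy_profiles$node, stringsAsFactors = FALSE)
  for (m in metrics) {
    out[[paste0(m, "_healthy")]] <- healthy_profiles[[m]]
    out[[paste0(m, "_t2dm")]] <- t2[[m]]
    out[[paste0("delta_", m)]] <- round(t2[[m]] - healthy_profiles[[m]],
                                        digits)
  }
  out
}

#' Vector-shift arrows between cohort centrality profiles
#'
#' Each node becomes an arrow from its Healthy (x, y) position to its T2DM
#' position in the plane spanned by two centrality metrics, with Euclidean
#' magnitude and a behavioral-theme color.
#'
#' @param healthy_profiles,t2dm_profiles Centrality profiles over the same
#'   nodes.
#' @param axes Two metric names (default eigenvector, betweenness).
#' @param theme_map Optional named vector node -> theme
#'   (dietary / psychological / lifestyle / sleep); see [default_theme_map()].
#' @return Data frame: node, base_x, base_y, tip_x, tip_y, magnitude, theme.
#' @export
vector_shift <- function(healthy_profiles, t2dm_profiles,
                         axes = c("eigenvector", "betweenness"),
                         theme_map = NULL) {
  if (!all(axes %in% names(healthy_profiles)))
    stop("unknown metric in axes: ", paste(axes, collapse = ", "))
  t2 <- t2dm_profiles[match(healthy_profiles$node, t2dm_profiles$node), ]
  dx <- t2[[axes[1]]] - healthy_profiles[[axes[1]]]
  dy <- t2[[axes[2]]] - healthy_profiles[[axes[2]]]
  theme <- if (is.null(theme_map)) NA_character_
           else unname(theme_map[healthy_profiles$node])
  data.frame(node = healthy_profiles$node,
             base_x = healthy_profiles[[axes[1]]],
             base_y = healthy_profiles[[axes[2]]],
             tip_x = t2[[axes[1]]], tip_y = t2[[axes[2]]],
             magnitude = sqrt(dx^2 + dy^2), theme = theme,
             stringsAsFactors = FALSE)
}

#' Default variable-to-theme map for the 18-predictor schema
#'
#' @return Named character vector mapping node names to behavioral themes.
#' @export
default_theme_map <- function() {
  c(loneliness_isolation = "psychological", seen_psychiatrist = "psychological",
    fed_up_feelings = "psychological", tense_highly_strung = "psychological",
    sleeplessness_insomnia = "sleep", sleep_duration_7_8h = "sleep",
    nap_during_day = "sleep", difficulty_getting_up = "sleep",
    plays_computer_games = "lifestyle", current_tobacco_smoking = "lifestyle",
    smoking_status = "lifestyle",
    salt_added_to_food = "dietary", bread_type = "dietary",
    cereal_type = "dietary", processed_meat = "dietary",
    beef_intake = "dietary", age = "demographic", bmi = "demographic")
}

#' Classify intervention roles from hazard ratios and centrality shifts
#'
#' Combines each node's Cox evidence (HR, p) with its healthy-to-T2DM
#' centrality deltas:
#' \itemize{
#'   \item dual_priority: significant risk factor (HR > 1, p < alpha) whose
#'     eigenvector or betweenness centrality rises in disease;
#'   \item structural_stabilizer: significant protective factor (HR < 1,
#'     p < alpha) whose eigenvector centrality falls;
#'   \item emergent_driver: risk-direction factor (HR > 1) whose outgoing
#'     influence or bridging rises while eigenvector centrality does not;
#'   \item other: everything else, including unmapped nodes.
#' }
#'
#' @param delta_table Output of [centrality_deltas()].
#' @param hazard_tab Data frame with columns `name`, `hr`, `p` (e.g. from
#'   [hazard_table()]).
#' @param node_map Named vector mapping hazard-term names to network nodes
#'   (categorical terms map to their parent node); default identity on
#'   matching names.
#' @param alpha Significance level (default 0.05).
#' @return Data frame: node, category, hr, hr_p, delta_eigenvector,
#'   delta_in_degree, delta_out_degree, delta_betweenness.
#' @export
classify_roles <- function(delta_table, hazard_tab, node_map = NULL,
                           alpha = 0.05) {
  if (is.null(node_map))
    node_map <- stats::setNames(hazard_tab$name, hazard_tab$name)
  rows <- lapply(seq_len(nrow(delta_table)), function(i) {
    node <- delta_table$node[i]
    terms <- names(node_map)[node_map == node]
    hrow <- hazard_tab[hazard_tab$name %in% terms, , drop = FALSE]
    if (nrow(hrow) == 0) {
      warning("node '", node, "' has no mapped hazard term; categorized other")
      hr <- NA_real_; p <- NA_real_
    } else {
      j <- which.max(abs(log(hrow$hr)))   # strongest mapped term
      hr <- hrow$hr[j]; p <- hrow$p[j]
    }
    de <- delta_table$delta_eigenvector[i]
    di <- delta_table$delta_in_degree[i]
    do_ <- delta_table$delta_out_degree[i]
    db <- delta_table$delta_betweenness[i]
    category <-
      if (is.na(hr)) "other"
      else if (hr > 1 && !is.na(p) && p < alpha && (de > 0 || db > 0))
        "dual_priority"
      else if (hr < 1 && !is.na(p) && p < alpha && de < 0)
        "structural_stabilizer"
      else if (hr > 1 && de <= 0 && (do_ > 0 || db > 0))
        "emergent_driver"
      else "other"
    data.frame(node = node, category = category, hr = hr, hr_p = p,
               delta_eigenvector = de, delta_in_degree = di,
               delta_out_degree = do_, delta_betweenness = db,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a graph as an edge-list CSV (and optionally GraphML)
#'
#' @param graph igraph object.
#' @param path CSV path.
#' @param graphml Optional GraphML path.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, graphml = NULL) {
  el <- igraph::as_data_frame(graph, what = "edges")
  utils::write.csv(el, path, row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(graph, graphml, format = "graphml")
  invisible(path)
}
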