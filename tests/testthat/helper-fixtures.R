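# Shared fixtures: tiny schemas, quick cohorts, and brute-force oracles.

# A 5-variable continuous schema for influence tests
schema5 <- function() {
  out <- lapply(paste0("v", 1:5), function(nm)
    variable_spec(nm, "continuous", cox_encoding = "continuous",
                  ann_encoding = "minmax_continuous", gen_params = c(0, 1)))
  names(out) <- paste0("v", 1:5)
  out
}

# Small mixed-type schema exercising every encoding
schema_mixed <- function() {
  specs <- list(
    variable_spec("flag", "binary", levels = c("0", "1"),
                  reference_level = "0", cox_encoding = "binary_indicator",
                  ann_encoding = "binary_indicator", gen_params = c(0.7, 0.3)),
    variable_spec("salt", "ordinal",
                  levels = c("never", "sometimes", "always"),
                  reference_level = "never", cox_encoding = "ordinal_numeric",
                  ann_encoding = "minmax_continuous",
                  gen_params = c(0.5, 0.3, 0.2)),
    variable_spec("bread", "nominal", levels = c("a", "b", "c"),
                  reference_level = "a", cox_encoding = "dummy_set",
                  ann_encoding = "one_hot", gen_params = c(0.5, 0.3, 0.2)),
    variable_spec("x", "continuous", cox_encoding = "continuous",
                  ann_encoding = "minmax_continuous", gen_params = c(0, 10))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Quick default-schema cohort
quick_cohort <- function(n_per_group = 300, seed = 1, ...) {
  simulate_cohort(generator_config(n_per_group = n_per_group, seed = seed,
                                   ...))
}

# Brute-force directed weighted betweenness (normalized), for <= 6 nodes:
# enumerates all simple paths between every ordered pair and counts, for
# every intermediate node, the share of shortest paths through it.
brute_betweenness <- function(nodes, edges) {
  # edges: data.frame(from, to, dist)
  n <- length(nodes)
  adj <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges)))
    adj[edges$from[i], edges$to[i]] <- edges$dist[i]
  paths_between <- function(s, t) {
    out <- list()
    recurse <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1]] <<- list(path = path, len = len)
        return(invisible())
      }
      for (v in nodes[is.finite(adj[last, ])]) {
        if (!v %in% path) recurse(c(path, v), len + adj[last, v])
      }
    }
    recurse(s, 0)
    out
  }
  btw <- stats::setNames(numeric(n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    shortest <- ps[abs(lens - min(lens)) < 1e-12]
    for (v in setdiff(nodes, c(s, t))) {
      through <- vapply(shortest, function(p) v %in% p$path, TRUE)
      btw[v] <- btw[v] + sum(through) / length(shortest)
    }
  }
  btw / ((n - 1) * (n - 2))
}
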