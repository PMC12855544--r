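test_that("edge rule keeps strictly positive median influence", {
  nodes <- c("a", "b", "c")
  m <- matrix(NA_real_, 3, 3, dimnames = list(nodes, nodes))
  m["a", "b"] <- 0.5; m["b", "c"] <- -0.4; m["c", "a"] <- 0
  g <- build_network(influence_matrix_from_values(m))
  expect_equal(igraph::ecount(g), 1)
  el <- igraph::as_data_frame(g)
  expect_equal(el$from, "a"); expect_equal(el$to, "b")
  expect_equal(el$weight, 0.5)
  # all-negative matrix yields an empty graph (with a warning)
  mneg <- m; mneg[!is.na(mneg)] <- -1
  expect_warning(g0 <- build_network(influence_matrix_from_values(mneg)),
                 "no edges")
  expect_equal(igraph::ecount(g0), 0)
})

test_that("edge count is non-increasing in the threshold", {
  set.seed(81)
  nodes <- paste0("n", 1:8)
  m <- matrix(runif(64, -1, 1), 8, 8, dimnames = list(nodes, nodes))
  diag(m) <- NA
  im <- influence_matrix_from_values(m)
  counts <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(th)
    igraph::ecount(suppressWarnings(build_network(im, threshold = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("centralities obey their normalization invariants", {
  # 3-node cycle: full symmetry
  nodes <- c("a", "b", "c")
  m <- matrix(NA_real_, 3, 3, dimnames = list(nodes, nodes))
  m["a", "b"] <- 1; m["b", "c"] <- 1; m["c", "a"] <- 1
  prof <- centrality_profile(build_network(influence_matrix_from_values(m)))
  expect_equal(prof$pagerank, rep(1 / 3, 3))
  expect_equal(prof$in_degree, rep(0.5, 3))

  # star: hub points at every leaf
  n <- 25
  nodes <- c("hub", paste0("leaf", 1:(n - 1)))
  m <- matrix(NA_real_, n, n, dimnames = list(nodes, nodes))
  m["hub", -1] <- 1
  prof <- centrality_profile(build_network(influence_matrix_from_values(m)))
  expect_equal(prof$out_degree[prof$node == "hub"], 1)
  expect_equal(unique(prof$in_degree[prof$node != "hub"]), 1 / (n - 1))

  # random graphs: property test
  set.seed(82)
  for (rep in 1:5) {
    k <- sample(5:30, 1)
    nd <- paste0("v", 1:k)
    mm <- matrix(runif(k * k, -1, 1), k, k, dimnames = list(nd, nd))
    diag(mm) <- NA
    g <- suppressWarnings(build_network(influence_matrix_from_values(mm)))
    p <- suppressWarnings(centrality_profile(g))
    expect_lt(abs(sum(p$pagerank) - 1), 1e-9)
    expect_true(all(p$in_degree >= 0 & p$in_degree <= 1))
    expect_true(all(p$out_degree >= 0 & p$out_degree <= 1))
    expect_true(all(p$betweenness >= 0 & p$betweenness <= 1))
    expect_lt(abs(max(p$eigenvector) - 1), 1e-6)
  }
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  set.seed(83)
  for (rep in 1:4) {
    k <- sample(4:6, 1)
    nodes <- paste0("v", 1:k)
    m <- matrix(NA_real_, k, k, dimnames = list(nodes, nodes))
    for (i in 1:k) for (j in 1:k)
      if (i != j && runif(1) < 0.5) m[i, j] <- runif(1, 0.2, 1)
    if (all(is.na(m))) m[1, 2] <- 0.5
    g <- suppressWarnings(build_network(influence_matrix_from_values(m)))
    p <- centrality_profile(g)
    idx <- which(!is.na(m), arr.ind = TRUE)
    edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                        dist = 1 / m[idx], stringsAsFactors = FALSE)
    oracle <- brute_betweenness(nodes, edges)
    expect_equal(setNames(p$betweenness, p$node)[nodes], oracle,
                 tolerance = 1e-9)
  }
})

test_that("centrality deltas reproduce the published shift columns", {
  ref <- reference_centrality_shifts()
  hp <- data.frame(node = ref$variable, in_degree = ref$in_degree_healthy,
                   out_degree = ref$out_degree_healthy,
                   eigenvector = ref$eigenvector_healthy,
                   betweenness = 0, pagerank = 1 / nrow(ref))
  tp <- data.frame(node = ref$variable, in_degree = ref$in_degree_t2dm,
                   out_degree = ref$out_degree_t2dm,
                   eigenvector = ref$eigenvector_t2dm,
                   betweenness = 0, pagerank = 1 / nrow(ref))
  d <- centrality_deltas(hp, tp)
  # published deltas come from the printed per-cohort columns; agreement to
  # the printed rounding
  expect_lt(max(abs(d$delta_in_degree - ref$in_degree_delta)), 0.011)
  expect_lt(max(abs(d$delta_out_degree - ref$out_degree_delta)), 0.011)
  expect_lt(max(abs(d$delta_eigenvector - ref$eigenvector_delta)), 0.011)
  # the headline shift: tobacco smoking eigenvector 0.43 -> 0.87
  tob <- d[d$node == "current_tobacco_smoking", ]
  expect_equal(tob$delta_eigenvector, 0.44)
  # identical profiles give all-zero deltas; swapped arguments negate
  z <- centrality_deltas(hp, hp)
  expect_true(all(z$delta_eigenvector == 0))
  sw <- centrality_deltas(tp, hp)
  expect_equal(sw$delta_eigenvector, -d$delta_eigenvector)
  expect_error(centrality_deltas(hp, tp[-1, ]), "node sets")
})

test_that("vector shifts are consistent with deltas and Euclidean length", {
  hp <- data.frame(node = c("a", "b"), in_degree = c(0.2, 0.4),
                   out_degree = c(0.1, 0.3), eigenvector = c(0.5, 0.2),
                   betweenness = c(0.1, 0.3), pagerank = c(0.5, 0.5))
  tp <- hp; tp$eigenvector <- c(0.8, 0.2); tp$betweenness <- c(0.5, 0.3)
  vs <- vector_shift(hp, tp)
  expect_equal(vs$magnitude, c(0.5, 0))      # 3-4-5 triangle and no change
  expect_equal(vs$tip_x - vs$base_x, tp$eigenvector - hp$eigenvector)
  expect_error(vector_shift(hp, tp, axes = c("eigenvector", "nope")),
               "unknown metric")
  # theme coloring from the map
  vs2 <- vector_shift(hp, tp, theme_map = c(a = "dietary", b = "sleep"))
  expect_equal(vs2$theme, c("dietary", "sleep"))
})

test_that("role classification reproduces the published archetypes", {
  deltas <- data.frame(
    node = c("current_tobacco_smoking", "cereal_type.muesli",
             "loneliness_isolation", "plays_computer_games"),
    delta_eigenvector = c(0.44, -0.07, -0.11, 0),
    delta_in_degree = c(0.28, -0.28, 0.20, 0),
    delta_out_degree = c(0.24, -0.24, 0.12, 0),
    delta_betweenness = c(0, 0, 0, 0))
  hz <- data.frame(name = c("current_tobacco_smoking", "cereal_type.muesli",
                            "loneliness_isolation", "plays_computer_games"),
                   hr = c(1.34, 0.57, 1.14, 1.00),
                   p = c(0.001, 0.001, 0.001, 0.9))
  roles <- classify_roles(deltas, hz)
  expect_equal(roles$category[roles$node == "current_tobacco_smoking"],
               "dual_priority")
  expect_equal(roles$category[roles$node == "cereal_type.muesli"],
               "structural_stabilizer")
  expect_equal(roles$category[roles$node == "loneliness_isolation"],
               "emergent_driver")
  expect_equal(roles$category[roles$node == "plays_computer_games"], "other")
  # pure function: identical inputs give identical assignments
  expect_identical(roles, classify_roles(deltas, hz))
  # unmapped nodes warn and fall to other
  expect_warning(r2 <- classify_roles(deltas, hz[-4, ]), "no mapped hazard")
  expect_equal(r2$category[r2$node == "plays_computer_games"], "other")
})
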