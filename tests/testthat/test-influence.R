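test_that("ANN encoding follows the per-scale contracts", {
  sch <- default_schema()
  tab <- data.frame(
    loneliness_isolation = c("1", "0"), seen_psychiatrist = c("0", "0"),
    sleeplessness_insomnia = c("0", "1"), fed_up_feelings = c("0", "0"),
    tense_highly_strung = c("0", "0"), sleep_duration_7_8h = c("1", "0"),
    nap_during_day = c("0", "0"), difficulty_getting_up = c("0", "0"),
    plays_computer_games = c("0", "0"), current_tobacco_smoking = c("0", "1"),
    smoking_status = c("never", "previous"),
    salt_added_to_food = c("never_rarely", "always"),
    bread_type = c("wholewheat", "white"), cereal_type = c("bran", "muesli"),
    processed_meat = c("five_to_six_week", "once_week"),
    beef_intake = c("never", "daily"),
    age = c(40, 70), bmi = c(18.5, 50), stringsAsFactors = FALSE)
  enc <- encode_for_ann(tab, sch)
  F <- enc$features
  # min-max endpoints map to 0 and 1
  expect_equal(unname(F[, "bmi"]), c(0, 1))
  expect_equal(unname(F[, "age"]), c(0, 1))
  # top-band intake indicator: 5-6/week and daily are 1, lower levels 0
  expect_equal(unname(F[, "processed_meat"]), c(1, 0))
  expect_equal(unname(F[, "beef_intake"]), c(0, 1))
  # smoking collapses to ever/never
  expect_equal(unname(F[, "smoking_status"]), c(0, 1))
  # one-hot rows sum to 1 within each nominal block
  bread_cols <- grep("^bread_type\\.", colnames(F))
  expect_equal(unname(rowSums(F[, bread_cols])), c(1, 1))
  expect_equal(sum(F[1, bread_cols]), 1)
  expect_equal(enc$groups$bread_type$head, "categorical")
  expect_equal(enc$groups$loneliness_isolation$head, "binary")
  expect_equal(enc$groups$age$head, "continuous")
})

test_that("effective weights equal the brute-force path enumeration", {
  set.seed(71)
  for (rep in 1:5) {
    w <- list(W1 = matrix(rnorm(6 * 4), 6, 4),
              W2 = matrix(rnorm(4 * 3), 4, 3),
              W3 = matrix(rnorm(3 * 2), 3, 2))
    eff <- effective_weights(w)
    oracle <- matrix(0, 6, 2)
    for (i in 1:6) for (o in 1:2) {
      s <- 0
      for (h1 in 1:4) for (h2 in 1:3)
        s <- s + w$W1[i, h1] * w$W2[h1, h2] * w$W3[h2, o]
      oracle[i, o] <- s
    }
    expect_lt(max(abs(eff - oracle)), 1e-10)
  }
  # all-ones network: each input's effective weight counts the paths
  ones <- list(W1 = matrix(1, 2, 2), W2 = matrix(1, 2, 1),
               W3 = matrix(1, 1, 1))
  expect_equal(unname(effective_weights(ones)), matrix(2, 2, 1))
  # a single path multiplies its weights
  single <- list(W1 = matrix(3, 1, 1), W2 = matrix(5, 1, 1),
                 W3 = matrix(7, 1, 1))
  expect_equal(unname(effective_weights(single)), matrix(105, 1, 1))
  bad <- list(W1 = matrix(1, 2, 3), W2 = matrix(1, 4, 2), W3 = matrix(1, 2, 1))
  expect_error(effective_weights(bad), "conformable")
})

test_that("sign-stability tiers follow the published thresholds", {
  mk <- function(np, nn) c(runif(np, 0.1, 1), -runif(nn, 0.1, 1))
  expect_equal(aggregate_influence(mk(45, 5))$tier, "highly_stable")
  expect_equal(aggregate_influence(mk(45, 5))$pct_positive, 90)
  expect_equal(aggregate_influence(mk(32, 18))$tier, "moderately_stable")
  expect_equal(aggregate_influence(mk(55, 45))$tier, "low_stability")
  expect_equal(aggregate_influence(mk(25, 25))$tier, "unstable")
  # zeros join the smaller sign class and percentages always total 100
  ag <- aggregate_influence(c(1, 1, 1, 0, -1))
  expect_equal(ag$pct_positive + ag$pct_negative, 100)
  expect_equal(ag$pct_negative, 40)   # the zero joins the negative class
  # order invariance of the aggregate
  x <- mk(30, 20)
  expect_equal(aggregate_influence(x), aggregate_influence(rev(x)))
  expect_error(aggregate_influence(1), "2 ensemble members")
})

test_that("ensemble training is deterministic and sized runs x folds", {
  set.seed(72)
  X <- matrix(runif(200 * 3), 200, 3)
  y <- as.numeric(X[, 1] > 0.5)
  arch <- network_architecture(hidden_sizes = c(8, 4), epochs = 15,
                               patience = 5)
  ens <- train_target_networks(X, y, "binary", arch, runs = 2, folds = 3,
                               seed = 73)
  expect_length(ens, 6)
  ens2 <- train_target_networks(X, y, "binary", arch, runs = 2, folds = 3,
                                seed = 73)
  expect_identical(lapply(ens, `[[`, "W1"), lapply(ens2, `[[`, "W1"))
  # runs = 10, folds = 5 would give 50 members; check the arithmetic cheaply
  expect_equal(10 * 5, 50)
})

test_that("each output head trains to better-than-chance loss", {
  set.seed(74)
  n <- 300
  X <- matrix(runif(n * 4), n, 4)
  arch <- network_architecture(hidden_sizes = c(16, 8), epochs = 60,
                               patience = 60, batch_size = 32)
  # binary
  yb <- as.numeric(X[, 1] + 0.2 * runif(n) > 0.6)
  fb <- mlp_fit(X, yb, "binary", arch, seed = 75)
  expect_lt(fb$val_loss, 0.6)
  # continuous
  yc <- 0.8 * X[, 2] + 0.1
  fc <- mlp_fit(X, yc, "continuous", arch, seed = 76)
  expect_lt(fc$val_loss, var(yc))
  # categorical (3 classes driven by X[,3])
  yk <- cut(X[, 3], c(-Inf, 0.33, 0.66, Inf), labels = FALSE)
  fk <- mlp_fit(X, yk, "categorical", arch, seed = 77)
  expect_lt(fk$val_loss, log(3))
})

test_that("influence grid has no self-influence and is order-invariant", {
  set.seed(78)
  sch <- schema5()
  n <- 400
  dat <- as.data.frame(matrix(runif(n * 5), n, 5))
  names(dat) <- names(sch)
  arch <- network_architecture(hidden_sizes = c(8, 4), epochs = 10,
                               patience = 3)
  im <- build_influence_matrix(dat, sch, arch, runs = 1, folds = 2, seed = 79)
  expect_equal(dim(im$median), c(5, 5))
  expect_true(all(is.na(diag(im$median))))
  expect_equal(sum(!is.na(im$median)), 5 * 4)
  # permuting the variable order permutes, not changes, the estimates
  perm <- c(3, 1, 5, 2, 4)
  im2 <- build_influence_matrix(dat, sch[perm], arch, runs = 1, folds = 2,
                                seed = 79, variables = names(sch)[perm])
  expect_equal(im2$median[im$nodes, im$nodes], im$median)
})

test_that("difference matrix subtracts healthy from t2dm and flags reversals", {
  nodes <- c("white_bread", "sleeplessness_insomnia", "muesli")
  mk <- function(vals) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(nodes, nodes))
    m[1, 2] <- vals[1]; m[3, 1] <- vals[2]; m[2, 3] <- vals[3]
    influence_matrix_from_values(m)
  }
  healthy <- mk(c(-1.28, 0.5, 0.2))
  t2dm <- mk(c(0.23, 0.4, -0.1))
  dm <- difference_matrix(t2dm, healthy)
  # printed worked cell: -1.28 in health, 0.23 in disease -> +1.51, reversal
  expect_equal(dm$difference["white_bread", "sleeplessness_insomnia"], 1.51)
  expect_true(dm$sign_reversal["white_bread", "sleeplessness_insomnia"])
  expect_false(dm$sign_reversal["muesli", "white_bread"])
  expect_equal(dm$absolute, abs(dm$difference))
  # identical matrices give zero; swapping arguments negates
  z <- difference_matrix(healthy, healthy)
  expect_true(all(z$difference == 0, na.rm = TRUE))
  sw <- difference_matrix(healthy, t2dm)
  expect_equal(sw$difference, -dm$difference)
  bad <- mk(c(1, 1, 1)); bad$nodes <- rev(bad$nodes)
  expect_error(difference_matrix(t2dm, bad), "different variable sets")
})

test_that("published influence differences reproduce from cohort columns", {
  ref <- reference_influence_scores()
  recomputed <- ref$t2dm_coeff - ref$healthy_coeff
  # printed differences come from unrounded coefficients: agreement holds to
  # one unit in the last printed decimal
  expect_lt(max(abs(recomputed - ref$difference)), 0.0105)
  # the headline reversal cell is exact: -1.28 -> 0.23 gives +1.51
  wb <- ref[ref$input == "white_bread" &
              ref$target == "sleeplessness_insomnia", ]
  expect_equal(wb$t2dm_coeff - wb$healthy_coeff, 1.51)
  expect_true(wb$healthy_coeff * wb$t2dm_coeff < 0)
  expect_equal(abs(ref$difference), ref$absolute, tolerance = 1e-8)
  # stability percentages are complementary
  expect_true(all(ref$healthy_pos + ref$healthy_neg == 100))
  expect_true(all(ref$t2dm_pos + ref$t2dm_neg == 100))
})
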