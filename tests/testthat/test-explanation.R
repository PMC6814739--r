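test_that("restricted objective ties to the divergence at the boundary selectors", {
  set.seed(40)
  for (i in 1:5) {
    p <- make_rep(30, runif(3, 1, 4))
    q <- make_rep(30, runif(2, 1, 4))
    expect_equal(restricted_objective(p, q, rep(1, 30)), cskl(p, q),
                 tolerance = 1e-8)
    expect_equal(restricted_objective(p, q, rep(0, 30)),
                 0.5 * 30 / (1 - 0.5))
  }
  p <- make_rep(10, c(2, 1))
  expect_error(restricted_objective(p, p, rep(1, 9)), "length")
  expect_error(restricted_objective(p, p, c(rep(1, 9), 2)), "0 or 1")
})

test_that("for a self-pair the restricted objective shrinks as the selector grows", {
  set.seed(41)
  p <- make_rep(40, c(3, 2, 1))
  ord <- sample(40)
  vals <- vapply(seq(5, 40, by = 5), function(k) {
    s <- numeric(40); s[ord[seq_len(k)]] <- 1
    restricted_objective(p, p, s)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  expect_true(all(vals >= -1e-9))
})

test_that("k = n forces the full selector and recovers the divergence", {
  set.seed(42)
  p <- make_rep(15, c(2, 1)); q <- make_rep(15, c(3, 1))
  ex <- explain_pair(p, q, k = 15, mode = "best", seed = 1)
  expect_equal(sort(ex$selected), 1:15)
  expect_equal(ex$objective, cskl(p, q), tolerance = 1e-8)
  expect_true(ex$converged)
  expect_lte(ex$iterations, 2L)
  expect_error(explain_pair(p, q, k = 16), "k must be")
})

test_that("alternating iterations never worsen the bilinear objective", {
  set.seed(43)
  for (i in 1:10) {
    p <- make_rep(25, runif(3, 1, 4)); q <- make_rep(25, runif(3, 1, 4))
    ex <- explain_pair(p, q, k = 6, mode = "best", seed = i)
    expect_true(all(diff(ex$trace) >= -1e-9))
  }
})

test_that("alternating optimum matches exhaustive search on small instances", {
  # reduced-size sanity version of the brute-force comparison (the full
  # 50-instance sweep lives in the acceptance suite)
  set.seed(44)
  matched <- 0L
  for (i in 1:15) {
    p <- make_rep(12, runif(2, 1, 4)); q <- make_rep(12, runif(2, 1, 4))
    sels <- utils::combn(12, 3)
    objs <- apply(sels, 2, function(ix) {
      s <- numeric(12); s[ix] <- 1
      restricted_objective(p, q, s)
    })
    ex <- explain_pair(p, q, k = 3, mode = "best", seed = i,
                       n_restarts = 25L)
    expect_gte(ex$objective, min(objs) - 1e-9)  # cannot beat the optimum
    if (ex$objective <= min(objs) + 1e-9) matched <- matched + 1L
  }
  expect_gte(matched, 13L)
})

test_that("best explanation dominates random selectors and the worst mode", {
  set.seed(45)
  p <- make_rep(60, c(4, 2)); q <- make_rep(60, c(3, 2))
  for (k in c(5, 20)) {
    best <- explain_pair(p, q, k, mode = "best", seed = 2)
    worst <- explain_pair(p, q, k, mode = "worst", seed = 2)
    expect_lte(best$objective, worst$objective)
    rnd <- vapply(1:100, function(b) {
      s <- numeric(60); s[sample.int(60, k)] <- 1
      restricted_objective(p, q, s)
    }, numeric(1))
    expect_lte(best$objective, min(rnd) + 1e-9)
    expect_equal(length(best$selected), k)
  }
})

test_that("a planted shared mechanism is recovered by the best-explaining set", {
  cl <- list(list(label_a = "disease_A", label_b = "disease_B",
                  n_shared = 10L, strength = 8))
  coll <- generate_collection(default_collection_spec(
    n_groups = 2L, datasets_per_group = 1L, n = 100L, m = 60L,
    cross_links = cl, seed = 5L))
  reps <- lapply(lapply(coll$datasets, standardize), decompose, alpha = 0.5)
  ex <- explain_pair(reps[[1]], reps[[2]], k = 10, mode = "best", seed = 2)
  shared <- coll$ground_truth$cross_links[[1L]]$variables
  expect_gte(length(intersect(ex$variable_ids, shared)), 8L)
})

test_that("explain_set reduces to explain_pair and is scale-invariant", {
  set.seed(46)
  p <- make_rep(30, c(3, 1)); q <- make_rep(30, c(2, 2))
  single <- explain_set(list(list(p, q)), k = 5, seed = 7)
  alone <- explain_pair(p, q, k = 5, seed = 7)
  expect_equal(single$selected, alone$selected)
  expect_equal(single$objective, alone$objective)
  doubled <- explain_set(list(list(p, q), list(p, q)), k = 5, seed = 7)
  expect_equal(doubled$selected, single$selected)
  expect_equal(doubled$objective, 2 * single$objective)
  expect_error(explain_set(list(), k = 2), "empty")
})

test_that("variables shared by several pairs rank above pair-specific structure", {
  # two cross-linked groups of two datasets: every cross-group pair shares
  # the same planted mechanism while carrying its own group structure; a
  # single selector over three such pairs should recover the shared set
  cl <- list(list(label_a = "disease_A", label_b = "disease_B",
                  n_shared = 8L, strength = 10))
  coll <- generate_collection(default_collection_spec(
    n_groups = 2L, datasets_per_group = 2L, n = 80L, m = 60L,
    cross_links = cl, seed = 101L))
  reps <- lapply(lapply(coll$datasets, standardize), decompose, alpha = 0.5)
  names(reps) <- vapply(coll$datasets, `[[`, character(1), "dataset_id")
  gt <- coll$ground_truth$pairs
  cross <- gt[gt$type == "cross_link", ][1:3, ]
  pair_list <- Map(function(a, b) list(reps[[a]], reps[[b]]),
                   cross$id_a, cross$id_b)
  ex <- explain_set(unname(pair_list), k = 8, seed = 3)
  shared <- coll$ground_truth$cross_links[[1L]]$variables
  expect_gte(length(intersect(ex$variable_ids, shared)), 6L)
})

test_that("explanation_curve lies below the random baseline on similar pairs", {
  coll <- generate_collection(default_collection_spec(
    n_groups = 1L, datasets_per_group = 2L, n = 200L, m = 60L, seed = 9L))
  reps <- lapply(lapply(coll$datasets, standardize), decompose, alpha = 0.5)
  cur <- explanation_curve(reps[[1]], reps[[2]], c(10, 50, 100),
                           n_random = 50, seed = 4)
  expect_equal(cur$k, c(10, 50, 100))
  expect_true(all(cur$objective_best < cur$random_mean))
  # k = n end point: optimized and random coincide at the divergence
  n <- reps[[1]]$n
  cur_full <- explanation_curve(reps[[1]], reps[[2]], n, n_random = 3,
                                seed = 4)
  expect_equal(cur_full$objective_best, cskl(reps[[1]], reps[[2]]),
               tolerance = 1e-8)
  expect_equal(cur_full$random_mean, cur_full$objective_best,
               tolerance = 1e-8)
})

test_that("jaccard handles the standard set cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(c("a", "a", "b"), c("b", "b", "a")), 1)  # set semantics
  expect_error(jaccard(character(0), character(0)), "undefined")
})
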