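make_pool <- function(X, ids = sprintf("chem%03d", seq_len(nrow(X)))) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$chemical_id <- ids
  df
}
feat_of <- function(pool) grep("^f", names(pool), value = TRUE)

test_that("random sampling truncates, reproduces, and is uniform", {
  pool <- make_pool(matrix(rnorm(6), 3, 2))
  sel <- sample_random(pool, 5)
  expect_setequal(sel$ids, pool$chemical_id)
  set.seed(1); a <- sample_random(pool, 2)
  set.seed(1); b <- sample_random(pool, 2)
  expect_identical(a$ids, b$ids)
  expect_error(sample_random(pool[0, ], 1), "empty")
  # 10,000 draws of 1-from-10 are compatible with a uniform multinomial
  pool10 <- make_pool(matrix(rnorm(20), 10, 2))
  set.seed(2)
  draws <- replicate(10000, sample_random(pool10, 1)$ids)
  counts <- table(factor(draws, levels = pool10$chemical_id))
  expect_gt(chisq.test(counts)$p.value, 0.001)
  expect_true(all(abs(counts - 1000) <= 4 * sqrt(10000 * 0.1 * 0.9)))
})

test_that("cluster representatives are the nearest-to-centroid chemicals", {
  set.seed(3)
  blob1 <- matrix(rnorm(40, 0, 0.3), 20, 2)
  blob2 <- matrix(rnorm(40, 8, 0.3), 20, 2)
  pool <- make_pool(rbind(blob1, blob2))
  sel <- sample_cluster_representatives(pool, feat_of(pool), 2)
  expect_length(sel$ids, 2)
  # one per blob
  picked <- match(sel$ids, pool$chemical_id)
  expect_equal(sort(as.integer(picked <= 20)), c(0, 1))
  # exhaustive oracle: within each cluster no member is closer to the centroid
  X <- as.matrix(pool[, feat_of(pool)])
  for (cl in unique(sel$diagnostics$cluster)) {
    members <- which(sel$diagnostics$cluster == cl)
    cen <- sel$diagnostics$centers[cl, ]
    d <- sqrt(colSums((t(X[members, , drop = FALSE]) - cen)^2))
    chosen <- intersect(pool$chemical_id[members], sel$ids)
    expect_length(chosen, 1)
    expect_equal(d[which(pool$chemical_id[members] == chosen)], min(d))
  }
  # truncation: pool smaller than n_sample returns everything
  expect_setequal(sample_cluster_representatives(pool[1:3, ],
                                                 feat_of(pool), 5)$ids,
                  pool$chemical_id[1:3])
})

test_that("n_sample = 1 on a symmetric point set picks the center", {
  X <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1), c(0, 0))
  pool <- make_pool(X)
  set.seed(4)
  sel <- sample_cluster_representatives(pool, feat_of(pool), 1)
  expect_equal(sel$ids, pool$chemical_id[5])
})

test_that("uncertainty sampling matches the sorting oracle with id tie-breaks", {
  pool <- make_pool(matrix(0, 4, 2))
  fake <- structure(list(widths = c(3, 2, 2, 1)), class = "interval_model")
  # inject widths through a stub interval model
  local_mocked_bindings(
    predict_interval = function(model, newdata) {
      data.frame(width = fake$widths[seq_len(nrow(newdata))])
    },
    .package = "alspace"
  )
  sel <- sample_uncertainty(pool, feat_of(pool), 2, fake)
  expect_equal(sel$ids, pool$chemical_id[c(1, 2)])
  fake$widths <- c(2, 2, 2, 2)
  sel2 <- sample_uncertainty(pool, feat_of(pool), 3, fake)
  expect_equal(sel2$ids, pool$chemical_id[1:3])
  expect_error(sample_uncertainty(pool, feat_of(pool), 1, list()),
               "interval_model")
})

test_that("uncertainty sampling picks the widest-interval chemical end to end", {
  df <- data.frame(f1 = c(rnorm(50, 0, 0.2), 5), f2 = 0)
  df$logIE <- df$f1 + c(rnorm(50, 0, 0.05), 0)
  im <- fit_interval_model(df, c("f1", "f2"), num_trees = 200, seed = 5)
  pool <- make_pool(cbind(c(0, 5), c(0, 0)))
  sel <- sample_uncertainty(pool, c("f1", "f2"), 1, im)
  w <- sel$diagnostics$width
  expect_equal(sel$ids, names(which.max(w)))
})

test_that("anticlustering separates coincident pairs optimally", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  pool <- make_pool(X)
  set.seed(6)
  plan <- build_anticlusters(pool, feat_of(pool), group_size = 2)
  expect_length(plan$groups, 2)
  expect_true(all(lengths(plan$groups) == 2))
  # optimal partition splits each coincident pair across groups
  D <- pairwise_euclidean(X, X)
  expect_equal(plan$objective, brute_force_anticluster(D))
  for (grp in plan$groups) {
    idx <- match(grp, pool$chemical_id)
    expect_length(intersect(idx, 1:2), 1)
  }
  # degenerate: all points coincident, objective 0
  pool0 <- make_pool(matrix(1, 4, 2))
  plan0 <- build_anticlusters(pool0, feat_of(pool0), 2)
  expect_equal(plan0$objective, 0)
  expect_error(build_anticlusters(pool[1:3, ], feat_of(pool), 2),
               "too small")
})

test_that("the exchange heuristic reaches 95% of the enumerated optimum", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20), 10, 2)
    pool <- make_pool(X)
    D <- pairwise_euclidean(X, X)
    opt <- brute_force_anticluster(D)
    plan <- build_anticlusters(pool, feat_of(pool), group_size = 5)
    expect_gte(plan$objective, plan$initial_objective)
    expect_gte(plan$objective, 0.95 * opt)
  }
})

test_that("anticluster plans partition the pool and visits label each chemical once", {
  pool <- make_pool(matrix(rnorm(28 * 2), 28, 2))
  set.seed(7)
  plan <- build_anticlusters(pool, feat_of(pool), group_size = 9)
  expect_length(plan$groups, 3)  # round(28/9) = 3; sizes 10/9/9
  expect_true(max(lengths(plan$groups)) - min(lengths(plan$groups)) <= 1)
  expect_setequal(unlist(plan$groups), pool$chemical_id)
  labeled <- character()
  for (it in seq_along(plan$order)) {
    sel <- sample_anticluster(plan, it, labeled)
    expect_length(intersect(sel$ids, labeled), 0)
    labeled <- c(labeled, sel$ids)
  }
  expect_setequal(labeled, pool$chemical_id)
  expect_error(sample_anticluster(plan, 4, labeled),
               class = "pool_exhausted")
  # visit order depends only on the seed
  set.seed(7)
  plan2 <- build_anticlusters(pool, feat_of(pool), group_size = 9)
  expect_identical(plan$order, plan2$order)
})

test_that("mix sampling classifies the diffuse blob sparse and width-argmaxes it", {
  set.seed(8)
  tight <- lapply(c(0, 10, 20, 30), function(cen) {
    matrix(rnorm(24, cen, 0.1), 12, 2)
  })
  diffuse <- matrix(rnorm(24, 50, 4), 12, 2)
  pool <- make_pool(do.call(rbind, c(tight, list(diffuse))))
  # train an interval model on data near the tight blobs so the diffuse
  # region is uncertain
  train <- as.data.frame(do.call(rbind, tight))
  names(train) <- c("f1", "f2")
  train$logIE <- train$f1 * 0.1 + rnorm(nrow(train), 0, 0.05)
  im <- fit_interval_model(train, c("f1", "f2"), num_trees = 200, seed = 8)
  sel <- sample_mix(pool, feat_of(pool), 5, im)
  expect_length(sel$ids, 5)
  # exactly one sparse cluster, and it is the diffuse one
  expect_equal(sum(sel$diagnostics$sparse), 1)
  sparse_cl <- which(sel$diagnostics$sparse)
  members <- which(sel$diagnostics$cluster == sparse_cl)
  expect_setequal(members, 49:60)
  # its selected chemical is the interval-width argmax within the blob
  w <- sel$diagnostics$width
  chosen <- intersect(sel$ids, pool$chemical_id[members])
  expect_equal(chosen,
               pool$chemical_id[members][which.max(w[members])])
  expect_error(sample_mix(pool, feat_of(pool), 1, im), "n_sample >= 2")
})

test_that("equal cluster tightness degenerates mix to pure clustering", {
  # two coincident-pair clusters: identical mean distances, all dense
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  pool <- make_pool(X)
  train <- data.frame(f1 = rnorm(30), f2 = rnorm(30))
  train$logIE <- rnorm(30)
  im <- fit_interval_model(train, c("f1", "f2"), num_trees = 50, seed = 9)
  set.seed(9)
  sel <- sample_mix(pool, feat_of(pool), 2, im)
  expect_false(any(sel$diagnostics$sparse))
  expect_length(sel$ids, 2)
})

test_that("cost sampling takes the cheapest available chemicals", {
  pool <- make_pool(matrix(0, 3, 2))
  pool$price <- c(5, 1, 3)
  expect_equal(sample_cost(pool, 2)$ids, pool$chemical_id[c(2, 3)])
  pool$price <- c(NA, NA, NA)
  expect_error(sample_cost(pool, 2), class = "pool_exhausted")
  pool$price <- c(NA, 2, 1)
  expect_setequal(sample_cost(pool, 5)$ids, pool$chemical_id[2:3])
  # ties broken by ascending chemical id
  pool$price <- c(1, 1, 1)
  expect_equal(sample_cost(pool, 2)$ids, pool$chemical_id[1:2])
})

test_that("no strategy returns an already-labeled chemical across a campaign", {
  ds <- generate_space(small_space_spec(seed = 17))
  ds$instances <- generate_prices(ds)
  for (strat in c("random", "clustering", "uncertainty", "anticlustering",
                  "mix", "cost")) {
    tr <- run_campaign(ds, fast_config(strat, n_sample = 8,
                                       n_repetitions = 1,
                                       n_iterations = 3))
    sel <- attr(tr, "selections")
    expect_false(any(duplicated(sel$chemical_id)), info = strat)
  }
})
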