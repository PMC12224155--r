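test_that("targeted-space split reproduces the 296/73 pool/test sizes", {
  chems <- data.frame(
    chemical_id = sprintf("c%03d", 1:369),
    class = rep(paste0("class", 1:4), c(129, 111, 74, 55)))
  set.seed(1)
  sp <- split_targeted_space(chems, 0.2)
  expect_length(sp$test, 73)
  expect_length(sp$pool, 296)
  expect_length(intersect(sp$pool, sp$test), 0)
  expect_setequal(c(sp$pool, sp$test), chems$chemical_id)
  # stratified: every class contributes to the test set proportionally
  test_cls <- table(chems$class[chems$chemical_id %in% sp$test])
  expect_true(all(test_cls >= 1))
  expect_true(max(abs(test_cls - 0.2 * c(129, 111, 74, 55))) <= 1)
})

test_that("split rejects degenerate fractions and falls back when unstratifiable", {
  chems <- data.frame(chemical_id = c("a", "b", "c", "d", "e"),
                      class = c("x", "x", "x", "x", "y"))
  expect_error(split_targeted_space(chems, 0), "between 0 and 1")
  expect_error(split_targeted_space(chems, 1), "between 0 and 1")
  set.seed(2)
  expect_warning(sp <- split_targeted_space(chems, 0.4), "unstratified")
  expect_length(sp$test, 2)
})

test_that("rmse, pooled rmse and R squared match hand arithmetic", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:2), "lengths differ")
  expect_equal(rmse_pooled(c(1, 1, 1, 1)), 1)
  expect_equal(rmse_pooled(c(3, 4)), 3.535534, tolerance = 1e-6)
  expect_equal(rmse_pooled(5), 5)
  # pooled RMSE is bounded by the per-class extremes
  set.seed(3)
  for (i in 1:20) {
    v <- runif(sample(2:6, 1), 0.1, 3)
    expect_gte(rmse_pooled(v), min(v))
    expect_lte(rmse_pooled(v), max(v))
  }
  expect_equal(r_squared(1:5, 1:5), 1)
  expect_equal(r_squared(1:5, -(1:5)), 1)
  p <- c(1, 2, 3); o <- c(2, 2, 4)
  expect_equal(r_squared(p, o), cor(p, o)^2)
  expect_error(r_squared(c(1, 1, 1), 1:3), "zero variance")
})

test_that("repetition stats use the denominator-N spread", {
  st <- repetition_stats(c(1, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$s, 1)
  expect_equal(st$sem, 1 / sqrt(2))
  expect_equal(repetition_stats(rep(2.2, 5))$s, 0)
  expect_equal(repetition_stats(rep(2.2, 5))$sem, 0)
  # SEM halves when N quadruples at fixed spread
  x4 <- c(1, 3); x16 <- rep(c(1, 3), 4)
  expect_equal(repetition_stats(x16)$sem,
               repetition_stats(x4)$sem / 2)
  expect_error(repetition_stats(2), "at least 2")
  # sample-sd variant uses N - 1
  expect_equal(repetition_stats(c(1, 3), sample_sd = TRUE)$s, sqrt(2))
})

test_that("labeling schedule reproduces the campaign bookkeeping", {
  sched <- labeling_schedule(296, 5, 20)
  expect_equal(sched$n_labeled[sched$iteration == 20], 100)
  expect_equal(round(sched$pct_labeled[sched$iteration == 20], 2), 33.78)
  expect_equal(labeling_schedule(296, 15, 20)$n_labeled[21], 296)
  expect_true(all(diff(sched$n_labeled) >= 0))
})

test_that("campaigns conserve chemicals and record a truthful trace", {
  ds <- generate_space(small_space_spec(seed = 19))
  cfg <- fast_config("random", n_sample = 10, n_repetitions = 2,
                     n_iterations = 3)
  tr <- run_campaign(ds, cfg)
  expect_s3_class(tr, "campaign_trace")
  expect_equal(nrow(tr), 2 * 4)  # iterations 0..3 per repetition
  # labeled counts follow the schedule and pct is labeled/pool
  pool_size <- floor(120 * 0.8) + (120 - floor(120 * 0.8)) - 24  # 96
  expect_equal(tr$n_labeled[tr$iteration == 2], rep(20, 2))
  expect_equal(tr$pct_labeled, 100 * tr$n_labeled / 96)
  # per-class RMSE columns pool to the recorded rmse_pooled
  cls_cols <- grep("^rmse_class", names(tr), value = TRUE)
  expect_length(cls_cols, 4)
  per_cls <- as.matrix(tr[, cls_cols])
  expect_equal(tr$rmse_pooled,
               apply(per_cls, 1, function(v) rmse_pooled(v[!is.na(v)])))
  # selections attribute matches the labeled counts
  sel <- attr(tr, "selections")
  expect_equal(nrow(sel), 2 * 3 * 10)
  expect_false(any(duplicated(sel[, c("repetition", "chemical_id")])))
})

test_that("iteration-0 metrics are identical across strategies (baseline invariance)", {
  ds <- generate_space(small_space_spec(seed = 19))
  ds$instances <- generate_prices(ds)
  base <- lapply(c("random", "clustering", "cost"), function(strat) {
    tr <- run_campaign(ds, fast_config(strat, n_sample = 5,
                                       n_repetitions = 2, n_iterations = 1))
    tr$rmse_pooled[tr$iteration == 0]
  })
  expect_equal(base[[1]], base[[2]])
  expect_equal(base[[1]], base[[3]])
})

test_that("an exhausted pool truncates the campaign instead of failing", {
  ds <- generate_space(small_space_spec(seed = 20, n_unexplored_chemicals = 20,
                                        n_classes = 2,
                                        class_proportions = c(0.5, 0.5)))
  # pool of 16; n_sample 10 exhausts it on the second selection
  tr <- run_campaign(ds, fast_config("random", n_sample = 10,
                                     n_repetitions = 1, n_iterations = 4))
  expect_lte(max(tr$n_labeled), 16)
  expect_true(any(tr$truncated))
  expect_lt(nrow(tr), 5)
})

test_that("importance tracking records per-iteration snapshots", {
  ds <- generate_space(small_space_spec(seed = 22))
  cfg <- fast_config("random", n_sample = 10, n_repetitions = 1,
                     n_iterations = 1, track_importance = TRUE)
  tr <- run_campaign(ds, cfg)
  vi <- attr(tr, "importance")
  expect_true(all(c("feature", "importance", "iteration") %in% names(vi)))
  expect_setequal(unique(vi$iteration), 0:1)
  expect_true(all(vi$importance >= 0))
})

test_that("space-separated CV rotates each class as the explored space", {
  ds <- generate_space(small_space_spec(seed = 24))
  cfg <- fast_config("random", n_sample = 5, n_repetitions = 1,
                     n_iterations = 1)
  cv <- space_separated_cv(ds, cfg)
  expect_named(cv, paste0("class", 1:4))
  for (tr in cv) {
    expect_s3_class(tr, "campaign_trace")
    expect_equal(max(tr$iteration), 1)
  }
  # explicit pairing subset and error cases
  cv1 <- space_separated_cv(ds, cfg, explored_classes = "class2")
  expect_named(cv1, "class2")
  cls_cols <- grep("^rmse_class", names(cv1$class2), value = TRUE)
  expect_false("rmse_class2" %in% cls_cols)
  expect_error(space_separated_cv(ds, cfg, explored_classes = "nope"),
               "unknown class")
  one_cls <- ds
  one_cls$instances$class[one_cls$instances$class != "explored"] <- "class1"
  expect_error(space_separated_cv(one_cls, cfg), "at least 2")
})

test_that("campaign traces serialize to CSV", {
  ds <- generate_space(small_space_spec(seed = 25))
  tr <- run_campaign(ds, fast_config("random", n_sample = 5,
                                     n_repetitions = 1, n_iterations = 1))
  dir <- withr::local_tempdir()
  paths <- write_campaign_trace(tr, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(file.path(dir, "trace.csv"))
  expect_equal(nrow(back), nrow(tr))
})
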