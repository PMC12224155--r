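#' Root-mean-squared error
#' @param pred,obs Numeric vectors of equal length.
#' @return RMSE.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(pred) == 0) stop("empty input")
  sqrt(mean((pred - obs)^2))
}

#' Pooled RMSE over chemical classes
#'
#' Gives every class equal weight regardless of size:
#' \deqn{RMSE_{pooled} = \sqrt{\frac{1}{m}\sum_{i=1}^m RMSE_i^2}}
#'
#' @param class_rmse Numeric vector of per-class RMSE values.
#' @return Pooled RMSE; always within `[min, max]` of the inputs.
#' @export
rmse_pooled <- function(class_rmse) {
  if (length(class_rmse) == 0) stop("empty input")
  sqrt(mean(class_rmse^2))
}

#' Spread and standard error of pooled RMSE across repetitions
#'
#' The spread uses denominator `N` (the number of repetitions):
#' \deqn{s = \sqrt{\frac{\sum (x - \bar x)^2}{N}}, \quad SEM = s/\sqrt{N}}
#'
#' @param values Pooled-RMSE values, one per repetition (`N >= 2`).
#' @param sample_sd Use denominator `N - 1` instead.
#' @return List with `mean`, `s`, `sem`, `n`.
#' @export
repetition_stats <- function(values, sample_sd = FALSE) {
  n <- length(values)
  if (n < 2) stop("need at least 2 repetitions")
  m <- mean(values)
  denom <- if (sample_sd) n - 1 else n
  s <- sqrt(sum((values - m)^2) / denom)
  list(mean = m, s = s, sem = s / sqrt(n), n = n)
}

#' Squared Pearson correlation between predictions and observations
#' @param pred,obs Numeric vectors (`>= 3` pairs, nonzero variance).
#' @return R squared.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  if (length(pred) < 3) stop("need at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    stop("zero variance: R squared undefined")
  }
  stats::cor(pred, obs)^2
}

#' Split the unexplored space into pool and targeted test set
#'
#' Holds out a class-stratified test set (the *targeted space*) from the
#' unexplored chemicals before any active learning, at the chemical
#' level. The total test size is `floor(test_fraction * n)`, allocated
#' across classes by largest remainder, so 369 chemicals at fraction 0.2
#' give a pool of 296 and a test set of 73.
#'
#' @param chemicals Chemical-level table with `chemical_id` and `class`.
#' @param test_fraction Fraction held out (strictly between 0 and 1).
#' @param stratify Stratify by class (falls back to an unstratified split
#'   with a warning when any class has fewer than 2 chemicals).
#' @return List of `pool` and `test` chemical-id vectors (disjoint,
#'   exhaustive).
#' @export
split_targeted_space <- function(chemicals, test_fraction = 0.2,
                                 stratify = TRUE) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be strictly between 0 and 1")
  }
  ids <- chemicals$chemical_id
  n <- length(ids)
  if (n == 0) stop("no unexplored chemicals to split")
  n_test <- floor(test_fraction * n)
  if (stratify && any(table(chemicals$class) < 2)) {
    warning("a class has fewer than 2 chemicals; splitting unstratified")
    stratify <- FALSE
  }
  if (!stratify) {
    test <- sample(ids, n_test)
  } else {
    cls <- split(ids, chemicals$class)
    quota <- largest_remainder_quota(n_test, lengths(cls))
    test <- unlist(mapply(function(v, q) sample(v, q), cls, quota,
                          SIMPLIFY = FALSE), use.names = FALSE)
  }
  list(pool = setdiff(ids, test), test = test)
}

# allocate n_test across strata of sizes `sizes` proportionally,
# largest remainder, never exceeding a stratum's size
largest_remainder_quota <- function(n_test, sizes) {
  quota <- n_test * sizes / sum(sizes)
  q <- pmin(floor(quota), sizes)
  rem <- n_test - sum(q)
  while (rem > 0) {
    room <- which(q < sizes)
    pick <- room[order(quota[room] - q[room], decreasing = TRUE)[1]]
    q[pick] <- q[pick] + 1
    rem <- rem - 1
  }
  q
}

#' Cumulative labeling schedule of a campaign
#'
#' @param pool_size Initial pool size (number of chemicals).
#' @param n_sample Batch size per iteration.
#' @param n_iterations Number of AL iterations.
#' @return Data frame (`iteration` 0..n, `n_labeled` capped at the pool
#'   size, `pct_labeled` = 100 x labeled / pool size).
#' @export
labeling_schedule <- function(pool_size, n_sample, n_iterations) {
  it <- 0:n_iterations
  n_labeled <- pmin(it * n_sample, pool_size)
  data.frame(iteration = it, n_labeled = n_labeled,
             pct_labeled = 100 * n_labeled / pool_size)
}

#' Campaign configuration
#'
#' @param strategy One of `"random"`, `"clustering"`, `"uncertainty"`,
#'   `"anticlustering"`, `"mix"`, `"cost"`.
#' @param n_sample Chemicals selected per iteration.
#' @param n_iterations AL iterations per repetition (default 20).
#' @param n_repetitions Independent repetitions (default 50).
#' @param test_fraction Targeted-space fraction (default 0.2).
#' @param seed Integer seed controlling every random choice.
#' @param params Booster hyperparameters ([regressor_params()]).
#' @param interval_quantiles Quantile pair for the interval model.
#' @param interval_trees Trees in the quantile forest.
#' @param rebuild_anticlusters Rebuild the anticluster plan each
#'   iteration instead of visiting a one-shot plan.
#' @param track_importance Record the variable-importance snapshot at
#'   each iteration (adds an `importance` attribute to the trace).
#' @return A `campaign_config`.
#' @export
campaign_config <- function(strategy, n_sample,
                            n_iterations = 20, n_repetitions = 50,
                            test_fraction = 0.2, seed = 1L,
                            params = regressor_params(),
                            interval_quantiles = c(0.05, 0.95),
                            interval_trees = 500,
                            rebuild_anticlusters = FALSE,
                            track_importance = FALSE) {
  known <- c("random", "clustering", "uncertainty", "anticlustering",
             "mix", "cost")
  strategy <- match.arg(strategy, known)
  stopifnot(n_sample >= 1, n_iterations >= 1, n_repetitions >= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(strategy = strategy, n_sample = as.integer(n_sample),
                 n_iterations = as.integer(n_iterations),
                 n_repetitions = as.integer(n_repetitions),
                 test_fraction = test_fraction, seed = as.integer(seed),
                 params = params,
                 interval_quantiles = interval_quantiles,
                 interval_trees = interval_trees,
                 rebuild_anticlusters = isTRUE(rebuild_anticlusters),
                 track_importance = isTRUE(track_importance)),
            class = "campaign_config")
}

needs_interval <- function(strategy) strategy %in% c("uncertainty", "mix")

#' Run an active-learning campaign
#'
#' For each repetition: split the unexplored chemicals into pool and
#' targeted test set, then iterate — re-clean and re-scale on the current
#' explored set, fit the log IE model, evaluate per-class RMSE /
#' pooled RMSE / R squared on the test set, select the next batch with
#' the configured strategy, and move every instance of the selected
#' chemicals from the pool into the explored set. The evaluation before
#' the first selection is recorded as iteration 0 (the "before AL"
#' baseline). If the pool empties before the iteration budget the
#' repetition ends early with `truncated = TRUE`.
#'
#' @param dataset A `synthetic_space` (or any list with an `instances`
#'   table of the same dialect).
#' @param config A [campaign_config()].
#' @return A `campaign_trace` data frame with one row per (repetition,
#'   iteration): `n_labeled`, `pct_labeled`, one `rmse_<class>` column
#'   per class, `rmse_pooled`, `r2`, `n_kept`, `truncated`, plus the
#'   selected ids in the `selections` attribute.
#' @export
run_campaign <- function(dataset, config) {
  stopifnot(inherits(config, "campaign_config"))
  inst <- dataset$instances
  chem <- chemical_table(inst)
  une_chem <- chem[chem$class != "explored", , drop = FALSE]
  if (nrow(une_chem) == 0) stop("dataset has no unexplored chemicals")
  classes <- sort(unique(une_chem$class))
  explored0 <- inst[inst$class == "explored", , drop = FALSE]
  if (config$strategy == "cost" && all(is.na(une_chem$price))) {
    stop("cost strategy requires prices; run generate_prices() first")
  }

  rows <- list()
  selections <- list()
  importances <- list()

  for (rep_i in seq_len(config$n_repetitions)) {
    set.seed(config$seed + rep_i)
    sp <- split_targeted_space(une_chem, config$test_fraction)
    pool_ids <- sort(sp$pool)
    pool_size0 <- length(pool_ids)
    explored <- explored0
    labeled <- character()
    plan <- NULL
    truncated <- FALSE

    for (it in 0:config$n_iterations) {
      cs <- clean_and_scale(
        explored,
        pool = inst[inst$chemical_id %in% pool_ids, , drop = FALSE],
        test = inst[inst$chemical_id %in% sp$test, , drop = FALSE])
      feat <- cs$report$kept
      fit_seed <- config$seed + rep_i
      model <- fit_regressor(cs$explored, feat, config$params,
                             seed = fit_seed)
      pred <- predict(model, cs$test)
      obs <- cs$test$logIE
      cls_rmse <- vapply(classes, function(cl) {
        sel <- cs$test$class == cl
        if (any(sel)) rmse(pred[sel], obs[sel]) else NA_real_
      }, numeric(1))
      pooled <- rmse_pooled(cls_rmse[!is.na(cls_rmse)])
      row <- data.frame(repetition = rep_i, iteration = it,
                        n_labeled = length(labeled),
                        pct_labeled = 100 * length(labeled) / pool_size0,
                        rmse_pooled = pooled,
                        r2 = r_squared(pred, obs),
                        n_kept = length(cs$report$kept_descriptors),
                        truncated = truncated)
      for (cl in classes) row[[paste0("rmse_", cl)]] <- cls_rmse[[cl]]
      rows[[length(rows) + 1]] <- row
      if (config$track_importance) {
        vi <- variable_importance(model)
        vi$repetition <- rep_i; vi$iteration <- it
        importances[[length(importances) + 1]] <- vi
      }

      if (it == config$n_iterations || truncated) break
      if (length(pool_ids) == 0) { truncated <- TRUE; next }

      pool_tbl <- cs$pool[!duplicated(cs$pool$chemical_id), , drop = FALSE]
      pool_tbl <- pool_tbl[order(pool_tbl$chemical_id), , drop = FALSE]
      imodel <- NULL
      if (needs_interval(config$strategy)) {
        imodel <- fit_interval_model(cs$explored, feat,
                                     quantiles = config$interval_quantiles,
                                     num_trees = config$interval_trees,
                                     seed = fit_seed)
      }
      sel <- tryCatch({
        switch(config$strategy,
          random = sample_random(pool_tbl, config$n_sample),
          clustering = sample_cluster_representatives(
            pool_tbl, feat, config$n_sample),
          uncertainty = sample_uncertainty(
            pool_tbl, feat, config$n_sample, imodel),
          mix = sample_mix(pool_tbl, feat, config$n_sample, imodel),
          cost = sample_cost(pool_tbl, config$n_sample),
          anticlustering = {
            if (is.null(plan) || config$rebuild_anticlusters) {
              plan <- build_anticlusters(pool_tbl, feat, config$n_sample)
            }
            it_idx <- if (config$rebuild_anticlusters) 1L else it + 1L
            sample_anticluster(plan, it_idx, labeled)
          })
      }, pool_exhausted = function(e) NULL)
      if (is.null(sel) || length(sel$ids) == 0) { truncated <- TRUE; next }

      selections[[length(selections) + 1]] <-
        data.frame(repetition = rep_i, iteration = it + 1,
                   strategy = config$strategy, chemical_id = sel$ids)
      labeled <- c(labeled, sel$ids)
      pool_ids <- setdiff(pool_ids, sel$ids)
      explored <- rbind(explored,
                        inst[inst$chemical_id %in% sel$ids, , drop = FALSE])
    }
  }

  trace <- do.call(rbind, rows)
  attr(trace, "selections") <- if (length(selections)) {
    do.call(rbind, selections)
  } else NULL
  if (config$track_importance) {
    attr(trace, "importance") <- do.call(rbind, importances)
  }
  attr(trace, "config") <- config
  class(trace) <- c("campaign_trace", "data.frame")
  trace
}

#' Aggregate a campaign trace across repetitions
#'
#' @param trace A `campaign_trace`.
#' @return Data frame per iteration: mean `pct_labeled`, mean
#'   `rmse_pooled`, its spread `s` and `sem` (denominator-`N` form, see
#'   [repetition_stats()]), and mean `r2`.
#' @export
summarize_campaign <- function(trace) {
  its <- sort(unique(trace$iteration))
  do.call(rbind, lapply(its, function(it) {
    sub <- trace[trace$iteration == it, , drop = FALSE]
    st <- if (nrow(sub) >= 2) repetition_stats(sub$rmse_pooled) else
      list(mean = mean(sub$rmse_pooled), s = NA_real_, sem = NA_real_)
    data.frame(iteration = it,
               pct_labeled = mean(sub$pct_labeled),
               rmse_pooled = st$mean, s = st$s, sem = st$sem,
               r2 = mean(sub$r2), n_reps = nrow(sub))
  }))
}

#' Space-separated cross-validation over explored/unexplored pairings
#'
#' Rotates which chemical class plays the explored space: for each
#' pairing one class's instances form the explored set and the remaining
#' classes the unexplored space, then a full campaign is run. This
#' isolates how the choice of starting space (its size and chemistry)
#' affects active learning.
#'
#' @param dataset A `synthetic_space`.
#' @param config A [campaign_config()].
#' @param explored_classes Classes to rotate as the explored space
#'   (default: every unexplored class in the dataset).
#' @return Named list of `campaign_trace` objects, one per pairing.
#' @export
space_separated_cv <- function(dataset, config,
                               explored_classes = NULL) {
  inst <- dataset$instances
  classes <- sort(setdiff(unique(inst$class), "explored"))
  if (length(classes) < 2) stop("space-separated CV needs at least 2 classes")
  if (is.null(explored_classes)) explored_classes <- classes
  if (!all(explored_classes %in% classes)) {
    stop("unknown class in explored_classes")
  }
  out <- lapply(explored_classes, function(cl) {
    sub <- inst[inst$class != "explored", , drop = FALSE]
    sub$class[sub$class == cl] <- "explored"
    run_campaign(list(instances = sub), config)
  })
  names(out) <- explored_classes
  out
}

#' Write a campaign trace (and its selections) as CSV
#' @param trace A `campaign_trace`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_campaign_trace <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, "trace.csv")
  utils::write.csv(as.data.frame(trace), tp, row.names = FALSE)
  paths <- tp
  sel <- attr(trace, "selections")
  if (!is.null(sel)) {
    sp <- file.path(dir, "selections.csv")
    utils::write.csv(sel, sp, row.names = FALSE)
    paths <- c(paths, sp)
  }
  invisible(paths)
}
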