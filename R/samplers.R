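#' @title Batch sampling strategies for active learning
#' @description Each sampler operates on the *chemical-level* unexplored
#'   pool (one row per chemical, cleaned and scaled descriptors) and
#'   returns a `selection`: the chemical ids to label next plus strategy
#'   diagnostics. See [run_campaign()] for the loop that applies them.
#' @name samplers
NULL

new_selection <- function(strategy, ids, diagnostics = list()) {
  structure(list(strategy = strategy, ids = as.character(ids),
                 diagnostics = diagnostics),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection [", x$strategy, "]: ", length(x$ids), " chemicals\n",
      sep = "")
  invisible(x)
}

pool_exhausted <- function(msg) {
  stop(structure(class = c("pool_exhausted", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Random sampling (baseline)
#'
#' Uniform draw without replacement; returns the whole pool when
#' `n_sample` exceeds it.
#'
#' @param pool Chemical-level pool table with a `chemical_id` column.
#' @param n_sample Batch size.
#' @return A `selection`.
#' @export
sample_random <- function(pool, n_sample) {
  ids <- pool$chemical_id
  if (length(ids) == 0) pool_exhausted("pool is empty")
  n <- min(n_sample, length(ids))
  new_selection("random", sample(ids, n))
}

# k-means with restarts; k capped at the number of distinct rows
pool_kmeans <- function(X, k, nstart = 10) {
  k_eff <- min(k, nrow(unique(X)))
  stats::kmeans(X, centers = k_eff, nstart = nstart, iter.max = 50)
}

#' Clustering-based sampling (representativeness)
#'
#' Partitions the pool into `n_sample` k-means clusters on the scaled
#' descriptors and selects, per cluster, the chemical closest to the
#' cluster centroid — one representative per region of the pool.
#'
#' @param pool Chemical-level pool table.
#' @param feature_cols Scaled feature columns used for clustering.
#' @param n_sample Batch size (= number of clusters).
#' @param nstart Number of k-means restarts.
#' @return A `selection` with cluster assignments in `diagnostics`.
#' @export
sample_cluster_representatives <- function(pool, feature_cols, n_sample,
                                           nstart = 10) {
  ids <- pool$chemical_id
  if (length(ids) == 0) pool_exhausted("pool is empty")
  if (length(ids) <= n_sample) return(new_selection("clustering", ids))
  X <- model_matrix(pool, feature_cols)
  km <- pool_kmeans(X, n_sample, nstart)
  picked <- vapply(seq_len(max(km$cluster)), function(cl) {
    members <- which(km$cluster == cl)
    d <- sqrt(rowSums((X[members, , drop = FALSE] -
                         matrix(km$centers[cl, ], length(members),
                                ncol(X), byrow = TRUE))^2))
    members[order(d, ids[members])[1]]
  }, integer(1))
  new_selection("clustering", ids[picked],
                diagnostics = list(cluster = km$cluster,
                                   centers = km$centers))
}

#' Uncertainty-based sampling (informativeness)
#'
#' Selects the chemicals with the widest quantile-regression-forest
#' prediction intervals; ties are broken by ascending chemical id.
#'
#' @param pool Chemical-level pool table.
#' @param feature_cols Feature columns.
#' @param n_sample Batch size.
#' @param interval_model An [fit_interval_model()] fit on the current
#'   explored set.
#' @return A `selection` with per-chemical widths in `diagnostics`.
#' @export
sample_uncertainty <- function(pool, feature_cols, n_sample,
                               interval_model) {
  if (!inherits(interval_model, "interval_model")) {
    stop("sample_uncertainty requires a fitted interval_model")
  }
  ids <- pool$chemical_id
  if (length(ids) == 0) pool_exhausted("pool is empty")
  w <- predict_interval(interval_model, pool)$width
  ord <- order(-w, ids)
  take <- ord[seq_len(min(n_sample, length(ids)))]
  new_selection("uncertainty", ids[take],
                diagnostics = list(width = stats::setNames(w, ids)))
}

anticluster_objective <- function(D, assignment) {
  sum(vapply(split(seq_along(assignment), assignment), function(idx) {
    sum(D[idx, idx]) / 2
  }, numeric(1)))
}

#' Build a maximum-diversity anticlustering plan
#'
#' Partitions the initial pool into `K = round(n / group_size)` groups of
#' near-equal size (sizes differ by at most 1) that each *maximize*
#' within-group spread: starting from a random balanced partition, the
#' exchange heuristic repeatedly applies the cross-group swap that most
#' increases the diversity objective (sum over groups of within-group
#' pairwise Euclidean distances) until no swap improves it or the swap
#' budget is exhausted. Each group is then a diverse batch; groups are
#' visited in a random order, one per iteration.
#'
#' @param pool Chemical-level pool table.
#' @param feature_cols Scaled feature columns.
#' @param group_size Nominal batch size (the campaign's `n_sample`).
#' @param n_exchange_passes Swap budget in units of pool size (the
#'   heuristic stops after `n_exchange_passes * n` accepted swaps).
#' @return An `anticluster_plan`: `groups` (list of id vectors),
#'   `assignment`, `order` (random visit permutation), `objective`,
#'   `initial_objective`.
#' @export
build_anticlusters <- function(pool, feature_cols, group_size,
                               n_exchange_passes = 10) {
  ids <- pool$chemical_id
  n <- length(ids)
  if (n < 2 * group_size) {
    stop("pool too small for anticlustering: need at least 2 x group_size")
  }
  K <- max(2L, as.integer(round(n / group_size)))
  X <- model_matrix(pool, feature_cols)
  D <- pairwise_euclidean(X, X)

  # random balanced start: sizes differ by at most 1
  g <- sample(rep(seq_len(K), length.out = n))
  obj0 <- anticluster_objective(D, g)
  obj <- obj0
  S <- D %*% outer(g, seq_len(K), "==")  # S[i, k] = sum of d(i, group k)
  budget <- n_exchange_passes * n
  swaps <- 0L
  tol <- 1e-9
  while (swaps < budget) {
    s1 <- S[cbind(seq_len(n), g)]            # S[i, g[i]]
    M1 <- t(S)[g, , drop = FALSE]            # [i,j] = S[j, g[i]]
    M2 <- S[, g, drop = FALSE]               # [i,j] = S[i, g[j]]
    delta <- M1 - s1 + M2 -
      matrix(s1, n, n, byrow = TRUE) - 2 * D
    delta[outer(g, g, "==")] <- -Inf
    best <- which.max(delta)
    if (delta[best] <= tol) break
    j <- (best - 1L) %/% n + 1L
    i <- (best - 1L) %% n + 1L
    a <- g[i]; b <- g[j]
    obj <- obj + delta[best]
    S[, a] <- S[, a] - D[, i] + D[, j]
    S[, b] <- S[, b] - D[, j] + D[, i]
    g[i] <- b; g[j] <- a
    swaps <- swaps + 1L
  }
  structure(list(groups = split(ids, g), assignment = g,
                 order = sample(K), objective = obj,
                 initial_objective = obj0, n_swaps = swaps),
            class = "anticluster_plan")
}

#' Anticlustering sampling (diversity)
#'
#' Returns all not-yet-labeled members of the next group in the plan's
#' random visit order. Once the visit order is exhausted the pool has
#' been fully labeled.
#'
#' @param plan An [build_anticlusters()] plan over the initial pool.
#' @param iteration 1-based iteration index into the visit order.
#' @param labeled Chemical ids already labeled.
#' @return A `selection`.
#' @export
sample_anticluster <- function(plan, iteration, labeled = character()) {
  stopifnot(inherits(plan, "anticluster_plan"))
  if (iteration > length(plan$order)) {
    pool_exhausted("anticluster visit order exhausted")
  }
  grp <- plan$groups[[plan$order[iteration]]]
  new_selection("anticlustering", setdiff(grp, labeled),
                diagnostics = list(group = plan$order[iteration]))
}

#' Mix sampling (sparse/dense split of cluster space)
#'
#' Balances representativeness and informativeness: (1) k-means with
#' `k = n_sample` on the scaled pool; (2) per cluster, the mean
#' member-to-centroid distance; (3) a second k-means (`k = 2`) on these
#' cluster-level means labels the group with the larger center *sparse*
#' and the other *dense* (if all means coincide every cluster is treated
#' as dense); (4) one chemical per cluster — the widest-interval chemical
#' in sparse clusters, the nearest-to-centroid chemical in dense ones.
#'
#' @param pool Chemical-level pool table.
#' @param feature_cols Feature columns.
#' @param n_sample Batch size (must be at least 2).
#' @param interval_model Interval model for the sparse-cluster picks.
#' @param nstart k-means restarts.
#' @return A `selection` with cluster assignments and the sparse flags in
#'   `diagnostics`.
#' @export
sample_mix <- function(pool, feature_cols, n_sample, interval_model,
                       nstart = 10) {
  if (n_sample < 2) {
    stop("mix sampling requires n_sample >= 2 (the sparse/dense 2-means ",
         "is undefined for a single cluster)")
  }
  ids <- pool$chemical_id
  if (length(ids) == 0) pool_exhausted("pool is empty")
  if (length(ids) <= n_sample) return(new_selection("mix", ids))
  X <- model_matrix(pool, feature_cols)
  km <- pool_kmeans(X, n_sample, nstart)
  k_eff <- max(km$cluster)
  mean_dist <- vapply(seq_len(k_eff), function(cl) {
    members <- which(km$cluster == cl)
    mean(sqrt(rowSums((X[members, , drop = FALSE] -
                         matrix(km$centers[cl, ], length(members),
                                ncol(X), byrow = TRUE))^2)))
  }, numeric(1))

  if (length(unique(mean_dist)) < 2) {
    sparse <- rep(FALSE, k_eff)  # degenerate 2-means: all dense
  } else {
    km2 <- stats::kmeans(matrix(mean_dist), centers = 2, nstart = 10)
    sparse <- km2$cluster == which.max(km2$centers)
  }

  w <- predict_interval(interval_model, pool)$width
  picked <- vapply(seq_len(k_eff), function(cl) {
    members <- which(km$cluster == cl)
    if (sparse[cl]) {
      members[order(-w[members], ids[members])[1]]
    } else {
      d <- sqrt(rowSums((X[members, , drop = FALSE] -
                           matrix(km$centers[cl, ], length(members),
                                  ncol(X), byrow = TRUE))^2))
      members[order(d, ids[members])[1]]
    }
  }, integer(1))
  new_selection("mix", ids[picked],
                diagnostics = list(cluster = km$cluster, sparse = sparse,
                                   mean_dist = mean_dist,
                                   width = stats::setNames(w, ids)))
}

#' Cost-based sampling (cheapest first)
#'
#' Selects the `n_sample` cheapest chemicals with a vendor price;
#' unpriced (unavailable) chemicals are excluded. Ties are broken by
#' ascending chemical id.
#'
#' @param pool Chemical-level pool table with a `price` column.
#' @param n_sample Batch size.
#' @return A `selection`.
#' @export
sample_cost <- function(pool, n_sample) {
  ids <- pool$chemical_id
  avail <- !is.na(pool$price)
  if (!any(avail)) pool_exhausted("no priced chemicals remain in the pool")
  ord <- order(pool$price[avail], ids[avail])
  take <- ord[seq_len(min(n_sample, sum(avail)))]
  new_selection("cost", ids[avail][take],
                diagnostics = list(price = stats::setNames(
                  pool$price[avail][take], ids[avail][take])))
}
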