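#' Pairwise Euclidean distances between two sets of descriptor rows
#'
#' @param A,B Numeric matrices (rows = chemicals, columns = scaled
#'   descriptors) with identical column sets.
#' @return `nrow(A)` x `nrow(B)` distance matrix.
#' @export
pairwise_euclidean <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must share the same columns")
  if (!is.null(colnames(A)) && !is.null(colnames(B)) &&
      !identical(colnames(A), colnames(B))) {
    stop("A and B must share the same columns")
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical negatives from cancellation
  sqrt(d2)
}

#' Mean distance to the k nearest neighbors (d_NN=k)
#'
#' For each query chemical, aggregates the `k` smallest Euclidean
#' distances to the reference set. With `exclude_self = TRUE` (the
#' within-space form) the zero self-distance of each row to itself is
#' removed positionally, so duplicated points still count as neighbors.
#'
#' @param query,reference Numeric matrices of scaled descriptors.
#' @param k Number of neighbors (default 5).
#' @param exclude_self Set when `query` and `reference` are the same rows.
#' @param agg Aggregator over the k distances: `"mean"` (default) or
#'   `"median"`.
#' @return Numeric vector of per-query d_NN=k values.
#' @export
knn_mean_distance <- function(query, reference, k = 5,
                              exclude_self = FALSE,
                              agg = c("mean", "median")) {
  agg <- match.arg(agg)
  query <- as.matrix(query); reference <- as.matrix(reference)
  need <- if (exclude_self) k + 1 else k
  if (nrow(reference) < need) {
    stop("reference needs at least ", need, " rows for k = ", k,
         if (exclude_self) " with self-exclusion" else "")
  }
  D <- pairwise_euclidean(query, reference)
  f <- if (agg == "mean") mean else stats::median
  vapply(seq_len(nrow(D)), function(i) {
    d <- sort(D[i, ], partial = need)[seq_len(need)]
    d <- sort(d)
    if (exclude_self) d <- d[-1]
    f(d[seq_len(k)])
  }, numeric(1))
}

#' Chemical-space overlap summary between explored and unexplored spaces
#'
#' Computes two d_NN=k distributions on scaled descriptors: from each
#' explored chemical to its k nearest explored neighbors (self excluded)
#' and from each unexplored chemical to its k nearest explored neighbors.
#' When the unexplored distribution sits well above the explored one, the
#' candidate pool lies outside the model's applicability domain and
#' chemical-space expansion is warranted.
#'
#' @param explored,unexplored Numeric matrices of scaled descriptors with
#'   identical columns (one row per chemical, same scaler).
#' @param k Number of neighbors (default 5).
#' @param agg Aggregator passed to [knn_mean_distance()].
#' @return An `overlap_summary` with the per-chemical distances
#'   (`within_explored`, `unexplored_to_explored`) and a `summary` table
#'   of min, max and 95% quantile (type 7) per distribution.
#' @export
overlap_summary <- function(explored, unexplored, k = 5,
                            agg = c("mean", "median")) {
  agg <- match.arg(agg)
  within <- knn_mean_distance(explored, explored, k = k,
                              exclude_self = TRUE, agg = agg)
  across <- knn_mean_distance(unexplored, explored, k = k,
                              exclude_self = FALSE, agg = agg)
  smry <- data.frame(
    space = c("within_explored", "unexplored_to_explored"),
    min = c(min(within), min(across)),
    max = c(max(within), max(across)),
    q95 = c(stats::quantile(within, 0.95, type = 7, names = FALSE),
            stats::quantile(across, 0.95, type = 7, names = FALSE))
  )
  structure(list(within_explored = within,
                 unexplored_to_explored = across,
                 k = k, summary = smry),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("chemical-space overlap (d_NN=", x$k, "):\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write an overlap summary as a long-format CSV
#' @param x An `overlap_summary`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_overlap_summary <- function(x, path) {
  stopifnot(inherits(x, "overlap_summary"))
  long <- do.call(rbind, lapply(c("min", "max", "q95"), function(m) {
    data.frame(metric = m, space = x$summary$space, value = x$summary[[m]])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
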