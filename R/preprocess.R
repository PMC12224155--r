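#' Near-zero-variance descriptor filter
#'
#' Flags descriptor columns whose value distribution is almost degenerate.
#' A non-protected column is dropped iff the ratio of the frequency of its
#' most common value to the frequency of its second most common value is
#' at least `freq_cut` (the "80/20" rule: 80/20 = 4) AND the percentage of
#' distinct values over rows is below `unique_cut`. A column with a single
#' distinct value is always dropped (its ratio is treated as infinite).
#' Protected columns are never dropped.
#'
#' @param x Data frame or matrix of descriptor columns.
#' @param freq_cut Frequency-ratio cutoff (default 80/20 = 4).
#' @param unique_cut Percent-unique cutoff (default 10).
#' @param protected Column names exempt from the filter.
#' @return Character vector of column names to drop.
#' @export
remove_near_zero_variance <- function(x, freq_cut = 80 / 20,
                                      unique_cut = 10,
                                      protected = character()) {
  x <- as.data.frame(x)
  if (nrow(x) < 2) stop("need at least 2 rows to assess variance")
  candidates <- setdiff(names(x), protected)
  drop <- vapply(candidates, function(cn) {
    v <- x[[cn]]
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)
    ratio <- tab[[1]] / tab[[2]]
    pct_unique <- 100 * length(tab) / length(v)
    ratio >= freq_cut && pct_unique < unique_cut
  }, logical(1))
  candidates[drop]
}

#' Greedy pairwise-correlation pruning
#'
#' Removes descriptor columns until no pair of kept non-protected columns
#' has absolute Pearson correlation above `cutoff`. At each step the
#' remaining pair with the largest absolute correlation above the cutoff is
#' located and the member with the larger mean absolute correlation to all
#' remaining columns is dropped (on a tie the later column, by input
#' order, is dropped). Protected columns take no part in the correlation
#' computations and are never dropped.
#'
#' @param x Data frame or matrix of descriptor columns (nonzero variance).
#' @param cutoff Absolute-correlation threshold (default 0.75).
#' @param protected Column names exempt from the filter.
#' @return Character vector of column names to drop, in drop order.
#' @export
remove_correlated <- function(x, cutoff = 0.75, protected = character()) {
  x <- as.data.frame(x)
  cand <- setdiff(names(x), protected)
  if (length(cand) < 2) return(character())
  C <- abs(stats::cor(as.matrix(x[, cand, drop = FALSE])))
  diag(C) <- 0
  C[is.na(C)] <- 0
  dropped <- character()
  repeat {
    if (nrow(C) < 2) break
    mx <- max(C)
    if (mx <= cutoff) break
    hit <- which(C == mx, arr.ind = TRUE)[1, ]
    i <- hit[["row"]]; j <- hit[["col"]]
    mean_i <- mean(C[i, -i])
    mean_j <- mean(C[j, -j])
    # tie: drop the later column so earlier columns survive
    victim <- if (mean_i > mean_j) i else if (mean_j > mean_i) j else max(i, j)
    dropped <- c(dropped, rownames(C)[victim])
    C <- C[-victim, -victim, drop = FALSE]
  }
  dropped
}

#' Fit a column scaler on the explored (training) instances
#'
#' Centers by the mean and scales by the standard deviation (denominator
#' n - 1) of each column. A zero-variance column (possible only for
#' protected columns, which bypass the variance filter) gets scale 1 so
#' that applying the scaler never divides by zero.
#'
#' @param x Data frame of the explored instances.
#' @param cols Columns to scale.
#' @return A `col_scaler` with `center` and `scale` named vectors.
#' @export
fit_scaler <- function(x, cols) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop("columns absent from table: ", paste(missing, collapse = ", "))
  }
  center <- vapply(cols, function(cn) mean(x[[cn]]), numeric(1))
  scl <- vapply(cols, function(cn) stats::sd(x[[cn]]), numeric(1))
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = center, scale = scl, cols = cols),
            class = "col_scaler")
}

#' Apply (or invert) a fitted scaler
#'
#' @param x Data frame containing the scaler's columns.
#' @param scaler A [fit_scaler()] result.
#' @param reverse If `TRUE`, undo the scaling.
#' @return `x` with the scaler's columns transformed.
#' @export
apply_scaler <- function(x, scaler, reverse = FALSE) {
  stopifnot(inherits(scaler, "col_scaler"))
  missing <- setdiff(scaler$cols, names(x))
  if (length(missing)) {
    stop("table is missing scaled columns: ", paste(missing, collapse = ", "))
  }
  for (cn in scaler$cols) {
    if (reverse) {
      x[[cn]] <- x[[cn]] * scaler$scale[[cn]] + scaler$center[[cn]]
    } else {
      x[[cn]] <- (x[[cn]] - scaler$center[[cn]]) / scaler$scale[[cn]]
    }
  }
  x
}

#' Clean and standardize descriptor columns, fitted on the explored set
#'
#' Runs the near-zero-variance filter then the correlation pruning on the
#' explored instances only, drops the flagged columns from all supplied
#' tables, and standardizes the kept feature columns with a scaler fitted
#' on the explored instances. The pool and test tables have no influence
#' on which columns are dropped or on the scaling parameters; they are
#' transformed with the explored-set fit, as required to avoid leakage.
#' Cleaning is meant to be re-run every time labeling enlarges the
#' explored set.
#'
#' @param explored Instance table of the current training set.
#' @param pool,test Optional instance tables transformed with the
#'   explored-set fit.
#' @param protected Protected feature columns (default the eluent
#'   descriptors present in `explored`).
#' @param freq_cut,unique_cut,cutoff Filter parameters; see
#'   [remove_near_zero_variance()] and [remove_correlated()].
#' @return A list with `explored`, `pool`, `test` (cleaned, scaled),
#'   `report` (a `cleaning_report`: `dropped_nzv`, `dropped_corr`, `kept`,
#'   `protected`, `scaler`).
#' @export
clean_and_scale <- function(explored, pool = NULL, test = NULL,
                            protected = intersect(eluent_columns(),
                                                  names(explored)),
                            freq_cut = 80 / 20, unique_cut = 10,
                            cutoff = 0.75) {
  dcols <- descriptor_columns(explored)
  feat <- c(dcols, protected)
  for (tb in list(pool, test)) {
    if (!is.null(tb) && length(setdiff(feat, names(tb)))) {
      stop("pool/test tables must share the explored feature schema")
    }
  }
  desc <- explored[, dcols, drop = FALSE]
  dropped_nzv <- remove_near_zero_variance(desc, freq_cut, unique_cut,
                                           protected = character())
  desc2 <- desc[, setdiff(dcols, dropped_nzv), drop = FALSE]
  dropped_corr <- remove_correlated(desc2, cutoff, protected = character())
  kept_desc <- setdiff(dcols, c(dropped_nzv, dropped_corr))
  kept <- c(kept_desc, protected)

  scaler <- fit_scaler(explored, kept)
  strip <- function(tb) {
    if (is.null(tb)) return(NULL)
    tb <- tb[, setdiff(names(tb), c(dropped_nzv, dropped_corr)),
             drop = FALSE]
    apply_scaler(tb, scaler)
  }
  report <- structure(
    list(dropped_nzv = dropped_nzv, dropped_corr = dropped_corr,
         kept = kept, kept_descriptors = kept_desc, protected = protected,
         scaler = scaler),
    class = "cleaning_report")
  list(explored = strip(explored), pool = strip(pool), test = strip(test),
       report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("descriptor cleaning report:\n",
      " dropped (near-zero variance):", length(x$dropped_nzv), "\n",
      " dropped (|r| pruning):       ", length(x$dropped_corr), "\n",
      " kept descriptors:            ", length(x$kept_descriptors), "\n",
      " protected (eluent):          ", paste(x$protected, collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a cleaning report as a key-value text file
#' @param report A `cleaning_report`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  lines <- c(
    paste0("dropped_nzv: ", paste(report$dropped_nzv, collapse = " ")),
    paste0("dropped_corr: ", paste(report$dropped_corr, collapse = " ")),
    paste0("kept: ", paste(report$kept, collapse = " ")),
    paste0("protected: ", paste(report$protected, collapse = " ")),
    paste0("scaler_center: ",
           paste(names(report$scaler$center),
                 format(report$scaler$center, digits = 12),
                 sep = "=", collapse = " ")),
    paste0("scaler_scale: ",
           paste(names(report$scaler$scale),
                 format(report$scaler$scale, digits = 12),
                 sep = "=", collapse = " "))
  )
  writeLines(lines, path)
  invisible(path)
}
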