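#' Default booster hyperparameters for the log IE regressor
#'
#' Fixed defaults: 300 rounds, maximum depth 6, learning rate 0.1,
#' squared-error objective, single thread for reproducibility. Reduced
#' settings (fewer rounds, shallower trees) are appropriate for repeated
#' simulation campaigns.
#'
#' @param nrounds Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param eta Learning rate.
#' @param ... Further xgboost parameters (e.g. `subsample`,
#'   `colsample_bytree`, `min_child_weight`).
#' @return A named list of hyperparameters.
#' @export
regressor_params <- function(nrounds = 300, max_depth = 6, eta = 0.1, ...) {
  c(list(nrounds = nrounds, max_depth = max_depth, eta = eta), list(...))
}

model_matrix <- function(x, cols) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    stop("table is missing model columns: ", paste(missing, collapse = ", "))
  }
  m <- as.matrix(x[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit the gradient-boosted log IE regressor
#'
#' Trains an extreme-gradient-boosting tree ensemble of the predicted
#' log10 ionization efficiency on cleaned, scaled molecular and eluent
#' descriptors. Deterministic given (data, hyperparameters, seed).
#'
#' @param train Instance table containing the feature columns and `logIE`.
#' @param feature_cols Feature columns (kept descriptors + eluent).
#' @param params Hyperparameters from [regressor_params()].
#' @param seed Integer seed.
#' @return A `logie_model` with the fitted booster, feature names and
#'   training metadata.
#' @export
fit_regressor <- function(train, feature_cols,
                          params = regressor_params(), seed = 1L) {
  if (!"logIE" %in% names(train)) stop("training table has no logIE column")
  if (nrow(train) < 10) stop("need at least 10 training instances")
  X <- model_matrix(train, feature_cols)
  y <- train$logIE
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  nrounds <- params$nrounds
  xgb_params <- c(list(objective = "reg:squarederror", nthread = 1,
                       seed = as.integer(seed)),
                  params[setdiff(names(params), "nrounds")])
  booster <- xgboost::xgb.train(
    params = xgb_params,
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0)
  structure(list(booster = booster, feature_cols = feature_cols,
                 n_train = nrow(train), params = params, seed = seed),
            class = "logie_model")
}

#' Predict log IE for new instances
#' @param object A `logie_model`.
#' @param newdata Instance table with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted log IE.
#' @export
predict.logie_model <- function(object, newdata, ...) {
  X <- model_matrix(newdata, object$feature_cols)
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Variable importance of a fitted log IE model
#'
#' Total-gain share per feature, normalized to sum to 1 over the model's
#' feature columns. Features never used in a split have importance 0;
#' dropped descriptors do not appear.
#'
#' @param model A `logie_model`.
#' @return Data frame (`feature`, `importance`) covering every feature
#'   column, sorted by decreasing importance.
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "logie_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- data.frame(feature = model$feature_cols,
                    importance = 0, stringsAsFactors = FALSE)
  idx <- match(imp$Feature, out$feature)
  out$importance[idx[!is.na(idx)]] <- imp$Gain[!is.na(idx)]
  tot <- sum(out$importance)
  if (tot > 0) out$importance <- out$importance / tot
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Fit the quantile regression forest interval estimator
#'
#' A quantile regression forest retains the response distribution within
#' each leaf, so conditional quantiles — and thus prediction intervals —
#' can be read off for new chemicals. The interval width is the model's
#' uncertainty proxy: wide intervals flag chemicals far from the explored
#' space.
#'
#' @param train Instance table with feature columns and `logIE`.
#' @param feature_cols Feature columns.
#' @param quantiles Lower/upper quantile pair (default `c(0.05, 0.95)`).
#' @param num_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @return An `interval_model`.
#' @export
fit_interval_model <- function(train, feature_cols,
                               quantiles = c(0.05, 0.95),
                               num_trees = 500, seed = 1L) {
  if (!"logIE" %in% names(train)) stop("training table has no logIE column")
  stopifnot(length(quantiles) == 2, quantiles[1] <= quantiles[2])
  df <- as.data.frame(model_matrix(train, feature_cols))
  df$.y <- train$logIE
  rf <- ranger::ranger(dependent.variable.name = ".y", data = df,
                       num.trees = num_trees, quantreg = TRUE,
                       seed = as.integer(seed), num.threads = 1)
  structure(list(forest = rf, feature_cols = feature_cols,
                 quantiles = quantiles, seed = seed),
            class = "interval_model")
}

#' Prediction intervals (and widths) for pool instances
#'
#' @param model An `interval_model`.
#' @param newdata Instance table with the model's feature columns.
#' @return Data frame with `lower`, `upper` and `width = upper - lower`
#'   (always non-negative), one row per instance.
#' @export
predict_interval <- function(model, newdata) {
  if (!inherits(model, "interval_model")) {
    stop("predict_interval requires a fitted interval_model")
  }
  df <- as.data.frame(model_matrix(newdata, model$feature_cols))
  q <- predict(model$forest, df, type = "quantiles",
               quantiles = model$quantiles, num.threads = 1)$predictions
  lower <- q[, 1]; upper <- q[, 2]
  data.frame(lower = lower, upper = upper,
             width = pmax(upper - lower, 0))
}
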