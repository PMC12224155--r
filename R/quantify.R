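#' Fit a response-factor calibration from calibrant chemicals
#'
#' Standard-free quantification rests on the response factor
#' (intensity / concentration) being predictable from ionization
#' efficiency. The calibration is a least-squares fit of
#' \deqn{\log_{10}(intensity / concentration) = a + b \cdot logIE_{pred}}
#' on chemicals with known concentrations.
#'
#' @param intensity Positive signal intensities of the calibrants.
#' @param concentration Positive known concentrations (uM).
#' @param logie_pred Predicted log IE of the calibrants.
#' @return A `calibration` with `a` (intercept), `b` (slope), `n`,
#'   `residual_sd`, and the slope's standard error `b_se`.
#' @export
fit_calibration <- function(intensity, concentration, logie_pred) {
  n <- length(intensity)
  if (n < 2 || length(concentration) != n || length(logie_pred) != n) {
    stop("need at least 2 calibrants with matching intensity, ",
         "concentration and logIE vectors")
  }
  if (any(intensity <= 0) || any(concentration <= 0)) {
    stop("intensities and concentrations must be positive")
  }
  if (stats::sd(logie_pred) == 0) {
    stop("calibrants have identical predicted log IE: slope unidentifiable")
  }
  rf <- log10(intensity / concentration)
  fit <- stats::lm(rf ~ logie_pred)
  # summary() warns on a perfect (noise-free) fit; that case is legitimate
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 n = n,
                 residual_sd = sm$sigma,
                 b_se = if (nrow(co) > 1) co[2, 2] else NA_real_),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(
    "response-factor calibration: log10(I/C) = %.4g + %.4g logIE (n = %d)\n",
    x$a, x$b, x$n))
  invisible(x)
}

#' Predict a concentration from intensity and predicted log IE
#'
#' Inverts the calibration map:
#' \deqn{C_{pred} = intensity / 10^{a + b \cdot logIE_{pred}}}
#'
#' @param cal A [fit_calibration()] result.
#' @param intensity Positive signal intensity.
#' @param logie_pred Predicted log IE.
#' @return Predicted concentration (same units as the calibrants').
#' @export
predict_concentration <- function(cal, intensity, logie_pred) {
  if (!inherits(cal, "calibration")) {
    stop("predict_concentration requires a fitted calibration")
  }
  if (any(intensity <= 0)) stop("intensity must be positive")
  intensity / 10^(cal$a + cal$b * logie_pred)
}

#' Fold error between predicted and reference concentration
#'
#' The symmetric, scale-invariant accuracy measure
#' `max(C_pred / C_ref, C_ref / C_pred)`, always at least 1.
#'
#' @param c_pred,c_ref Positive concentrations (vectorized).
#' @return Fold error(s).
#' @export
fold_error <- function(c_pred, c_ref) {
  if (any(c_pred <= 0) || any(c_ref <= 0)) {
    stop("concentrations must be positive")
  }
  pmax(c_pred / c_ref, c_ref / c_pred)
}

#' Summarize fold errors over referenced chemicals
#'
#' @param fold_errors Fold errors of chemicals with reference
#'   concentrations.
#' @return List with `geometric_mean` (`exp(mean(log(x)))`), `min`,
#'   `max`, `n`.
#' @export
summarize_fold_errors <- function(fold_errors) {
  if (length(fold_errors) == 0) stop("no referenced chemicals")
  list(geometric_mean = exp(mean(log(fold_errors))),
       min = min(fold_errors), max = max(fold_errors),
       n = length(fold_errors))
}

#' Quantification records for a set of chemicals
#'
#' Convenience wrapper building the per-chemical quantification table:
#' predicted concentration from the calibration, and fold error where a
#' reference concentration is available.
#'
#' @param cal A `calibration`.
#' @param chemicals Data frame with `chemical_id`, `intensity`,
#'   `logie_pred` and optional `c_ref`.
#' @return The input with `c_pred` and `fold_error` (NA without
#'   reference) appended.
#' @export
quantify_chemicals <- function(cal, chemicals) {
  out <- chemicals
  out$c_pred <- predict_concentration(cal, chemicals$intensity,
                                      chemicals$logie_pred)
  out$fold_error <- NA_real_
  if ("c_ref" %in% names(chemicals)) {
    has <- !is.na(chemicals$c_ref)
    out$fold_error[has] <- fold_error(out$c_pred[has],
                                      chemicals$c_ref[has])
  }
  out
}

#' Reference quantification of natural products in Alpinia officinarum
#'
#' Measured and predicted values for ten natural products in an
#' *Alpinia officinarum* (galangal) extract quantified by predicted
#' ionization efficiency with a log IE model trained before and after
#' chemical-space expansion: reference concentration `c_ref` (uM; five
#' chemicals have analytical standards), predicted log IE and predicted
#' concentration (uM) under each model.
#'
#' @return Data frame with columns `chemical`, `c_ref`,
#'   `logie_pred_before`, `c_pred_before`, `logie_pred_after`,
#'   `c_pred_after`.
#' @export
alpinia_quant <- function() {
  path <- system.file("extdata", "alpinia_quant.csv", package = "alspace",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
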