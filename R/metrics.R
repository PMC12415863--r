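#' Root mean square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_n (a_n - p_n)^2 / N}}, in the units of the
#' endpoint.
#'
#' @param actual,predicted Numeric vectors of equal nonzero length.
#' @return Nonnegative scalar.
#' @export
rmse <- function(actual, predicted) {
  check_pair(actual, predicted)
  sqrt(mean((actual - predicted)^2))
}

#' Mean absolute percentage error
#'
#' \eqn{\mathrm{MAPE} = 100 \cdot \frac{1}{N}\sum_n |a_n - p_n| / a_n} with the
#' absolute value applied to the whole ratio, so negative actual values do not
#' flip the sign. Undefined when any actual value is zero.
#'
#' @inheritParams rmse
#' @return Nonnegative percentage.
#' @export
mape <- function(actual, predicted) {
  check_pair(actual, predicted)
  if (any(actual == 0)) {
    stop("undefined MAPE: `actual` contains zero", call. = FALSE)
  }
  100 * mean(abs((actual - predicted) / actual))
}

#' Classify a MAPE value into its accuracy band
#'
#' Bands: \eqn{\le 10}\% high accuracy; \eqn{(10, 20]}\% good;
#' \eqn{(20, 50)}\% acceptable; \eqn{\ge 50}\% misleading. The published scale
#' leaves exactly 50\% unassigned (acceptable is printed as an open interval,
#' misleading as strictly above 50); the boundary is assigned to the
#' conservative "misleading" label.
#'
#' @param m Nonnegative MAPE percentage.
#' @return One of \code{"high_accuracy"}, \code{"good"}, \code{"acceptable"},
#'   \code{"misleading"}.
#' @export
classify_mape <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0) {
    stop("classify_mape(): `m` must be a nonnegative scalar", call. = FALSE)
  }
  if (m <= 10) "high_accuracy"
  else if (m <= 20) "good"
  else if (m < 50) "acceptable"
  else "misleading"
}

#' Coefficient of determination, printed-form variant
#'
#' \eqn{R^2 = 1 - \sum_n (a_n - p_n)^2 / \sum_n p_n^2}: the residual sum of
#' squares is scaled by the sum of squared \emph{predictions}, not by the
#' centred sum of squares of the observations. This is the form the source
#' tables print; it saturates near 1 whenever predictions are far from zero
#' relative to the residuals, so it cannot discriminate between good models.
#' Use [r2_conventional()] for model selection; both are reported.
#'
#' @inheritParams rmse
#' @return Scalar \eqn{\le 1}.
#' @export
r2_paper <- function(actual, predicted) {
  check_pair(actual, predicted)
  denom <- sum(predicted^2)
  if (denom == 0) {
    stop("undefined R2: all predictions are zero", call. = FALSE)
  }
  1 - sum((actual - predicted)^2) / denom
}

#' Coefficient of determination, conventional variant
#'
#' \eqn{R^2 = 1 - \sum_n (a_n - p_n)^2 / \sum_n (a_n - \bar a)^2}: fraction of
#' the observed variance explained by the predictions.
#'
#' @inheritParams rmse
#' @return Scalar \eqn{\le 1}; 0 for the mean-only null model.
#' @export
r2_conventional <- function(actual, predicted) {
  check_pair(actual, predicted)
  if (length(actual) < 2L) {
    stop("undefined R2: need at least two observations", call. = FALSE)
  }
  denom <- sum((actual - mean(actual))^2)
  if (denom == 0) {
    stop("undefined R2: `actual` is constant", call. = FALSE)
  }
  1 - sum((actual - predicted)^2) / denom
}

#' All evaluation metrics for one prediction set
#'
#' @inheritParams rmse
#' @return A list of class \code{eval_metrics}: \code{rmse}, \code{mape},
#'   \code{mape_band}, \code{r2_paper}, \code{r2_conventional}, \code{n}.
#' @export
eval_metrics <- function(actual, predicted) {
  m <- mape(actual, predicted)
  structure(
    list(
      rmse = rmse(actual, predicted),
      mape = m,
      mape_band = classify_mape(m),
      r2_paper = r2_paper(actual, predicted),
      r2_conventional = r2_conventional(actual, predicted),
      n = length(actual)
    ),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "RMSE %.4g  MAPE %.3g%% (%s)  R2 %.4f (printed-form %.4f)  n = %d\n",
    x$rmse, x$mape, x$mape_band, x$r2_conventional, x$r2_paper, x$n))
  invisible(x)
}

check_pair <- function(actual, predicted) {
  if (!is.numeric(actual) || !is.numeric(predicted)) {
    stop("metric inputs must be numeric", call. = FALSE)
  }
  if (length(actual) != length(predicted)) {
    stop("metric inputs must have equal length (", length(actual), " vs ",
         length(predicted), ")", call. = FALSE)
  }
  if (length(actual) == 0L) {
    stop("metric inputs must be nonempty", call. = FALSE)
  }
  if (anyNA(actual) || anyNA(predicted) ||
      any(!is.finite(actual)) || any(!is.finite(predicted))) {
    stop("metric inputs must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
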