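#' Goodness-of-fit criteria
#'
#' The calibration criterion and the two fit metrics used throughout:
#' `sse()` is the sum of squared differences minimized by the optimizer;
#' `rmse()` is sqrt(SSE / n); `rrmse()` is RMSE divided by the mean of the
#' observations (dimensionless).
#'
#' @param observed,predicted Numeric series of equal length (n >= 1).
#' @return `sse()` in squared units of the series, `rmse()` in the series
#'   units, `rrmse()` dimensionless.
#' @examples
#' rmse(c(10, 20, 30), c(12, 18, 33))
#' rrmse(c(10, 20, 30), c(12, 18, 33))
#' @export
sse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length", call. = FALSE)
  if (length(observed) < 1L) stop("need at least one pair", call. = FALSE)
  sum((observed - predicted)^2)
}

#' @rdname sse
#' @export
rmse <- function(observed, predicted) {
  sqrt(sse(observed, predicted) / length(observed))
}

#' @rdname sse
#' @export
rrmse <- function(observed, predicted) {
  xbar <- mean(observed)
  if (!is.finite(xbar) || xbar <= 0)
    stop("rrmse requires a positive mean of the observations", call. = FALSE)
  rmse(observed, predicted) / xbar
}
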