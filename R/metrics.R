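# Performance indices for surrogate evaluation.

#' Regression performance indices: R-squared, RMSE, MBE
#'
#' Computes the three indices used throughout the package to score
#' surrogate predictions:
#' \deqn{R^2 = 1 - \sum (y_i - \hat y_i)^2 / \sum (y_i - \bar y)^2}
#' \deqn{RMSE = \sqrt{\sum (y_i - \hat y_i)^2 / n}}
#' \deqn{MBE = (1/n) \sum (\hat y_i - y_i)}
#' MBE is signed predicted-minus-observed: positive means the model
#' overpredicts on average, and \eqn{|MBE| \le RMSE} always.
#'
#' @param observed Numeric vector of observations (length >= 2). A constant
#'   observed vector leaves R-squared undefined: \code{r2} is \code{NA}
#'   with a warning while RMSE and MBE are still returned.
#' @param predicted Numeric vector of predictions, same length.
#' @return A \code{metric_set} list: \code{r2}, \code{rmse}, \code{mbe},
#'   \code{n}.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 2, 2))  # R2 = 0 when predicting the mean
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length")
  }
  if (length(observed) < 2) stop("need at least 2 observations")
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop("non-finite values in observed or predicted")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) warning("constant observed vector: R2 undefined (NA)")
  sse <- sum((observed - predicted)^2)
  structure(list(r2 = if (sst == 0) NA_real_ else 1 - sse / sst,
                 rmse = sqrt(sse / length(observed)),
                 mbe = mean(predicted - observed),
                 n = length(observed)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("R2 = %.4f  RMSE = %.4g  MBE = %.4g  (n = %d)\n",
              x$r2, x$rmse, x$mbe, x$n))
  invisible(x)
}
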