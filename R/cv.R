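# Repeated cross-validation scoring of a surrogate family.

family_fitters <- function() {
  list(grnn = function(X, y, hp) {
    do.call(fit_grnn, c(list(X = X, y = y), hp))
  },
  mlp = function(X, y, hp) {
    do.call(fit_mlp, c(list(X = X, y = y), hp))
  },
  anfis = function(X, y, hp) {
    do.call(fit_anfis, c(list(X = X, y = y), hp))
  })
}

#' Cross-validate a surrogate family
#'
#' For every (train, test) pair of the fold plan: fits the family on the
#' training partition only (input scaler and target Box-Cox are refit on
#' the training data, so no information leaks from the test partition),
#' predicts both partitions in original units, and scores R-squared, RMSE
#' and MBE. Folds whose fit fails are recorded and skipped with a warning.
#'
#' @param family \code{"grnn"}, \code{"mlp"} or \code{"anfis"}.
#' @param X,y Full dataset.
#' @param fold_plan A \code{\link{make_folds}} plan for \code{nrow(X)}.
#' @param hyperparams Named list passed to the family's fitting function
#'   (e.g. \code{list(sigma = 0.2)} for GRNN).
#' @return A \code{cv_report}: data frame with one row per fold pair and
#'   partition, columns \code{family, pair_id, repeat_id, fold, partition,
#'   r2, rmse, mbe, n}. \code{summary()} gives per-partition means.
#' @export
evaluate_cv <- function(family = c("grnn", "mlp", "anfis"), X, y, fold_plan,
                        hyperparams = list()) {
  family <- match.arg(family)
  X <- as.matrix(X)
  stopifnot(max(unlist(lapply(fold_plan$pairs, `[[`, "test"))) <= nrow(X))
  fitter <- family_fitters()[[family]]
  rows <- list()
  failed <- 0
  for (i in seq_along(fold_plan$pairs)) {
    p <- fold_plan$pairs[[i]]
    m <- tryCatch(
      fitter(X[p$train, , drop = FALSE], y[p$train], hyperparams),
      error = function(e) e)
    if (inherits(m, "error")) {
      failed <- failed + 1
      next
    }
    for (part in c("train", "test")) {
      idx <- p[[part]]
      met <- compute_metrics(y[idx], predict(m, X[idx, , drop = FALSE]))
      rows[[length(rows) + 1]] <- data.frame(
        family = family, pair_id = i, repeat_id = p$repeat_id,
        fold = p$fold, partition = part, r2 = met$r2, rmse = met$rmse,
        mbe = met$mbe, n = met$n)
    }
  }
  if (failed > 0) {
    warning(failed, " of ", length(fold_plan$pairs),
            " fold fits failed and were skipped")
  }
  if (length(rows) == 0) stop("every fold fit failed; nothing to report")
  out <- do.call(rbind, rows)
  class(out) <- c("cv_report", "data.frame")
  out
}

#' @export
summary.cv_report <- function(object, ...) {
  df <- as.data.frame(object)
  agg <- stats::aggregate(df[, c("r2", "rmse", "mbe")],
                          by = df[, c("family", "partition")], FUN = mean)
  agg$n_pairs <- stats::aggregate(df$r2, by = df[, c("family", "partition")],
                                  FUN = length)$x
  agg
}
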