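# Generalized regression neural network: Nadaraya-Watson kernel-weighted
# average of the stored training targets,
#   yhat(x) = sum_i y_i exp(-D_i^2 / 2 sigma^2) / sum_i exp(-D_i^2 / 2 sigma^2),
#   D_i^2 = (x - x_i)' (x - x_i)  on min-max scaled inputs.
# Training is storage only; the single width parameter sigma controls the
# bias-variance trade-off.

#' Fit a generalized regression neural network surrogate
#'
#' Stores the scaled training inputs and (optionally Box-Cox transformed)
#' targets; prediction is a Gaussian-kernel weighted average of the stored
#' targets, so every prediction is a convex combination of training targets
#' and is bounded by their range. As \code{sigma -> 0} the model
#' interpolates (nearest-neighbour limit); as \code{sigma -> Inf} it
#' predicts the target mean everywhere.
#'
#' @param X Numeric matrix of inputs (one row per observation).
#' @param y Numeric target vector.
#' @param sigma Positive kernel width on the scaled-input distance scale.
#' @param transform_y Box-Cox-normalize the target before storage (default
#'   TRUE; the monotone back-transform preserves the convexity bound).
#' @param bounds Optional 2 x d bounds matrix used by the input scaler;
#'   default the data range.
#' @param trait Optional trait label carried in the object.
#' @return A \code{grnn_surrogate} (also \code{growth_surrogate}).
#' @examples
#' m <- fit_grnn(matrix(c(0, 1)), c(0, 1), sigma = 1, transform_y = FALSE)
#' predict(m, matrix(0.5))  # symmetry: 0.5
#' @export
fit_grnn <- function(X, y, sigma, transform_y = TRUE, bounds = NULL,
                     trait = NA_character_) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive number")
  }
  prep <- prepare_training(X, y, transform_y, bounds)
  fit <- list(Xs = prep$Xs, z = prep$z, sigma = sigma)
  new_surrogate("grnn", fit, prep$scaler, prep$boxcox, as.matrix(X), y,
                trait)
}

grnn_forward <- function(fit, Xs) {
  # squared Euclidean distances query x training, fully vectorized
  D2 <- outer(rowSums(Xs^2), rowSums(fit$Xs^2), "+") -
    2 * Xs %*% t(fit$Xs)
  D2[D2 < 0] <- 0
  L <- -D2 / (2 * fit$sigma^2)
  # subtract the row max before exponentiating: keeps weights finite for
  # tiny sigma, and yields the nearest-neighbour limit as sigma -> 0
  L <- L - apply(L, 1, max)
  W <- exp(L)
  as.numeric((W %*% fit$z) / rowSums(W))
}

#' Select the GRNN width by cross-validation
#'
#' Evaluates each candidate width over the fold plan and returns the one
#' minimizing mean test RMSE (ties broken toward the smaller width, i.e.
#' the less smoothed model).
#'
#' @param X,y Training data.
#' @param fold_plan A \code{\link{make_folds}} plan for \code{nrow(X)}.
#' @param grid Candidate widths on the scaled-input distance scale; default
#'   20 log-spaced values in [0.02, 2].
#' @param transform_y,bounds Passed to \code{\link{fit_grnn}}.
#' @return The selected width, with the per-candidate mean CV RMSE attached
#'   as attribute \code{"cv"}.
#' @export
select_sigma <- function(X, y, fold_plan, grid = NULL, transform_y = TRUE,
                         bounds = NULL) {
  if (is.null(grid)) grid <- exp(seq(log(0.02), log(2), length.out = 20))
  if (length(grid) == 0) stop("empty sigma grid")
  grid <- sort(grid)
  X <- as.matrix(X)
  rmse <- vapply(grid, function(s) {
    errs <- vapply(fold_plan$pairs, function(p) {
      m <- fit_grnn(X[p$train, , drop = FALSE], y[p$train], sigma = s,
                    transform_y = transform_y, bounds = bounds)
      pred <- predict(m, X[p$test, , drop = FALSE])
      sqrt(mean((y[p$test] - pred)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- grid[which.min(rmse)]
  attr(best, "cv") <- data.frame(sigma = grid, rmse = rmse)
  best
}
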