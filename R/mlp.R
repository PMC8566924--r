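# Single-hidden-layer perceptron: tanh hidden units, linear output,
#   yhat = w0 + sum_j w_j tanh(sum_i W_ji x_i + b_j),
# trained by Levenberg-Marquardt (damped Gauss-Newton) on the
# sum-of-squares loss. The target is internally z-standardized (after the
# optional Box-Cox) so the damping scale is problem-independent.

#' Fit a multilayer-perceptron surrogate
#'
#' One hidden layer of \code{hidden_size} hyperbolic-tangent units and a
#' linear output, trained by Levenberg-Marquardt: at each iteration the
#' update solves \eqn{(J'J + \mu I)\delta = J'r} with the damping factor
#' \eqn{\mu} multiplied by 10 on a rejected step and divided by 10 on an
#' accepted one (initial 1e-3). Training stops at \code{max_iter}
#' iterations, when the gradient infinity-norm falls below \code{grad_tol},
#' or when \eqn{\mu} exceeds 1e10. Weight initialization is seeded, so the
#' same seed and configuration reproduce identical weights.
#'
#' @param X Numeric input matrix.
#' @param y Numeric target vector.
#' @param hidden_size Number of hidden units (>= 1).
#' @param seed Integer seed for weight initialization.
#' @param max_iter Maximum LM iterations (default 200).
#' @param grad_tol Gradient infinity-norm stopping tolerance (default 1e-8).
#' @param transform_y Box-Cox-normalize the target first (default TRUE).
#' @param bounds Optional input-scaler bounds.
#' @param trait Optional trait label.
#' @return An \code{mlp_surrogate} (also \code{growth_surrogate}); element
#'   \code{fit} holds the weights, the per-iteration loss \code{history}
#'   and the number of iterations.
#' @export
fit_mlp <- function(X, y, hidden_size, seed = 1, max_iter = 200,
                    grad_tol = 1e-8, transform_y = TRUE, bounds = NULL,
                    trait = NA_character_) {
  if (!is.numeric(hidden_size) || hidden_size < 1 ||
      hidden_size != round(hidden_size)) {
    stop("hidden_size must be a positive integer")
  }
  prep <- prepare_training(X, y, transform_y, bounds)
  zc <- mean(prep$z); zs <- stats::sd(prep$z)
  if (zs == 0) zs <- 1
  t <- (prep$z - zc) / zs
  d <- ncol(prep$Xs); p <- hidden_size
  rng <- local_rng(seed)
  theta <- 0.5 * (rng$runif(p * (d + 1) + p + 1) * 2 - 1)
  res <- lm_train(prep$Xs, t, p, theta, max_iter, grad_tol)
  fit <- c(unpack_mlp(res$theta, d, p),
           list(hidden_size = p, z_center = zc, z_scale = zs,
                history = res$history, iterations = res$iterations,
                seed = seed))
  new_surrogate("mlp", fit, prep$scaler, prep$boxcox, as.matrix(X), y, trait)
}

unpack_mlp <- function(theta, d, p) {
  W1 <- matrix(theta[seq_len(p * d)], nrow = p)
  b1 <- theta[p * d + seq_len(p)]
  w2 <- theta[p * d + p + seq_len(p + 1)]  # p hidden-output weights + bias
  list(W1 = W1, b1 = b1, w2 = w2)
}

mlp_forward_raw <- function(W1, b1, w2, Xs) {
  A <- tanh(sweep(Xs %*% t(W1), 2, b1, "+"))  # n x p activations
  as.numeric(A %*% w2[seq_len(ncol(A))] + w2[length(w2)])
}

mlp_forward <- function(fit, Xs) {
  mlp_forward_raw(fit$W1, fit$b1, fit$w2, Xs) * fit$z_scale + fit$z_center
}

# Jacobian of the forward pass wrt the packed parameter vector.
mlp_jacobian <- function(theta, Xs, d, p) {
  par <- unpack_mlp(theta, d, p)
  Z <- sweep(Xs %*% t(par$W1), 2, par$b1, "+")
  A <- tanh(Z)
  dA <- (1 - A^2) * matrix(par$w2[seq_len(p)], nrow(Xs), p, byrow = TRUE)
  n <- nrow(Xs)
  J <- matrix(0, n, length(theta))
  for (j in seq_len(p)) {                      # d f / d W1[j, ] and b1[j]
    J[, (seq_len(d) - 1) * p + j] <- dA[, j] * Xs
    J[, p * d + j] <- dA[, j]
  }
  J[, p * d + p + seq_len(p)] <- A             # d f / d w2
  J[, p * d + 2 * p + 1] <- 1                  # d f / d output bias
  list(J = J, f = as.numeric(A %*% par$w2[seq_len(p)] + par$w2[p + 1]))
}

lm_train <- function(Xs, t, p, theta, max_iter, grad_tol) {
  d <- ncol(Xs)
  mu <- 1e-3
  jb <- mlp_jacobian(theta, Xs, d, p)
  r <- t - jb$f
  sse <- sum(r^2)
  history <- sse
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    g <- crossprod(jb$J, r)
    if (max(abs(g)) < grad_tol) break
    H <- crossprod(jb$J)
    accepted <- FALSE
    while (!accepted && mu <= 1e10) {
      delta <- tryCatch(
        solve(H + mu * diag(nrow(H)), g),
        error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        jb_new <- mlp_jacobian(cand, Xs, d, p)
        sse_new <- sum((t - jb_new$f)^2)
        if (!is.finite(sse_new)) {
          stop("divergence: non-finite loss at iteration ", iter)
        }
        if (sse_new < sse) {
          theta <- cand; jb <- jb_new
          r <- t - jb$f; sse <- sse_new
          mu <- mu / 10
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * 10
    }
    history <- c(history, sse)
    if (!accepted) break  # damping saturated: converged to numerical limit
  }
  list(theta = theta, history = history, iterations = iter)
}

#' Select the MLP hidden-layer size by cross-validation
#'
#' Fits every candidate size on every fold pair and returns the size with
#' the highest mean CV test R-squared (ties broken toward the smaller,
#' simpler network).
#'
#' @param X,y Training data.
#' @param fold_plan A \code{\link{make_folds}} plan.
#' @param candidates Candidate hidden sizes, a subset of 1..20 (default
#'   \code{c(2, 4, 8, 12)}).
#' @param seed,max_iter,transform_y,bounds Passed to \code{\link{fit_mlp}}.
#' @return The selected size, with per-candidate mean CV test R-squared as
#'   attribute \code{"cv"}.
#' @export
select_hidden_size <- function(X, y, fold_plan, candidates = c(2, 4, 8, 12),
                               seed = 1, max_iter = 100, transform_y = TRUE,
                               bounds = NULL) {
  if (length(candidates) == 0) stop("no candidate sizes")
  if (any(candidates < 1 | candidates > 20)) {
    stop("candidate sizes must lie in 1..20")
  }
  candidates <- sort(candidates)
  X <- as.matrix(X)
  r2 <- vapply(candidates, function(p) {
    vals <- vapply(fold_plan$pairs, function(fp) {
      m <- tryCatch(
        fit_mlp(X[fp$train, , drop = FALSE], y[fp$train], hidden_size = p,
                seed = seed, max_iter = max_iter, transform_y = transform_y,
                bounds = bounds),
        error = function(e) NULL)
      if (is.null(m)) return(NA_real_)
      compute_metrics(y[fp$test], predict(m, X[fp$test, , drop = FALSE]))$r2
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  best <- candidates[which.max(r2)]
  attr(best, "cv") <- data.frame(hidden_size = candidates, test_r2 = r2)
  best
}
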