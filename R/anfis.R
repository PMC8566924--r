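# First-order Takagi-Sugeno neuro-fuzzy system (ANFIS) on a grid partition:
# per-input Gaussian membership functions mu(x) = exp[-((x - c)/a)^2]
# (width in the denominator without the conventional factor 2 -- see
# `conventional_mf`), one rule per combination of membership functions,
# normalized firing strengths, and linear consequents f_r = p_r . x + r_r.
# Hybrid learning: ridge-regularized least squares for the consequents
# given the premises, then a gradient step on the premise (a, c) parameters,
# per epoch.

#' Fit an adaptive neuro-fuzzy inference system surrogate
#'
#' Grid-partition Takagi-Sugeno ANFIS with Gaussian memberships. The rule
#' base enumerates every combination of the per-input membership functions
#' (\code{mf_per_input ^ n_inputs} rules), so the rule count explodes
#' quickly: with 5 inputs and 3 MFs there are already 243 rules against 66
#' observations. The consequent least-squares step is therefore
#' ridge-regularized (solved in its dual form when the parameter count
#' exceeds n), and fits beyond \code{rule_cap} rules are refused with an
#' error advising fewer membership functions.
#'
#' @param X Numeric input matrix.
#' @param y Numeric target vector.
#' @param mf_per_input Gaussian membership functions per input, 3..5
#'   (scalar or per-input vector).
#' @param epochs Hybrid-learning epochs (default 10).
#' @param seed Integer seed (premise initialization is deterministic; the
#'   seed is kept for provenance).
#' @param penalty Ridge penalty of the consequent least squares
#'   (default 1e-6, the weak regularization of a standard recursive
#'   least-squares initialization).
#' @param learn_rate Gradient-descent step for the premise parameters
#'   (default 0.01 on the scaled-input scale).
#' @param rule_cap Maximum admissible rule count (default 500).
#' @param conventional_mf Use \eqn{\exp(-(x-c)^2 / 2a^2)} instead of the
#'   default \eqn{\exp(-((x-c)/a)^2)} (default FALSE).
#' @param transform_y Box-Cox-normalize the target first (default TRUE).
#' @param bounds Optional input-scaler bounds.
#' @param trait Optional trait label.
#' @return An \code{anfis_surrogate} (also \code{growth_surrogate}).
#' @export
fit_anfis <- function(X, y, mf_per_input = 3, epochs = 10, seed = 1,
                      penalty = 1e-6, learn_rate = 0.01, rule_cap = 500,
                      conventional_mf = FALSE, transform_y = TRUE,
                      bounds = NULL, trait = NA_character_) {
  prep <- prepare_training(X, y, transform_y, bounds)
  Xs <- prep$Xs
  d <- ncol(Xs)
  mf <- rep(mf_per_input, length.out = d)
  if (any(mf < 2 | mf != round(mf))) {
    stop("mf_per_input must be integer(s) >= 2")
  }
  n_rules <- prod(mf)
  if (n_rules > rule_cap) {
    stop("rule explosion: ", n_rules, " rules exceed the cap of ", rule_cap,
         "; use fewer membership functions per input or raise 'rule_cap'")
  }
  # premise initialization: centers spread evenly over [0,1], widths set so
  # neighbouring memberships overlap at ~0.5
  centers <- lapply(mf, function(m) seq(0, 1, length.out = m))
  widths <- lapply(mf, function(m) rep(1 / (m - 1) * 0.85, m))
  rules <- as.matrix(expand.grid(lapply(mf, seq_len)))
  colnames(rules) <- colnames(Xs)
  zc <- mean(prep$z); zs <- stats::sd(prep$z)
  if (zs == 0) zs <- 1
  t <- (prep$z - zc) / zs
  fit <- list(mf_per_input = mf, centers = centers, widths = widths,
              rules = rules, theta = numeric(n_rules * (d + 1)),
              conventional = conventional_mf, z_center = zc, z_scale = zs,
              epochs = epochs, seed = seed)
  for (e in seq_len(epochs)) {
    fit$theta <- anfis_solve_consequents(fit, Xs, t, penalty)
    if (e < epochs) {
      fit <- anfis_premise_step(fit, Xs, t, learn_rate)
    }
  }
  new_surrogate("anfis", fit, prep$scaler, prep$boxcox, as.matrix(X), y,
                trait)
}

# Gaussian membership grade; equals 1 exactly at its own center.
anfis_mf <- function(x, c, a, conventional) {
  if (conventional) exp(-((x - c)^2) / (2 * a^2)) else exp(-((x - c) / a)^2)
}

# Normalized firing strengths for each query row: n x R matrix with rows
# summing to 1.
anfis_firing <- function(fit, Xs) {
  n <- nrow(Xs)
  W <- matrix(1, n, nrow(fit$rules))
  for (j in seq_len(ncol(Xs))) {
    M <- vapply(seq_len(fit$mf_per_input[j]), function(k) {
      anfis_mf(Xs[, j], fit$centers[[j]][k], fit$widths[[j]][k],
               fit$conventional)
    }, numeric(n))
    M <- matrix(M, nrow = n)
    W <- W * M[, fit$rules[, j], drop = FALSE]
  }
  s <- rowSums(W)
  s[s == 0] <- 1  # no rule fires (cannot happen with Gaussian MFs)
  W / s
}

# Consequent design matrix: column block r holds wbar_r * [x, 1].
anfis_design <- function(fit, Xs) {
  Wb <- anfis_firing(fit, Xs)
  d <- ncol(Xs)
  R <- nrow(fit$rules)
  Phi <- matrix(0, nrow(Xs), R * (d + 1))
  A <- cbind(Xs, 1)
  for (r in seq_len(R)) {
    Phi[, (r - 1) * (d + 1) + seq_len(d + 1)] <- Wb[, r] * A
  }
  Phi
}

anfis_solve_consequents <- function(fit, Xs, t, penalty) {
  Phi <- anfis_design(fit, Xs)
  n <- nrow(Phi); p <- ncol(Phi)
  if (p > n) {
    # dual (kernel) ridge: theta = Phi' (Phi Phi' + lambda I)^-1 t
    K <- tcrossprod(Phi)
    as.numeric(crossprod(Phi, solve(K + penalty * diag(n), t)))
  } else {
    as.numeric(solve(crossprod(Phi) + penalty * diag(p), crossprod(Phi, t)))
  }
}

anfis_predict_std <- function(fit, Xs) {
  as.numeric(anfis_design(fit, Xs) %*% fit$theta)
}

anfis_forward <- function(fit, Xs) {
  anfis_predict_std(fit, Xs) * fit$z_scale + fit$z_center
}

# One numerical-gradient descent step on the premise (center, width)
# parameters with the consequents held fixed.
anfis_premise_step <- function(fit, Xs, t, learn_rate) {
  err <- function(f) mean((t - anfis_predict_std(f, Xs))^2)
  h <- 1e-4
  base <- err(fit)
  out <- fit
  for (j in seq_len(ncol(Xs))) {
    for (k in seq_len(fit$mf_per_input[j])) {
      for (field in c("centers", "widths")) {
        f2 <- fit
        f2[[field]][[j]][k] <- f2[[field]][[j]][k] + h
        g <- (err(f2) - base) / h
        new_val <- fit[[field]][[j]][k] - learn_rate * g
        if (field == "widths") new_val <- max(new_val, 0.02)
        out[[field]][[j]][k] <- new_val
      }
    }
  }
  out
}
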