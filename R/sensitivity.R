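# Variable-sensitivity-ratio (VSR) input-importance ranking.
#
# VSE for input j is the RMSE of the model's predictions after input j is
# "removed" by replacing its column with the training mean (no refit);
# VSR(j) = VSE(j) / RMSE_full. A model that ignores input j has VSR(j) = 1;
# the more a model relies on an input, the larger its VSR.

#' Variable sensitivity ratio of one input
#'
#' @param model A fitted \code{growth_surrogate}.
#' @param X,y The data the model was fitted on.
#' @param input Input index (or name matching \code{colnames(X)}).
#' @param rmse_full Optional externally supplied full-model RMSE. For
#'   near-interpolating models (GRNN at small width) the resubstitution
#'   RMSE approaches zero and the ratio degenerates; pass a
#'   cross-validation RMSE instead (as \code{\link{rank_inputs}} does).
#' @param refit Remove the input by refitting the family without the
#'   column instead of mean-substitution (GRNN only; default FALSE).
#' @return The VSR, a positive scalar.
#' @export
compute_vsr <- function(model, X, y, input, rmse_full = NULL,
                        refit = FALSE) {
  stopifnot(inherits(model, "growth_surrogate"))
  X <- as.matrix(X)
  j <- if (is.character(input)) match(input, colnames(X)) else input
  if (is.na(j) || j < 1 || j > ncol(X)) stop("unknown input: ", input)
  if (is.null(rmse_full)) {
    rmse_full <- sqrt(mean((y - predict(model, X))^2))
  }
  if (rmse_full <= .Machine$double.eps^0.5 * max(1, stats::sd(y))) {
    stop("full-model RMSE is ~0 (interpolating model); supply a ",
         "cross-validation RMSE via 'rmse_full'")
  }
  if (refit) {
    if (model$family != "grnn") stop("refit removal implemented for GRNN only")
    m2 <- fit_grnn(X[, -j, drop = FALSE], y, sigma = model$fit$sigma,
                   transform_y = !is.null(model$boxcox))
    pred <- predict(m2, X[, -j, drop = FALSE])
  } else {
    X2 <- X
    X2[, j] <- mean(X[, j])
    pred <- predict(model, X2)
  }
  vse <- sqrt(mean((y - pred)^2))
  vse / rmse_full
}

#' Rank the inputs of a fitted surrogate by VSR
#'
#' Computes the VSR of every input and assigns descending ranks (rank 1 =
#' largest VSR = most important). Ties are broken by the fixed input order.
#' By default the denominator RMSE is estimated by cross-validation so that
#' interpolating models get a meaningful (non-degenerate) ratio.
#'
#' @param model A fitted \code{growth_surrogate}.
#' @param X,y The data the model was fitted on.
#' @param rmse_full Full-model RMSE; default a 5-fold CV estimate obtained
#'   by refitting the model's family at its stored hyperparameters.
#' @param cv_seed Seed of the default CV estimate.
#' @return A \code{sensitivity_report}: data frame with columns
#'   \code{input}, \code{vsr}, \code{rank}.
#' @export
rank_inputs <- function(model, X, y, rmse_full = NULL, cv_seed = 11) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(rmse_full)) {
    rmse_full <- cv_rmse_for(model, X, y, cv_seed)
  }
  vsr <- vapply(seq_len(ncol(X)), function(j) {
    compute_vsr(model, X, y, j, rmse_full = rmse_full)
  }, numeric(1))
  rank <- integer(length(vsr))
  rank[order(-vsr, seq_along(vsr))] <- seq_along(vsr)
  out <- data.frame(input = colnames(X), vsr = vsr, rank = rank)
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

# CV RMSE of the model's family at its stored hyperparameters.
cv_rmse_for <- function(model, X, y, seed) {
  hp <- switch(model$family,
               grnn = list(sigma = model$fit$sigma),
               mlp = list(hidden_size = model$fit$hidden_size,
                          seed = model$fit$seed),
               anfis = list(mf_per_input = model$fit$mf_per_input[1],
                            epochs = model$fit$epochs,
                            seed = model$fit$seed))
  hp$transform_y <- !is.null(model$boxcox)
  plan <- make_folds(nrow(X), k = 5, repeats = 1, seed = seed)
  rep <- evaluate_cv(model$family, X, y, plan, hp)
  mean(rep$rmse[rep$partition == "test"])
}

#' Replicate-level sensitivity ranking
#'
#' The experiment records only treatment-level means and SEs, but the
#' growth models of interest were developed on individual plantlet
#' measurements. This function reconstructs plantlet-level datasets with
#' \code{\link{pseudo_replicates}}, fits a GRNN per trait (width selected
#' by cross-validation), computes mean-substitution VSRs against a CV RMSE
#' denominator, and averages the VSRs over \code{n_draws} independent
#' reconstructions to suppress the Monte-Carlo noise of any single draw.
#'
#' @param dataset A \code{growth_dataset}.
#' @param traits Traits to rank (default all five).
#' @param n_draws Pseudo-replicate reconstructions averaged (default 5).
#' @param seed Base seed; draw r uses \code{seed + r}.
#' @param cv_k,cv_repeats,cv_seed Fold plan used for width selection and
#'   the RMSE denominator.
#' @return A data frame with one row per trait x input: \code{trait},
#'   \code{input}, \code{vsr} (ensemble mean), \code{rank}.
#' @export
replicate_sensitivity <- function(dataset, traits = growth_traits(),
                                  n_draws = 5, seed = 1, cv_k = 5,
                                  cv_repeats = 2, cv_seed = 101) {
  dataset <- validate_growth_dataset(as.data.frame(dataset))
  out <- list()
  for (tr in traits) {
    V <- rowMeans(vapply(seq_len(n_draws), function(r) {
      pr <- pseudo_replicates(dataset, seed = seed + r)
      X <- as.matrix(pr[, growth_inputs()])
      y <- pr[[tr]]
      plan <- make_folds(nrow(pr), k = cv_k, repeats = cv_repeats,
                         seed = cv_seed)
      s <- as.numeric(select_sigma(X, y, plan, bounds = input_bounds()))
      g <- fit_grnn(X, y, sigma = s, bounds = input_bounds(), trait = tr)
      cvr <- evaluate_cv("grnn", X, y, plan,
                         list(sigma = s, bounds = input_bounds()))
      rmse_cv <- mean(cvr$rmse[cvr$partition == "test"])
      vapply(seq_len(ncol(X)), function(j) {
        compute_vsr(g, X, y, j, rmse_full = rmse_cv)
      }, numeric(1))
    }, numeric(length(growth_inputs()))))
    rank <- integer(length(V))
    rank[order(-V, seq_along(V))] <- seq_along(V)
    out[[tr]] <- data.frame(trait = tr, input = growth_inputs(), vsr = V,
                            rank = rank)
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}
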