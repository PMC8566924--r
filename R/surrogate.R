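# Common surrogate-model contract: every family is fitted on min-max scaled
# inputs and an optionally Box-Cox-normalized target, and predicts in the
# trait's original units by inverting the transform chain.

new_surrogate <- function(family, fit, scaler, boxcox, X, y, trait = NA_character_) {
  structure(list(family = family, fit = fit, scaler = scaler,
                 boxcox = boxcox, X = X, y = y, trait = trait),
            class = c(paste0(family, "_surrogate"), "growth_surrogate"))
}

prepare_training <- function(X, y, transform_y, bounds) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  scaler <- minmax_fit(X, bounds)
  bc <- if (isTRUE(transform_y)) boxcox_fit(y) else NULL
  z <- if (is.null(bc)) y else boxcox_apply(bc, y)
  list(scaler = scaler, boxcox = bc, Xs = minmax_apply(scaler, X), z = z)
}

#' Predict growth responses from a fitted surrogate
#'
#' Applies the stored input scaler, evaluates the family-specific forward
#' pass, and back-transforms predictions to the trait's original units.
#'
#' @param object A fitted \code{growth_surrogate}.
#' @param newdata Numeric matrix of query points (one row per point,
#'   columns in training-input order) or a single numeric vector.
#' @param ... Unused.
#' @return Numeric vector of predictions in original trait units.
#' @export
predict.growth_surrogate <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(X) != length(object$scaler$lower)) {
    stop("dimension mismatch: model expects ", length(object$scaler$lower),
         " inputs, got ", ncol(X))
  }
  Xs <- minmax_apply(object$scaler, X)
  z <- surrogate_forward(object, Xs)
  if (is.null(object$boxcox)) return(z)
  # Guard the back-transform: for lambda < 0 the transform's image is
  # bounded above and the inverse explodes near the boundary, so
  # transformed-scale predictions are clamped to the training-target range
  # padded by 10% (an explicit extrapolation limit) before inversion.
  zr <- range(boxcox_apply(object$boxcox, object$y))
  pad <- 0.1 * diff(zr)
  if (pad == 0) pad <- 0.1 * max(abs(zr), 1)
  lo <- zr[1] - pad; hi <- zr[2] + pad
  lam <- object$boxcox$lambda
  if (abs(lam) >= 1e-8) {
    # stay strictly inside the transform's image: lambda * z + 1 > 0
    edge <- -1 / lam
    if (lam > 0) lo <- max(lo, edge + 1e-8 * max(1, abs(edge)))
    else hi <- min(hi, edge - 1e-8 * max(1, abs(edge)))
  }
  z <- pmin(pmax(z, lo), hi)
  boxcox_invert(object$boxcox, z)
}

# Forward pass on scaled inputs, transformed-target scale.
surrogate_forward <- function(object, Xs) {
  switch(object$family,
         grnn = grnn_forward(object$fit, Xs),
         mlp = mlp_forward(object$fit, Xs),
         anfis = anfis_forward(object$fit, Xs),
         stop("unknown surrogate family '", object$family, "'"))
}

#' @export
print.growth_surrogate <- function(x, ...) {
  cat("Growth surrogate (", x$family, "), ", nrow(x$X), " training points, ",
      ncol(x$X), " inputs", sep = "")
  if (!is.na(x$trait)) cat(", trait: ", x$trait, sep = "")
  cat("\n")
  if (!is.null(x$boxcox)) {
    cat("  target Box-Cox: lambda =", signif(x$boxcox$lambda, 4),
        " shift =", signif(x$boxcox$shift, 4), "\n")
  }
  hp <- switch(x$family,
               grnn = paste0("sigma = ", signif(x$fit$sigma, 4)),
               mlp = paste0("hidden units = ", x$fit$hidden_size),
               anfis = paste0(x$fit$mf_per_input, " MFs/input, ",
                              nrow(x$fit$rules), " rules"))
  cat("  ", hp, "\n", sep = "")
  invisible(x)
}

#' @export
summary.growth_surrogate <- function(object, ...) {
  m <- compute_metrics(object$y, predict(object, object$X))
  cat("Training-set fit (resubstitution):\n")
  print(m)
  invisible(m)
}

#' @export
residuals.growth_surrogate <- function(object, ...) {
  object$y - predict(object, object$X)
}

#' Serialize a surrogate model to JSON and back
#'
#' Writes a versioned JSON container holding the family tag,
#' hyperparameters, weights/centers and transform parameters, sufficient to
#' reconstruct the model exactly.
#'
#' @param model A \code{growth_surrogate}.
#' @param path File path.
#' @return \code{write_surrogate} returns \code{path} invisibly;
#'   \code{read_surrogate} returns the reconstructed model.
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "growth_surrogate"))
  payload <- list(container = "cultivopt-surrogate", version = 1L,
                  family = model$family, trait = model$trait,
                  scaler = model$scaler[c("lower", "upper")],
                  boxcox = if (!is.null(model$boxcox)) {
                    model$boxcox[c("lambda", "shift")]
                  },
                  fit = serialize_fit(model$fit, model$family),
                  X = model$X, y = model$y)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$container, "cultivopt-surrogate")) {
    stop("not a cultivopt surrogate container: ", path)
  }
  scaler <- structure(list(lower = as.numeric(p$scaler$lower),
                           upper = as.numeric(p$scaler$upper)),
                      class = "minmax_scaler")
  bc <- if (!is.null(p$boxcox)) {
    structure(list(lambda = p$boxcox$lambda, shift = p$boxcox$shift),
              class = "boxcox_transform")
  }
  fit <- deserialize_fit(p$fit, p$family)
  trait <- if (is.null(p$trait)) NA_character_ else p$trait
  new_surrogate(p$family, fit, scaler, bc, as.matrix(p$X),
                as.numeric(p$y), trait)
}

serialize_fit <- function(fit, family) {
  if (family == "anfis") {
    fit$rules <- unclass(fit$rules)
    # flatten the per-input membership parameters; the per-input counts in
    # mf_per_input let the reader rebuild the ragged structure
    fit$centers <- unlist(fit$centers)
    fit$widths <- unlist(fit$widths)
  }
  fit
}

deserialize_fit <- function(fit, family) {
  if (family == "grnn") {
    fit$Xs <- as.matrix(fit$Xs); fit$z <- as.numeric(fit$z)
  } else if (family == "mlp") {
    fit$W1 <- as.matrix(fit$W1); fit$b1 <- as.numeric(fit$b1)
    fit$w2 <- as.numeric(fit$w2)
  } else if (family == "anfis") {
    fit$rules <- as.matrix(fit$rules)
    mf <- as.integer(fit$mf_per_input)
    grp <- rep(seq_along(mf), mf)
    fit$centers <- unname(split(as.numeric(unlist(fit$centers)), grp))
    fit$widths <- unname(split(as.numeric(unlist(fit$widths)), grp))
    fit$mf_per_input <- mf
    fit$theta <- as.numeric(fit$theta)
  }
  fit
}
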