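# Target normalization, input scaling, outlier screening and
# cross-validation fold plans.

#' Fit a Box-Cox transform to a target variable
#'
#' Growth targets are right-skewed (SEs grow with means), so targets are
#' normalized by a one-parameter Box-Cox power transform before model
#' fitting. lambda is chosen by profile maximum likelihood over a bounded
#' interval. Because some targets contain exact zeros (treatments in which
#' no roots emerged), a shift is added first: zero when all values are
#' positive, otherwise half the smallest positive value of the column --
#' a scale-aware constant that keeps the transform defined.
#'
#' @param values Numeric vector of non-negative target values (>= 3 finite
#'   values, not all equal).
#' @param lambda_range Interval searched for lambda (default [-2, 2]).
#' @return A \code{boxcox_transform} with elements \code{lambda},
#'   \code{shift}, \code{loglik}.
#' @export
boxcox_fit <- function(values, lambda_range = c(-2, 2)) {
  x <- values[is.finite(values)]
  if (length(x) < 3) stop("need at least 3 finite values")
  if (stats::sd(x) == 0) stop("constant input: no variance to normalize")
  if (any(x < 0)) stop("Box-Cox requires non-negative values")
  shift <- if (min(x) > 0) 0 else min(x[x > 0]) / 2
  xs <- x + shift
  # profile log-likelihood of the normal model on the transformed scale,
  # including the Jacobian term (lambda - 1) * sum(log x)
  ll <- function(lam) {
    z <- bc_forward(xs, lam)
    n <- length(z)
    -n / 2 * log(sum((z - mean(z))^2) / n) + (lam - 1) * sum(log(xs))
  }
  opt <- stats::optimize(ll, interval = lambda_range, maximum = TRUE,
                         tol = 1e-6)
  structure(list(lambda = opt$maximum, shift = shift,
                 loglik = opt$objective),
            class = "boxcox_transform")
}

bc_forward <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Apply / invert a fitted Box-Cox transform
#'
#' Forward: \eqn{((x+s)^\lambda - 1)/\lambda} for \eqn{\lambda \ne 0},
#' \eqn{\log(x+s)} for \eqn{\lambda = 0}. \code{boxcox_invert} is the exact
#' inverse; values outside the image of the transform (e.g. below
#' \eqn{-1/\lambda} for \eqn{\lambda > 0}) raise a domain error.
#'
#' @param transform A \code{boxcox_transform}.
#' @param values Numeric vector.
#' @return Transformed (or back-transformed) numeric vector.
#' @export
boxcox_apply <- function(transform, values) {
  stopifnot(inherits(transform, "boxcox_transform"))
  x <- values + transform$shift
  if (any(x <= 0, na.rm = TRUE)) {
    stop("domain error: shifted values must be positive")
  }
  bc_forward(x, transform$lambda)
}

#' @rdname boxcox_apply
#' @export
boxcox_invert <- function(transform, values) {
  stopifnot(inherits(transform, "boxcox_transform"))
  lam <- transform$lambda
  x <- if (abs(lam) < 1e-8) {
    exp(values)
  } else {
    base <- lam * values + 1
    if (any(base <= 0, na.rm = TRUE)) {
      stop("domain error: value outside the image of the lambda=",
           signif(lam, 4), " transform")
    }
    base^(1 / lam)
  }
  x - transform$shift
}

#' @export
print.boxcox_transform <- function(x, ...) {
  cat("Box-Cox transform: lambda =", signif(x$lambda, 4),
      " shift =", signif(x$shift, 4), "\n")
  invisible(x)
}

#' Repeated k-fold cross-validation plan
#'
#' Builds the fold plan used to score surrogate families: indices 1..n are
#' shuffled once per repeat and split into k near-equal folds, giving
#' k * repeats (train, test) pairs. Plans are bit-reproducible from the
#' seed. Defaults follow the study design: 5 folds, 10 repetitions.
#'
#' @param n Number of observations.
#' @param k Folds per repeat (2 <= k <= n).
#' @param repeats Number of shuffled repeats.
#' @param seed Integer seed.
#' @return A \code{fold_plan}: list with \code{n, k, repeats, seed} and
#'   \code{pairs}, a list of \code{list(train=, test=, repeat_id=, fold=)}.
#' @export
make_folds <- function(n, k = 5, repeats = 10, seed = 1) {
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  rng <- local_rng(seed)
  pairs <- list()
  for (r in seq_len(repeats)) {
    perm <- rng$sample_int(n)
    fold_of <- rep(seq_len(k), length.out = n)[order(perm)]
    # order(perm) assigns shuffled membership; sizes differ by at most 1
    for (f in seq_len(k)) {
      test <- which(fold_of == f)
      pairs[[length(pairs) + 1]] <-
        list(train = setdiff(seq_len(n), test), test = test,
             repeat_id = r, fold = f)
    }
  }
  structure(list(n = n, k = k, repeats = repeats, seed = seed,
                 pairs = pairs),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("Fold plan: n =", x$n, ", k =", x$k, ", repeats =", x$repeats,
      ", seed =", x$seed, "(", length(x$pairs), "train/test pairs )\n")
  invisible(x)
}

#' @export
as.data.frame.fold_plan <- function(x, ...) {
  rows <- lapply(seq_along(x$pairs), function(i) {
    p <- x$pairs[[i]]
    data.frame(pair_id = i, repeat_id = p$repeat_id, fold = p$fold,
               index = c(p$train, p$test),
               role = rep(c("train", "test"),
                          c(length(p$train), length(p$test))))
  })
  do.call(rbind, rows)
}

#' PCA-based outlier screen for the input design
#'
#' Standardizes the columns, projects onto the leading principal components
#' covering at least \code{var_explained} of the variance, and flags rows
#' whose score distance exceeds \code{sd_threshold} standard deviations of
#' the score distances. The permissive default (3 SD on components covering
#' 95 % of variance) flags nothing on the packaged balanced design.
#'
#' @param X Numeric matrix with more rows than columns.
#' @param sd_threshold Flagging threshold in SD units (default 3).
#' @param var_explained Minimum cumulative variance of the retained
#'   components (default 0.95).
#' @return Logical vector, one flag per row.
#' @export
pca_outlier_flags <- function(X, sd_threshold = 3, var_explained = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more rows than columns for the screen")
  keep <- apply(X, 2, stats::sd) > 0
  Z <- scale(X[, keep, drop = FALSE])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- which(cum >= var_explained)[1]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  d <- sqrt(rowSums(sweep(scores, 2, pc$sdev[seq_len(m)], "/")^2))
  d > mean(d) + sd_threshold * stats::sd(d)
}

# Min-max input scaler: designed factor levels are mapped to [0,1] so that
# kernel distances and membership widths are comparable across inputs.
minmax_fit <- function(X, bounds = NULL) {
  X <- as.matrix(X)
  if (is.null(bounds)) {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  } else {
    lo <- bounds[1, ]; hi <- bounds[2, ]
  }
  hi <- ifelse(hi > lo, hi, lo + 1)
  structure(list(lower = lo, upper = hi), class = "minmax_scaler")
}

minmax_apply <- function(scaler, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  sweep(sweep(X, 2, scaler$lower), 2, scaler$upper - scaler$lower, "/")
}
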