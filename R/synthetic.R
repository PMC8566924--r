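# Synthetic response surfaces and simulated datasets with the statistical
# structure of the packaged experiment, so downstream stages can be tested
# against known ground truth.

#' Build a synthetic growth-response surface
#'
#' Constructs a smooth ground-truth surface over the 5-D culture design box
#' as baseline + one Gaussian bump per input + optional pairwise interaction
#' terms:
#' \deqn{f(x) = b_0 + \sum_j A_j \exp[-((x_j - c_j)/w_j)^2]
#'   + \sum_{jk} A_{jk} g_j(x_j) g_k(x_k)}
#' where \eqn{g_j} are the (unit-amplitude) per-input bumps. With
#' non-negative amplitudes the surface is maximized exactly at the bump
#' centers, so the argmax is known analytically; the per-input amplitudes
#' define a known importance ordering. Replicate noise is described by a
#' coefficient of variation (see \code{\link{simulate_growth}}), matching
#' the way the experimental SEs grow with the treatment means.
#'
#' @param seed Integer seed; surfaces are deterministic given the seed.
#' @param centers Optional 5-vector of bump centers (argmax). Default:
#'   drawn uniformly from the central 60 % of each dimension's range.
#' @param widths Optional 5-vector of bump widths in input units. Default:
#'   40 % of each dimension's range.
#' @param amplitudes Optional 5-vector of non-negative bump amplitudes
#'   (importance weights). Default: strictly decreasing weights in a
#'   shuffled input order so each seed plants a distinct importance
#'   ordering.
#' @param baseline Surface value far from all bumps (default 30, a typical
#'   small shoot length in mm).
#' @param interactions Number of random pairwise product interaction terms
#'   (default 0). Interaction amplitudes are kept at 10 % of the smallest
#'   main-effect amplitude so the argmax stays at \code{centers}.
#' @param noise_cv Replicate coefficient of variation used by
#'   \code{\link{simulate_growth}} (default 0.4, the median SE-implied
#'   replicate CV of the packaged dataset: CV = sd/mean = sqrt(n) SE/mean
#'   at n = 4).
#' @param bounds 2 x 5 bounds matrix as \code{\link{input_bounds}}.
#' @return A \code{growth_surface} object with elements \code{centers}
#'   (= \code{known_argmax}), \code{widths}, \code{amplitudes},
#'   \code{baseline}, \code{interactions}, \code{noise_cv}, \code{bounds}.
#'   Evaluate it with \code{predict(surface, X)}.
#' @examples
#' s <- growth_surface(seed = 1)
#' predict(s, matrix(s$known_argmax, nrow = 1))  # the analytic maximum
#' @export
growth_surface <- function(seed, centers = NULL, widths = NULL,
                           amplitudes = NULL, baseline = 30,
                           interactions = 0, noise_cv = 0.4,
                           bounds = input_bounds()) {
  if (!is.matrix(bounds) || nrow(bounds) != 2) {
    stop("config error: 'bounds' must be a 2 x d matrix (lower; upper)")
  }
  if (any(bounds[2, ] <= bounds[1, ])) {
    stop("config error: upper bounds must exceed lower bounds")
  }
  d <- ncol(bounds)
  range <- bounds[2, ] - bounds[1, ]
  rng <- local_rng(seed)
  if (is.null(centers)) {
    centers <- bounds[1, ] + range * (0.2 + 0.6 * rng$runif(d))
  }
  if (is.null(widths)) widths <- 0.4 * range
  if (is.null(amplitudes)) {
    # strictly decreasing weights assigned to a shuffled input order
    amplitudes <- (120 * 0.55 ^ (seq_len(d) - 1))[rng$sample_int(d)]
  }
  centers <- as.numeric(centers); widths <- as.numeric(widths)
  amplitudes <- as.numeric(amplitudes)
  stopifnot(length(centers) == d, length(widths) == d,
            length(amplitudes) == d)
  if (any(widths <= 0)) stop("config error: widths must be positive")
  if (any(amplitudes < 0)) stop("config error: amplitudes must be >= 0")
  if (any(centers < bounds[1, ] | centers > bounds[2, ])) {
    stop("config error: centers must lie inside the bounds")
  }
  if (baseline < 0) stop("config error: baseline must be >= 0")
  if (noise_cv < 0) stop("config error: noise_cv must be >= 0")
  inter <- NULL
  if (interactions > 0) {
    pairs <- utils::combn(d, 2)
    pick <- rng$sample_int(ncol(pairs))[seq_len(min(interactions, ncol(pairs)))]
    inter <- list(pairs = pairs[, pick, drop = FALSE],
                  amp = rep(0.1 * min(amplitudes[amplitudes > 0], 1),
                            length(pick)))
  }
  structure(
    list(centers = centers, known_argmax = centers, widths = widths,
         amplitudes = amplitudes, importance_weights = amplitudes,
         baseline = baseline, interactions = inter, noise_cv = noise_cv,
         bounds = bounds, seed = seed),
    class = "growth_surface")
}

#' @rdname growth_surface
#' @param object A \code{growth_surface}.
#' @param newdata Numeric matrix of input points (one row per point) or a
#'   single numeric vector.
#' @param ... Unused.
#' @export
predict.growth_surface <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  d <- length(object$centers)
  stopifnot(ncol(X) == d)
  G <- vapply(seq_len(d), function(j) {
    exp(-((X[, j] - object$centers[j]) / object$widths[j])^2)
  }, numeric(nrow(X)))
  G <- matrix(G, nrow = nrow(X))
  f <- object$baseline + as.numeric(G %*% object$amplitudes)
  if (!is.null(object$interactions)) {
    p <- object$interactions$pairs
    for (k in seq_len(ncol(p))) {
      f <- f + object$interactions$amp[k] * G[, p[1, k]] * G[, p[2, k]]
    }
  }
  f
}

#' @export
print.growth_surface <- function(x, ...) {
  cat("Synthetic growth-response surface (seed ", x$seed, ")\n", sep = "")
  cat("  argmax:", paste(signif(x$known_argmax, 4), collapse = ", "), "\n")
  cat("  amplitudes:", paste(signif(x$amplitudes, 4), collapse = ", "), "\n")
  cat("  baseline:", x$baseline, " noise CV:", x$noise_cv, "\n")
  invisible(x)
}

#' The packaged experiment's factor design
#'
#' The 22 distinct light-spectrum combinations of the packaged dataset
#' crossed with the 3 sucrose levels (1, 3, 6 % w/v): the 66-point design
#' used as the default layout for simulated datasets.
#'
#' @return A 66 x 5 data frame of input levels.
#' @export
default_design <- function() {
  d <- as.data.frame(growth_data())[, growth_inputs()]
  rownames(d) <- NULL
  d
}

#' Simulate a growth dataset from a known surface
#'
#' For every design point, draws \code{n_rep} replicate plantlet values from
#' Normal(f(x), noise_cv * f(x)) truncated at zero (growth quantities cannot
#' be negative; truncation induces a small positive bias at high CV), then
#' records the replicate mean and standard error exactly as the experimental
#' dataset does. All five traits are simulated from the same surface scaled
#' to each trait's typical magnitude.
#'
#' @param surface A \code{growth_surface}.
#' @param design Data frame or matrix of input points (columns in
#'   \code{growth_inputs()} order); default \code{default_design()}.
#' @param n_rep Replicates per design point (default 4, as in the
#'   experiment).
#' @param seed Integer seed.
#' @param trait_scale Named multipliers applied to the surface per trait
#'   (default 1 for shoot/root length, 0.05 for counts, 20 for canopy area,
#'   roughly matching the observed trait magnitudes).
#' @return A validated \code{growth_dataset}.
#' @export
simulate_growth <- function(surface, design = default_design(), n_rep = 4,
                            seed = 1,
                            trait_scale = c(shoot_length = 1,
                                            root_length = 1,
                                            node_number = 0.05,
                                            shoot_number = 0.05,
                                            canopy_area = 20)) {
  stopifnot(inherits(surface, "growth_surface"))
  if (n_rep < 1) stop("n_rep must be >= 1")
  design <- as.data.frame(design)
  if (nrow(design) == 0) stop("empty design")
  X <- as.matrix(design[, growth_inputs()])
  f <- predict(surface, X)
  rng <- local_rng(seed)
  out <- design[, growth_inputs()]
  for (tr in growth_traits()) {
    mu <- f * trait_scale[[tr]]
    sd <- surface$noise_cv * mu
    m <- se <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
      reps <- rtruncnorm0(rng, n_rep, mu[i], sd[i])
      m[i] <- mean(reps)
      se[i] <- if (n_rep > 1) stats::sd(reps) / sqrt(n_rep) else 0
    }
    out[[paste0("mean_", tr)]] <- m
    out[[paste0("se_", tr)]] <- se
  }
  out$n <- as.integer(n_rep)
  validate_growth_dataset(out)
}

#' Draw pseudo-replicates consistent with recorded means and SEs
#'
#' Inverts the mean +/- SE summary: for each treatment record, draws
#' \code{n} per-plantlet values from Normal(mean, SE * sqrt(n)) truncated at
#' zero for every trait. The sample mean of many draws converges to the
#' recorded mean (up to the small truncation bias when SE is large relative
#' to the mean).
#'
#' @param dataset A \code{growth_dataset}.
#' @param seed Integer seed.
#' @param n_draws Draws per record; default the recorded replicate count.
#' @return A data frame with one row per simulated plantlet: the input
#'   columns, \code{replicate}, and one column per trait.
#' @export
pseudo_replicates <- function(dataset, seed = 1, n_draws = NULL) {
  df <- as.data.frame(dataset)
  rng <- local_rng(seed)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    n <- if (is.null(n_draws)) df$n[i] else n_draws
    rec <- df[rep(i, n), growth_inputs(), drop = FALSE]
    rec$replicate <- seq_len(n)
    for (tr in growth_traits()) {
      m <- df[[paste0("mean_", tr)]][i]
      s <- df[[paste0("se_", tr)]][i] * sqrt(df$n[i])
      rec[[tr]] <- rtruncnorm0(rng, n, m, s)
    }
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Draw n values from Normal(mu, sd) truncated below at 0 by inversion, so a
# single uniform stream keeps the draws reproducible.
rtruncnorm0 <- function(rng, n, mu, sd) {
  if (sd <= 0) return(rep(mu, n))
  p0 <- stats::pnorm(0, mu, sd)
  u <- p0 + (1 - p0) * rng$runif(n)
  stats::qnorm(u, mu, sd)
}

# Seeded RNG that does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  run <- function(expr_fun) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    })
    expr_fun()
  }
  list(
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = n, replace = FALSE, prob = NULL) {
      run(function() sample.int(n, size, replace = replace, prob = prob))
    }
  )
}

#' Space-filling (Latin hypercube) design over the input box
#'
#' Stratified-permutation Latin hypercube: each dimension is divided into n
#' equal strata, one point drawn per stratum, and strata matched across
#' dimensions by independent random permutations. Used for recovery tests,
#' where the experiment's own 22-spectrum layout is too sparse to localize
#' an arbitrary interior optimum.
#'
#' @param n Number of design points.
#' @param seed Integer seed.
#' @param bounds 2 x d bounds matrix (default \code{\link{input_bounds}}).
#' @return An n x d data frame of input levels.
#' @export
lhs_design <- function(n, seed = 1, bounds = input_bounds()) {
  rng <- local_rng(seed)
  d <- ncol(bounds)
  u <- vapply(seq_len(d), function(j) {
    (rng$sample_int(n) - rng$runif(n)) / n
  }, numeric(n))
  X <- sweep(sweep(matrix(u, n, d), 2, bounds[2, ] - bounds[1, ], "*"),
             2, bounds[1, ], "+")
  colnames(X) <- colnames(bounds)
  as.data.frame(X)
}
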