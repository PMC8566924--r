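# Four bound-constrained single-objective metaheuristics sharing one
# problem/result contract, used to maximize a fitted surrogate over the
# culture-condition box. All four: seeded initial population uniform in the
# bounds, candidates clipped to the box after every move, incumbent best
# tracked elitistically so the convergence history is non-decreasing.

#' Define a box-constrained maximization problem
#'
#' @param objective Function mapping an input vector to a finite scalar.
#'   If \code{vectorized = TRUE} it must accept a matrix (one point per
#'   row) and return a vector -- substantially faster for the
#'   population-based optimizers.
#' @param lower,upper Numeric bound vectors (\code{lower < upper}).
#' @param vectorized Whether \code{objective} is matrix-aware.
#' @return An \code{optim_problem}.
#' @export
optim_problem <- function(objective, lower, upper, vectorized = FALSE) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(lower >= upper)) {
    stop("need lower < upper in every dimension")
  }
  structure(list(objective = objective, lower = lower, upper = upper,
                 vectorized = vectorized, dim = length(lower)),
            class = "optim_problem")
}

#' Maximization problem over a fitted growth surrogate
#'
#' Wraps \code{predict(model, .)} as a vectorized objective over the
#' culture-condition box (light channels in [0, 100] umol/m^2/s, sucrose in
#' [1, 6] % w/v by default). Because the optimum of a monotone transform is
#' attained at the same input, maximizing original-unit predictions and
#' maximizing Box-Cox-scale predictions locate the same conditions.
#'
#' @param model A fitted \code{growth_surrogate}.
#' @param bounds 2 x d bounds matrix; default \code{\link{input_bounds}}.
#' @return An \code{optim_problem}.
#' @export
surrogate_problem <- function(model, bounds = input_bounds()) {
  stopifnot(inherits(model, "growth_surrogate"))
  optim_problem(function(X) predict(model, X),
                lower = bounds[1, ], upper = bounds[2, ], vectorized = TRUE)
}

#' Optimizer run settings
#'
#' Defaults follow the study configuration: population 200, 1000
#' generations, mutation rate 0.05, crossover fraction 0.6 (GA), migration
#' blend alpha = 1 and maximum immigration/emigration rates E = I = 1
#' (BBO), mirror threshold rising linearly 0.1 -> 0.9 and random-walk scale
#' 0.01 (UB - LB) (ISA). \code{test_profile()} shrinks the budget to
#' population 50 / 200 generations for fast runs.
#'
#' @param population Population size (>= 2).
#' @param generations Generation budget (the only stopping rule).
#' @param seed Integer seed; same seed and settings reproduce the run
#'   bit-exactly.
#' @param mutation_rate Per-gene mutation probability (GA, BBO).
#' @param crossover_fraction Fraction of GA pairs undergoing crossover.
#' @param alpha BBO migration blend in [0, 1].
#' @param E,I BBO maximum emigration / immigration rates.
#' @param mutation_sd BBO Gaussian mutation SD as a fraction of the range.
#' @param elitism Number of elite solutions carried over unchanged.
#' @param as_printed_migration Use the uncorrected migration update
#'   \code{SIV_i + alpha (SIV_j + SIV_i)} (diverges off the box; kept only
#'   for comparison -- see the methods vignette).
#' @return An \code{optim_control} list.
#' @export
optim_control <- function(population = 200, generations = 1000, seed = 1,
                          mutation_rate = 0.05, crossover_fraction = 0.6,
                          alpha = 1, E = 1, I = 1, mutation_sd = 0.1,
                          elitism = 2, as_printed_migration = FALSE) {
  if (population < 2) stop("population must be >= 2")
  if (mutation_rate < 0 || mutation_rate > 1 ||
      crossover_fraction < 0 || crossover_fraction > 1) {
    stop("rates must lie in [0, 1]")
  }
  structure(list(population = population, generations = generations,
                 seed = seed, mutation_rate = mutation_rate,
                 crossover_fraction = crossover_fraction, alpha = alpha,
                 E = E, I = I, mutation_sd = mutation_sd,
                 elitism = min(elitism, population - 1),
                 as_printed_migration = as_printed_migration),
            class = "optim_control")
}

#' @rdname optim_control
#' @param ... Overrides passed to \code{optim_control}.
#' @export
test_profile <- function(...) {
  optim_control(population = 50, generations = 200, ...)
}

new_optim_result <- function(algorithm, best_x, best_f, history,
                             evaluations, seed) {
  structure(list(algorithm = algorithm, best_x = best_x, best_f = best_f,
                 history = history, evaluations = evaluations, seed = seed),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(toupper(x$algorithm), " maximization: best f = ",
      signif(x$best_f, 6), "\n  at x = (",
      paste(signif(x$best_x, 5), collapse = ", "), ")\n  ",
      length(x$history), " generations, ", x$evaluations,
      " objective evaluations, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# --- shared machinery ------------------------------------------------------

make_evaluator <- function(problem) {
  count <- new.env(); count$n <- 0
  f <- function(X) {
    X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
    count$n <- count$n + nrow(X)
    v <- if (problem$vectorized) {
      problem$objective(X)
    } else {
      apply(X, 1, problem$objective)
    }
    v <- as.numeric(v)
    if (any(!is.finite(v))) {
      i <- which(!is.finite(v))[1]
      stop("non-finite objective at point (",
           paste(signif(X[i, ], 6), collapse = ", "), ")")
    }
    v
  }
  list(f = f, count = count)
}

clip_box <- function(X, lower, upper) {
  X <- pmin(pmax(X, matrix(lower, nrow(X), length(lower), byrow = TRUE)),
            matrix(upper, nrow(X), length(upper), byrow = TRUE))
  X
}

init_population <- function(rng, n, lower, upper) {
  d <- length(lower)
  matrix(rng$runif(n * d), n, d) *
    matrix(upper - lower, n, d, byrow = TRUE) +
    matrix(lower, n, d, byrow = TRUE)
}

# Roulette-wheel index draw on shifted-positive weights.
roulette <- function(rng, weights, size = 1) {
  w <- weights - min(weights) + 1e-12
  rng$sample_int(length(w), size = size, replace = TRUE, prob = w)
}

# --- genetic algorithm -----------------------------------------------------

#' Genetic algorithm
#'
#' Real-coded GA: roulette-wheel selection on shifted-positive fitness,
#' two-point crossover applied to \code{crossover_fraction} of the parent
#' pairs, uniform resampling mutation at \code{mutation_rate} per gene, and
#' elitism. Children are clipped to the bounds.
#'
#' @param problem An \code{\link{optim_problem}}.
#' @param control An \code{\link{optim_control}}.
#' @return An \code{optim_result}.
#' @export
optimize_ga <- function(problem, control = optim_control()) {
  ev <- make_evaluator(problem)
  rng <- local_rng(control$seed)
  d <- problem$dim
  pop <- init_population(rng, control$population, problem$lower,
                         problem$upper)
  fit <- ev$f(pop)
  history <- numeric(control$generations)
  for (g in seq_len(control$generations)) {
    elite_idx <- order(fit, decreasing = TRUE)[seq_len(control$elitism)]
    n_child <- control$population - control$elitism
    parents <- roulette(rng, fit, size = 2 * n_child)
    P1 <- pop[parents[seq_len(n_child)], , drop = FALSE]
    P2 <- pop[parents[n_child + seq_len(n_child)], , drop = FALSE]
    children <- P1
    do_cx <- rng$runif(n_child) < control$crossover_fraction
    for (i in which(do_cx)) {
      cuts <- sort(rng$sample_int(d + 1, size = 2) - 1)  # cut points 0..d
      seg <- seq_len(d) > cuts[1] & seq_len(d) <= cuts[2]
      children[i, seg] <- P2[i, seg]
    }
    mut <- matrix(rng$runif(n_child * d) < control$mutation_rate, n_child, d)
    if (any(mut)) {
      fresh <- init_population(rng, n_child, problem$lower, problem$upper)
      children[mut] <- fresh[mut]
    }
    children <- clip_box(children, problem$lower, problem$upper)
    child_fit <- ev$f(children)
    pop <- rbind(pop[elite_idx, , drop = FALSE], children)
    fit <- c(fit[elite_idx], child_fit)
    history[g] <- max(fit)
  }
  best <- which.max(fit)
  new_optim_result("ga", pop[best, ], fit[best], cummax(history),
                   ev$count$n, control$seed)
}

# --- biogeography-based optimization ---------------------------------------

#' Biogeography-based optimization
#'
#' Habitats (solutions) are ranked by fitness (habitat suitability);
#' per-rank emigration rates \eqn{\mu = E \cdot S / S_{max}} form an
#' arithmetic progression over [0, 1] with step 1/(population - 1), and
#' immigration rates are \eqn{\lambda = 1 - \mu}. Each decision variable of
#' each non-elite habitat immigrates with probability \eqn{\lambda}; the
#' donor habitat is chosen by roulette wheel proportional to \eqn{\mu} and
#' the migrated value is the blend
#' \eqn{SIV_i + \alpha (SIV_j - SIV_i)}. Gaussian mutation perturbs genes
#' at \code{mutation_rate}; elites are preserved; everything is clipped to
#' the bounds.
#'
#' @inheritParams optimize_ga
#' @return An \code{optim_result}.
#' @export
optimize_bbo <- function(problem, control = optim_control()) {
  ev <- make_evaluator(problem)
  rng <- local_rng(control$seed)
  d <- problem$dim
  n <- control$population
  pop <- init_population(rng, n, problem$lower, problem$upper)
  fit <- ev$f(pop)
  history <- numeric(control$generations)
  # rank 1 = best habitat: most species, highest emigration, lowest
  # immigration
  mu_rank <- control$E * seq(1, 0, length.out = n)
  lambda_rank <- control$I * (1 - seq(1, 0, length.out = n))
  for (g in seq_len(control$generations)) {
    ord <- order(fit, decreasing = TRUE)
    rank_of <- integer(n); rank_of[ord] <- seq_len(n)
    elite_idx <- ord[seq_len(control$elitism)]
    new_pop <- pop
    for (i in seq_len(n)) {
      if (i %in% elite_idx) next
      lam <- lambda_rank[rank_of[i]]
      immigrate <- rng$runif(d) < lam
      if (any(immigrate)) {
        for (m in which(immigrate)) {
          j <- roulette(rng, mu_rank[rank_of])
          delta <- if (control$as_printed_migration) {
            control$alpha * (pop[j, m] + pop[i, m])
          } else {
            control$alpha * (pop[j, m] - pop[i, m])
          }
          new_pop[i, m] <- pop[i, m] + delta
        }
      }
      mut <- rng$runif(d) < control$mutation_rate
      if (any(mut)) {
        new_pop[i, mut] <- new_pop[i, mut] +
          rng$rnorm(sum(mut)) * control$mutation_sd *
          (problem$upper[mut] - problem$lower[mut])
      }
    }
    new_pop <- clip_box(new_pop, problem$lower, problem$upper)
    changed <- which(rowSums(new_pop != pop) > 0)
    if (length(changed) > 0) {
      fit[changed] <- ev$f(new_pop[changed, , drop = FALSE])
      pop <- new_pop
    }
    history[g] <- max(fit)
  }
  best <- which.max(fit)
  new_optim_result("bbo", pop[best, ], fit[best], cummax(history),
                   ev$count$n, control$seed)
}

# --- interior search algorithm ---------------------------------------------

#' Interior search algorithm
#'
#' Per iteration the mirror threshold \eqn{\alpha} rises linearly from 0.1
#' to 0.9. The fittest element takes a local random walk
#' \eqn{x_{gb} + rn \cdot \lambda_w} with \eqn{\lambda_w = 0.01 (UB - LB)}.
#' Every other element joins the mirror group when \eqn{r_1 \le \alpha}
#' (reflected through a random mirror point placed between itself and the
#' fittest element) and the composition group otherwise (resampled
#' uniformly within the bounds). Updates are accepted greedily.
#'
#' @inheritParams optimize_ga
#' @return An \code{optim_result}.
#' @export
optimize_isa <- function(problem, control = optim_control()) {
  ev <- make_evaluator(problem)
  rng <- local_rng(control$seed)
  d <- problem$dim
  n <- control$population
  lower <- problem$lower; upper <- problem$upper
  lambda_w <- 0.01 * (upper - lower)
  pop <- init_population(rng, n, lower, upper)
  fit <- ev$f(pop)
  history <- numeric(control$generations)
  G <- control$generations
  for (g in seq_len(G)) {
    alpha <- if (G > 1) 0.1 + 0.8 * (g - 1) / (G - 1) else 0.9
    gb <- which.max(fit)
    x_gb <- pop[gb, ]
    cand <- pop
    # fittest element: random walk around itself
    cand[gb, ] <- x_gb + rng$rnorm(d) * lambda_w
    r1 <- rng$runif(n)
    for (i in seq_len(n)) {
      if (i == gb) next
      if (r1[i] <= alpha) {                      # mirror group
        r3 <- rng$runif(1)
        x_m <- r3 * pop[i, ] + (1 - r3) * x_gb
        cand[i, ] <- 2 * x_m - pop[i, ]
      } else {                                   # composition group
        cand[i, ] <- lower + (upper - lower) * rng$runif(d)
      }
    }
    cand <- clip_box(cand, lower, upper)
    cand_fit <- ev$f(cand)
    accept <- cand_fit > fit
    pop[accept, ] <- cand[accept, , drop = FALSE]
    fit[accept] <- cand_fit[accept]
    history[g] <- max(fit)
  }
  best <- which.max(fit)
  new_optim_result("isa", pop[best, ], fit[best], cummax(history),
                   ev$count$n, control$seed)
}

# --- symbiotic organisms search --------------------------------------------

#' Symbiotic organisms search
#'
#' Each organism passes through three phases per generation, each accepted
#' greedily. Mutualism with a random partner j: mutual vector
#' \eqn{MV = (x_i + x_j)/2}, benefit factors \eqn{BF_1, BF_2} drawn
#' independently from \{1, 2\}, updates
#' \eqn{x + rand(0,1)(x_{best} - MV \cdot BF)}. Commensalism:
#' \eqn{x_i + rand(0,1)(x_{best} - x_j)}. Parasitism: a parasite vector --
#' a copy of \eqn{x_i} with a random non-empty subset of dimensions
#' resampled uniformly in the bounds -- replaces a random host \eqn{x_j}
#' iff strictly better. SOS has no tunable operator parameters beyond the
#' population and generation budget.
#'
#' @inheritParams optimize_ga
#' @return An \code{optim_result}.
#' @export
optimize_sos <- function(problem, control = optim_control()) {
  ev <- make_evaluator(problem)
  rng <- local_rng(control$seed)
  d <- problem$dim
  n <- control$population
  lower <- problem$lower; upper <- problem$upper
  pop <- init_population(rng, n, lower, upper)
  fit <- ev$f(pop)
  history <- numeric(control$generations)
  for (g in seq_len(control$generations)) {
    for (i in seq_len(n)) {
      best_idx <- which.max(fit)
      x_best <- pop[best_idx, ]
      # mutualism
      j <- rng$sample_int(n - 1, 1); if (j >= i) j <- j + 1
      MV <- (pop[i, ] + pop[j, ]) / 2
      BF <- 1 + (rng$runif(2) < 0.5)
      cand <- rbind(pop[i, ] + rng$runif(d) * (x_best - MV * BF[1]),
                    pop[j, ] + rng$runif(d) * (x_best - MV * BF[2]))
      cand <- clip_box(cand, lower, upper)
      cf <- ev$f(cand)
      if (cf[1] > fit[i]) { pop[i, ] <- cand[1, ]; fit[i] <- cf[1] }
      if (cf[2] > fit[j]) { pop[j, ] <- cand[2, ]; fit[j] <- cf[2] }
      # commensalism
      j <- rng$sample_int(n - 1, 1); if (j >= i) j <- j + 1
      x_best <- pop[which.max(fit), ]
      cand <- clip_box(matrix(pop[i, ] + rng$runif(d) * (x_best - pop[j, ]),
                              1), lower, upper)
      cf <- ev$f(cand)
      if (cf > fit[i]) { pop[i, ] <- cand[1, ]; fit[i] <- cf }
      # parasitism
      j <- rng$sample_int(n - 1, 1); if (j >= i) j <- j + 1
      pv <- pop[i, ]
      n_change <- rng$sample_int(d, 1)
      dims <- rng$sample_int(d, n_change)
      pv[dims] <- lower[dims] + (upper[dims] - lower[dims]) *
        rng$runif(n_change)
      pf <- ev$f(matrix(pv, 1))
      if (pf > fit[j]) { pop[j, ] <- pv; fit[j] <- pf }
    }
    history[g] <- max(fit)
  }
  best <- which.max(fit)
  new_optim_result("sos", pop[best, ], fit[best], cummax(history),
                   ev$count$n, control$seed)
}

# --- joint runner ----------------------------------------------------------

#' Run all four optimizers on one problem
#'
#' Runs GA, BBO, ISA and SOS with the same (or per-algorithm) settings and
#' tabulates the best input vectors, best objective values, and the
#' relative spread of the best values across algorithms. Individual
#' failures are reported and do not stop the others.
#'
#' @param problem An \code{\link{optim_problem}}.
#' @param control An \code{\link{optim_control}} shared by all algorithms,
#'   or a named list of per-algorithm controls.
#' @return An \code{optim_table}: list with \code{results} (named
#'   \code{optim_result}s), \code{table} (one row per algorithm), and
#'   \code{spread} = (max best_f - min best_f) / |max best_f|.
#' @export
optimize_all <- function(problem, control = optim_control()) {
  algos <- c("ga", "bbo", "isa", "sos")
  runners <- list(ga = optimize_ga, bbo = optimize_bbo, isa = optimize_isa,
                  sos = optimize_sos)
  results <- list()
  for (a in algos) {
    ctrl <- if (inherits(control, "optim_control")) control else control[[a]]
    results[[a]] <- tryCatch(runners[[a]](problem, ctrl),
                             error = function(e) e)
    if (inherits(results[[a]], "error")) {
      warning("optimizer '", a, "' failed: ",
              conditionMessage(results[[a]]))
    }
  }
  ok <- !vapply(results, inherits, logical(1), "error")
  tab <- do.call(rbind, lapply(results[ok], function(r) {
    row <- data.frame(algorithm = r$algorithm, best_f = r$best_f,
                      evaluations = r$evaluations, seed = r$seed)
    for (k in seq_along(r$best_x)) row[[paste0("x", k)]] <- r$best_x[k]
    row
  }))
  rownames(tab) <- NULL
  bf <- tab$best_f
  spread <- if (length(bf) > 1) (max(bf) - min(bf)) / max(abs(max(bf)),
                                                          1e-12) else 0
  structure(list(results = results, table = tab, spread = spread),
            class = "optim_table")
}

#' @export
print.optim_table <- function(x, ...) {
  print(x$table)
  cat("relative best-value spread:", signif(x$spread, 4), "\n")
  invisible(x)
}
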