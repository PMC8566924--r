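# Surrogate families: closed-form GRNN behaviour, MLP training and forward
# contract, ANFIS structure, and the shared serialization container.

test_that("GRNN kernel weighting follows the closed form", {
  m <- fit_grnn(matrix(c(0, 1)), c(0, 1), sigma = 1, transform_y = FALSE)
  # exp(-0.5) / (1 + exp(-0.5)) weighting of the far target
  expect_equal(predict(m, matrix(0)), 0.37754, tolerance = 1e-5)
  expect_equal(predict(m, matrix(0.5)), 0.5)      # symmetry midpoint
  # kernel limits: interpolation and global mean
  m0 <- fit_grnn(matrix(c(0, 1)), c(0, 1), sigma = 1e-8,
                 transform_y = FALSE)
  expect_equal(predict(m0, matrix(c(0, 1), ncol = 1)), c(0, 1))
  mI <- fit_grnn(matrix(c(0, 1)), c(0, 1), sigma = 1e8,
                 transform_y = FALSE)
  expect_equal(predict(mI, matrix(0.123)), 0.5, tolerance = 1e-9)
  expect_error(fit_grnn(matrix(c(0, 1)), c(0, 1), sigma = 0), "positive")
})

test_that("GRNN predictions are convex combinations of training targets", {
  tm <- trait_matrix(fixture_data(), "shoot_length")
  m <- fit_grnn(tm$X, tm$y, sigma = 0.3, bounds = input_bounds())
  set.seed(31)
  Q <- cbind(matrix(runif(500 * 4, 0, 100), 500, 4), runif(500, 1, 6))
  p <- predict(m, Q)
  expect_true(all(p >= min(tm$y) - 1e-9 & p <= max(tm$y) + 1e-9))
  expect_true(max(p) <= 154.68 + 1e-9)
  # weights sum to one: constant targets are reproduced everywhere
  mc <- fit_grnn(tm$X, rep(42, 66), sigma = 0.3, transform_y = FALSE,
                 bounds = input_bounds())
  expect_equal(predict(mc, Q), rep(42, 500))
})

test_that("width selection tracks the signal-to-noise regime", {
  set.seed(32)
  X <- matrix(seq(0, 1, length.out = 40))
  plan <- make_folds(40, 5, 2, seed = 1)
  grid <- c(0.05, 0.2, 1, 5)
  s_signal <- select_sigma(X, y = 2 * X[, 1], plan, grid = grid,
                           transform_y = FALSE)
  s_noise <- select_sigma(X, y = rnorm(40), plan, grid = grid,
                          transform_y = FALSE)
  expect_lt(as.numeric(s_signal), as.numeric(s_noise))
  expect_equal(as.numeric(s_noise), 5)
  expect_equal(as.numeric(select_sigma(X, 2 * X[, 1], plan, grid = 0.7)),
               0.7)
  expect_error(select_sigma(X, 2 * X[, 1], plan, grid = numeric(0)),
               "empty")
})

test_that("MLP trains a representable target to near-zero error", {
  set.seed(33)
  X <- matrix(runif(120), 60, 2)
  y <- 3 * X[, 1]
  m <- fit_mlp(X, y, hidden_size = 2, seed = 1, transform_y = FALSE)
  expect_gt(compute_metrics(y, predict(m, X))$r2, 0.999)
  # seeded initialization makes training deterministic
  m2 <- fit_mlp(X, y, hidden_size = 2, seed = 1, transform_y = FALSE)
  expect_identical(m$fit[c("W1", "b1", "w2")], m2$fit[c("W1", "b1", "w2")])
  expect_error(fit_mlp(X, y, hidden_size = 0), "positive integer")
})

test_that("MLP forward pass equals the explicit network formula", {
  set.seed(34)
  X <- matrix(runif(40), 20, 2)
  m <- fit_mlp(X, X[, 1]^2 + X[, 2], hidden_size = 3, seed = 2,
               transform_y = FALSE, max_iter = 30)
  f <- m$fit
  Q <- matrix(runif(10), 5, 2)
  Qs <- cultivopt:::minmax_apply(m$scaler, Q)
  oracle <- vapply(seq_len(nrow(Qs)), function(s) {
    acc <- f$w2[f$hidden_size + 1]
    for (j in seq_len(f$hidden_size)) {
      acc <- acc + f$w2[j] * tanh(sum(f$W1[j, ] * Qs[s, ]) + f$b1[j])
    }
    acc * f$z_scale + f$z_center
  }, numeric(1))
  expect_equal(predict(m, Q), oracle, tolerance = 1e-12)
})

test_that("hidden-size selection prefers small nets for simple targets", {
  set.seed(35)
  X <- matrix(runif(100), 50, 2)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(50, sd = 0.2)
  plan <- make_folds(50, 5, 1, seed = 2)
  h <- select_hidden_size(X, y, plan, candidates = c(1, 12), seed = 1,
                          max_iter = 60, transform_y = FALSE)
  expect_equal(as.integer(h), 1L)
  expect_equal(as.integer(select_hidden_size(X, y, plan, candidates = 7,
                                             max_iter = 5)), 7L)
  expect_error(select_hidden_size(X, y, plan, candidates = c(3, 25)),
               "1..20")
})

test_that("ANFIS memberships, firing strengths, and span behave as built", {
  expect_equal(cultivopt:::anfis_mf(0.4, c = 0.4, a = 0.2, FALSE), 1)
  set.seed(36)
  X <- matrix(runif(80), 40, 2)
  a <- fit_anfis(X, 2 * X[, 1] + 3, mf_per_input = 3, transform_y = FALSE)
  W <- cultivopt:::anfis_firing(a$fit, matrix(runif(20), 10, 2))
  expect_equal(rowSums(W), rep(1, 10))
  # linear target lies in the model span: near-exact recovery
  expect_lt(sqrt(mean((2 * X[, 1] + 3 - predict(a, X))^2)), 1e-3)
  # constant consequents give a constant model
  R <- nrow(a$fit$rules)
  a$fit$theta <- rep(c(0, 0, 7), R)
  expect_equal(cultivopt:::anfis_predict_std(a$fit, matrix(runif(10), 5, 2)),
               rep(7, 5))
  expect_error(fit_anfis(matrix(runif(300), 60, 5), runif(60),
                         mf_per_input = 4), "rule explosion")
})

test_that("surrogates serialize to JSON and back without changing output", {
  tm <- trait_matrix(fixture_data(), "node_number")
  set.seed(37)
  Q <- cbind(matrix(runif(50 * 4, 0, 100), 50, 4), runif(50, 1, 6))
  models <- list(
    fit_grnn(tm$X, tm$y, sigma = 0.25, bounds = input_bounds(),
             trait = "node_number"),
    fit_mlp(tm$X, tm$y, hidden_size = 3, seed = 1, max_iter = 40,
            bounds = input_bounds()),
    fit_anfis(tm$X, tm$y, mf_per_input = 3, epochs = 2,
              bounds = input_bounds()))
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".json")
    write_surrogate(m, path)
    back <- read_surrogate(path)
    expect_equal(predict(back, Q), predict(m, Q), tolerance = 1e-12)
  }
})
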