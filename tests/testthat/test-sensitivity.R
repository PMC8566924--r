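test_that("a model that ignores an input has VSR exactly 1", {
  # a constant input column is ignored by the kernel distance, so
  # mean-substitution changes nothing
  set.seed(51)
  X <- cbind(a = runif(30), b = rep(0.5, 30))
  y <- 2 * X[, 1]
  m <- fit_grnn(X, y, sigma = 0.2, transform_y = FALSE)
  expect_equal(compute_vsr(m, X, y, "b"), 1)
  expect_gt(compute_vsr(m, X, y, "a"), 1)
})

test_that("degenerate full-model RMSE demands a CV denominator", {
  set.seed(52)
  X <- cbind(a = runif(20), b = runif(20))
  y <- X[, 1]
  m <- fit_grnn(X, y, sigma = 1e-6, transform_y = FALSE)  # interpolates
  expect_error(compute_vsr(m, X, y, 1), "cross-validation RMSE")
  expect_gt(compute_vsr(m, X, y, 1, rmse_full = 0.1), 0)
})

test_that("ranks are a permutation with fixed-order tie breaking", {
  set.seed(53)
  # constant input columns: the fitted model ignores every input, all
  # VSRs tie at exactly 1 and ranks fall back to the fixed input order
  X <- matrix(rep(c(1, 2, 3, 4, 5), each = 20), 20, 5)
  colnames(X) <- growth_inputs()
  y <- rnorm(20, 10)
  m <- fit_grnn(X, y, sigma = 1, transform_y = FALSE)
  rep <- rank_inputs(m, X, y, rmse_full = stats::sd(y))
  expect_equal(nrow(rep), 5)
  expect_setequal(rep$rank, 1:5)
  expect_equal(rep$rank, 1:5)   # exact ties: fixed input order
  expect_equal(rep$input[rep$rank == 1],
               rep$input[which.max(rep$vsr)])
})

test_that("planted importance orderings are recovered on noiseless data", {
  b <- input_bounds()
  width <- b[2, ] - b[1, ]
  amps <- c(150, 95, 65, 40, 20)    # strictly ordered, in input order
  surf <- growth_surface(seed = 5, amplitudes = amps, widths = 0.3 * width,
                         noise_cv = 0)
  dat <- simulate_growth(surf, design = lhs_design(250, seed = 9),
                         n_rep = 1, seed = 1)
  tm <- trait_matrix(dat, "shoot_length")
  plan <- make_folds(250, 5, 2, seed = 3)
  sig <- as.numeric(select_sigma(tm$X, tm$y, plan, bounds = b))
  m <- fit_grnn(tm$X, tm$y, sigma = sig, bounds = b)
  cvr <- evaluate_cv("grnn", tm$X, tm$y, plan,
                     list(sigma = sig, bounds = b))
  rep <- rank_inputs(m, tm$X, tm$y,
                     rmse_full = mean(cvr$rmse[cvr$partition == "test"]))
  expect_equal(rep$rank, order(-amps))
  expect_equal(rep$input[rep$rank == 1], "blue")
})

test_that("ranking is invariant to monotone rescaling of the VSRs", {
  # scaling the denominator scales every VSR equally: ranks unchanged
  set.seed(54)
  X <- matrix(runif(150), 30, 5)
  y <- 3 * X[, 2] + X[, 4] + rnorm(30, sd = 0.05)
  m <- fit_grnn(X, y, sigma = 0.3, transform_y = FALSE)
  r1 <- rank_inputs(m, X, y, rmse_full = 0.2)
  r2 <- rank_inputs(m, X, y, rmse_full = 2)
  expect_equal(r1$rank, r2$rank)
  expect_equal(r1$vsr / r2$vsr, rep(10, 5))
})
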