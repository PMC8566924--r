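optimizers <- list(ga = optimize_ga, bbo = optimize_bbo, isa = optimize_isa,
                   sos = optimize_sos)

test_that("every optimizer maximizes a sphere to its analytic optimum", {
  prob <- sphere_problem()
  for (nm in names(optimizers)) {
    r <- optimizers[[nm]](prob, test_profile(seed = 42))
    expect_lt(abs(r$best_f - 0), 1e-3)
    expect_true(all(abs(r$best_x - 0.3) < 0.05))
    expect_false(is.unsorted(r$history))
    expect_true(all(r$best_x >= 0 & r$best_x <= 1))
  }
})

test_that("the broad global bump beats the deceptive decoy", {
  prob <- two_bump_problem()
  for (nm in names(optimizers)) {
    r <- optimizers[[nm]](prob, test_profile(seed = 42))
    expect_lt(abs(r$best_f - 1), 1e-3)
    expect_true(all(abs(r$best_x - 0.65) < 0.1))  # global, not the decoy
  }
})

test_that("runs are bit-reproducible from the seed", {
  prob <- sphere_problem()
  for (nm in names(optimizers)) {
    ctrl <- optim_control(population = 20, generations = 30, seed = 9)
    r1 <- optimizers[[nm]](prob, ctrl)
    r2 <- optimizers[[nm]](prob, ctrl)
    expect_identical(r1[c("best_x", "best_f", "history", "evaluations")],
                     r2[c("best_x", "best_f", "history", "evaluations")])
  }
})

test_that("degenerate BBO migration (alpha = 0, no mutation) is static", {
  prob <- sphere_problem()
  r <- optimize_bbo(prob, optim_control(population = 15, generations = 10,
                                        seed = 3, alpha = 0,
                                        mutation_rate = 0))
  # SIV_new = SIV_i + 0 * (SIV_j - SIV_i): nothing ever moves
  expect_length(unique(r$history), 1)
})

test_that("the as-printed migration variant stays runnable but clipped", {
  prob <- sphere_problem()
  r <- optimize_bbo(prob, optim_control(population = 15, generations = 20,
                                        seed = 3,
                                        as_printed_migration = TRUE))
  expect_true(all(r$best_x >= 0 & r$best_x <= 1))
})

test_that("invalid configurations and objectives are rejected", {
  expect_error(optim_control(population = 1), "population")
  expect_error(optim_control(mutation_rate = 1.5), "rates")
  expect_error(optim_problem(identity, c(0, 0), c(1, 0)), "lower < upper")
  bad <- optim_problem(function(X) rep(NaN, nrow(X)), rep(0, 2), rep(1, 2),
                       vectorized = TRUE)
  expect_error(optimize_ga(bad, optim_control(population = 5,
                                              generations = 2)),
               "non-finite objective")
})

test_that("optimize_all tabulates the four algorithms jointly", {
  prob <- sphere_problem()
  res <- optimize_all(prob, optim_control(population = 30,
                                          generations = 60, seed = 5))
  expect_setequal(res$table$algorithm, c("ga", "bbo", "isa", "sos"))
  expect_equal(nrow(res$table), 4)
  expect_lt(res$spread, Inf)
  res2 <- optimize_all(prob, optim_control(population = 30,
                                           generations = 60, seed = 5))
  expect_identical(res$table, res2$table)
})
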