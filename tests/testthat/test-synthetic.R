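test_that("surfaces are deterministic with analytically known argmax", {
  s1 <- growth_surface(seed = 1)
  s2 <- growth_surface(seed = 1)
  expect_equal(s1$centers, s2$centers)
  expect_equal(s1$amplitudes, s2$amplitudes)
  # peak value is attained at the stated argmax
  set.seed(2)
  Q <- cbind(matrix(runif(400 * 4, 0, 100), 400, 4), runif(400, 1, 6))
  expect_true(all(predict(s1, Q) <=
                    predict(s1, matrix(s1$known_argmax, 1)) + 1e-12))
  # explicit center pins the argmax by construction
  ctr <- c(5, 90, 30, 20, 3.7)
  s3 <- growth_surface(seed = 1, centers = ctr)
  expect_equal(s3$known_argmax, ctr)
  # dominant amplitude pins the importance order
  s4 <- growth_surface(seed = 1, amplitudes = c(1, 2, 3, 4, 400))
  expect_equal(which.max(s4$importance_weights), 5L)
  # surfaces stay nonnegative and bounded on the box
  expect_true(all(predict(s1, Q) >= 0))
})

test_that("surface configuration is validated", {
  expect_error(growth_surface(seed = 1, widths = c(-1, 1, 1, 1, 1)),
               "widths")
  expect_error(growth_surface(seed = 1, centers = c(500, 1, 1, 1, 3)),
               "inside the bounds")
  b <- input_bounds(); b[2, 1] <- -5
  expect_error(growth_surface(seed = 1, bounds = b), "bounds")
})

test_that("simulated datasets mirror the experiment's structure", {
  surf <- growth_surface(seed = 2, noise_cv = 0)
  dat <- simulate_growth(surf, n_rep = 4, seed = 9)
  expect_equal(nrow(dat), 66)
  expect_equal(sum(dat$n), 264)
  # zero noise: recorded means equal the surface exactly
  X <- as.matrix(as.data.frame(dat)[, growth_inputs()])
  expect_equal(dat$mean_shoot_length, predict(surf, X))
  expect_true(all(dat$se_shoot_length == 0))
  # determinism
  surf2 <- growth_surface(seed = 2, noise_cv = 0.2)
  d1 <- simulate_growth(surf2, n_rep = 4, seed = 9)
  d2 <- simulate_growth(surf2, n_rep = 4, seed = 9)
  expect_identical(d1, d2)
  expect_error(simulate_growth(surf, design = default_design()[0, ]),
               "empty design")
})

test_that("replicate means converge to the surface as n_rep grows", {
  surf <- growth_surface(seed = 4, noise_cv = 0.1)
  des <- default_design()[c(2, 20, 50), ]
  dat <- simulate_growth(surf, design = des, n_rep = 10000, seed = 13)
  truth <- predict(surf, as.matrix(des))
  # 3-sigma band of a mean of 1e4 draws at CV 0.1
  expect_true(all(abs(dat$mean_shoot_length - truth) <
                    3 * 0.1 * truth / sqrt(10000) + 1e-9))
})

test_that("pseudo-replicates invert the mean/SE summaries", {
  d <- fixture_data()
  pr <- pseudo_replicates(d, seed = 5)
  expect_equal(nrow(pr), 264)
  expect_true(all(pr$shoot_length >= 0))
  # SE = 0 records reproduce the mean exactly (first record, shoot number)
  row1 <- as.data.frame(d)[1, ]
  expect_equal(row1$se_shoot_number, 0)
  expect_true(all(pr$shoot_number[1:4] == row1$mean_shoot_number))
  # law of large numbers on a record with negligible truncation
  big <- pseudo_replicates(validate_growth_dataset(as.data.frame(d)[1, ]),
                           seed = 6, n_draws = 10000)
  sd_rep <- row1$se_node_number * sqrt(row1$n)
  expect_lt(abs(mean(big$node_number) - row1$mean_node_number),
            3 * sd_rep / sqrt(10000))
})

test_that("latin hypercube designs stratify every dimension", {
  des <- lhs_design(40, seed = 8)
  expect_equal(dim(des), c(40L, 5L))
  b <- input_bounds()
  for (j in seq_len(5)) {
    u <- (des[[j]] - b[1, j]) / (b[2, j] - b[1, j])
    expect_true(all(u >= 0 & u <= 1))
    # exactly one point per stratum
    expect_equal(sort(unique(floor(u * 40))), 0:39)
  }
  expect_identical(lhs_design(40, seed = 8), lhs_design(40, seed = 8))
})
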