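test_that("Box-Cox lambda matches the profile-likelihood oracle", {
  skip_if_not_installed("MASS")
  set.seed(11)
  x <- exp(rnorm(500))           # lognormal: true lambda 0
  t <- boxcox_fit(x)
  expect_equal(t$shift, 0)
  expect_lt(abs(t$lambda), 0.1)
  # independent oracle: MASS profile over a fine grid
  bx <- MASS::boxcox(stats::lm(x ~ 1, data = data.frame(x = x), y = TRUE,
                               qr = TRUE),
                     lambda = seq(-2, 2, 1 / 400), plotit = FALSE)
  expect_lt(abs(t$lambda - bx$x[which.max(bx$y)]), 0.01)
  # a second shape: chi-square (right-skewed, lambda ~ 1/3)
  y <- rchisq(500, df = 3)
  t2 <- boxcox_fit(y)
  bx2 <- MASS::boxcox(stats::lm(y ~ 1, data = data.frame(y = y), y = TRUE,
                                qr = TRUE),
                      lambda = seq(-2, 2, 1 / 400), plotit = FALSE)
  expect_lt(abs(t2$lambda - bx2$x[which.max(bx2$y)]), 0.01)
})

test_that("zeros get a scale-aware shift and the transform stays defined", {
  y <- trait_matrix(fixture_data(), "root_length")$y
  expect_true(any(y == 0))
  t <- boxcox_fit(y)
  expect_equal(t$shift, min(y[y > 0]) / 2)
  expect_true(all(is.finite(boxcox_apply(t, y))))
  expect_error(boxcox_fit(rep(3, 10)), "constant")
  expect_error(boxcox_fit(c(1, 2)), "at least 3")
})

test_that("apply/invert follow the power-transform formulas exactly", {
  t1 <- structure(list(lambda = 1, shift = 0), class = "boxcox_transform")
  expect_equal(boxcox_apply(t1, c(2, 5, 9)), c(1, 4, 8))
  t0 <- structure(list(lambda = 0, shift = 0), class = "boxcox_transform")
  expect_equal(boxcox_apply(t0, c(1, 10, 100)),
               c(0, 2.302585, 4.605170), tolerance = 1e-6)
  set.seed(12)
  x <- rgamma(50, 2)
  t <- boxcox_fit(x)
  expect_equal(boxcox_invert(t, boxcox_apply(t, x)), x, tolerance = 1e-9)
  # out-of-image values are a domain error
  tneg <- structure(list(lambda = -0.5, shift = 0),
                    class = "boxcox_transform")
  expect_error(boxcox_invert(tneg, 3), "domain error")
})

test_that("Box-Cox reduces skewness of right-skewed samples", {
  skewness <- function(v) mean((v - mean(v))^3) / stats::sd(v)^3
  set.seed(13)
  for (r in 1:5) {
    x <- exp(rnorm(300, sd = 0.8)) + r
    t <- boxcox_fit(x)
    expect_lt(abs(skewness(boxcox_apply(t, x))), abs(skewness(x)))
  }
})

test_that("fold plans partition, balance, and reproduce", {
  fp <- make_folds(66, k = 5, repeats = 10, seed = 7)
  expect_length(fp$pairs, 50)
  sizes <- vapply(fp$pairs, function(p) length(p$test), integer(1))
  expect_true(all(sizes %in% c(13L, 14L)))
  for (p in fp$pairs) {
    expect_length(intersect(p$train, p$test), 0)
    expect_setequal(c(p$train, p$test), 1:66)
  }
  # within each repeat the test sets partition 1..n
  for (r in 1:10) {
    tests <- unlist(lapply(Filter(function(p) p$repeat_id == r, fp$pairs),
                           `[[`, "test"))
    expect_setequal(tests, 1:66)
    expect_length(tests, 66)
  }
  expect_identical(fp, make_folds(66, 5, 10, seed = 7))
  expect_false(identical(fp$pairs, make_folds(66, 5, 10, seed = 8)$pairs))
  expect_error(make_folds(4, k = 5), "k <= n")
  # exportable long form
  df <- as.data.frame(fp)
  expect_equal(nrow(df), 50 * 66)
  expect_setequal(df$role, c("train", "test"))
})

test_that("PCA screen flags planted outliers and nothing else", {
  X <- trait_matrix(fixture_data(), "shoot_length")$X
  expect_equal(sum(pca_outlier_flags(X)), 0)
  flags <- pca_outlier_flags(rbind(X, 10 * apply(X, 2, max)))
  expect_true(flags[67])
  expect_equal(sum(flags[1:66]), 0)
  # duplicated rows are not outliers
  expect_equal(sum(pca_outlier_flags(X[rep(1:11, 6), ])), 0)
  expect_error(pca_outlier_flags(X[1:3, ]), "more rows")
})
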