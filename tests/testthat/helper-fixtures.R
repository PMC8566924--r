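# Shared fixtures built in code.

fixture_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- growth_data()
    cache
  }
})

# a tiny smooth 2-D surface and bounds for fast model tests
toy_bounds <- function() {
  b <- rbind(lower = c(0, 0), upper = c(100, 100))
  colnames(b) <- c("x1", "x2")
  b
}

toy_surface <- function(noise_cv = 0) {
  growth_surface(seed = 3, centers = c(40, 60), widths = c(35, 35),
                 amplitudes = c(100, 80), baseline = 20,
                 noise_cv = noise_cv, bounds = toy_bounds())
}

toy_xy <- function(n = 120, seed = 4) {
  surf <- toy_surface()
  set.seed(seed)
  X <- cbind(x1 = runif(n, 0, 100), x2 = runif(n, 0, 100))
  list(X = X, y = predict(surf, X), surface = surf)
}

# 5-D benchmark objectives for the optimizers
sphere_problem <- function() {
  optim_problem(function(X) -rowSums((X - 0.3)^2), rep(0, 5), rep(1, 5),
                vectorized = TRUE)
}

# broad global bump at 0.65 with a sharp deceptive decoy at 0.15; the bumps
# are effectively disjoint so the maximum is 1 to well below 1e-6
two_bump_problem <- function() {
  optim_problem(function(X) {
    exp(-rowSums((X - 0.65)^2) / (2 * 0.55^2)) +
      0.6 * exp(-rowSums((X - 0.15)^2) / (2 * 0.15^2))
  }, rep(0, 5), rep(1, 5), vectorized = TRUE)
}
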