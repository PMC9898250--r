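two_gauss_sample <- function(n, w1, sep = 8, seed = 1) {
  set.seed(seed)
  n1 <- rbinom(1, n, w1)
  rbind(cbind(rnorm(n1), rnorm(n1)),
        cbind(rnorm(n - n1) + sep, rnorm(n - n1)))
}

test_that("single-Gaussian data yields a compact fit near the truth", {
  set.seed(2)
  x <- cbind(rnorm(20000, 3, 1), rnorm(20000, -1, 1))
  g <- fit_density(x, k_min = 1, k_max = 3, seed = 1)
  mu <- colSums(g$means * g$weights)
  se <- 1 / sqrt(20000)
  expect_lt(abs(mu[1] - 3), 3 * se)
  expect_lt(abs(mu[2] + 1), 3 * se)
  # density normalisation by wide quadrature
  gx <- seq(-6, 12, length.out = 200); gy <- seq(-10, 8, length.out = 200)
  pts <- as.matrix(expand.grid(gx, gy))
  quad <- sum(gmm_density(g, pts)) * diff(gx)[1] * diff(gy)[1]
  expect_equal(quad, 1, tolerance = 1e-3)
})

test_that("well-separated equal mixture recovers half/half weights", {
  x <- two_gauss_sample(30000, 0.5, seed = 3)
  g <- fit_density(x, k_min = 2, k_max = 3, seed = 1)
  top2 <- sort(g$weights, decreasing = TRUE)[1:2]
  expect_lt(abs(top2[1] - 0.5), 0.02)
  expect_lt(abs(top2[2] - 0.5), 0.02)
})

test_that("fits are deterministic under a fixed seed and permutation-invariant", {
  x <- two_gauss_sample(5000, 0.7, seed = 4)
  g1 <- fit_density(x, k_min = 2, k_max = 4, seed = 9)
  g2 <- fit_density(x, k_min = 2, k_max = 4, seed = 9)
  expect_identical(g1$weights, g2$weights)
  expect_identical(g1$means, g2$means)
  ls1 <- free_energy_grid(g1, ranges = list(c(-5, 13), c(-5, 5)))
  # permuting samples leaves the landscape unchanged (samples are put in
  # canonical order before folds and initialisation are drawn)
  set.seed(1); xp <- x[sample(nrow(x)), ]
  g3 <- fit_density(xp, k_min = 2, k_max = 4, seed = 9)
  ls3 <- free_energy_grid(g3, ranges = list(c(-5, 13), c(-5, 5)))
  expect_identical(ls1$F, ls3$F)
})

test_that("free-energy grids convert density, shift the minimum and scale with kT", {
  g <- structure(list(weights = c(0.7, 0.3),
                      means = rbind(c(0, 0), c(8, 0)),
                      covs = array(rep(diag(2), 2), c(2, 2, 2)), k = 2L),
                 class = "abc_gmm")
  ls <- free_energy_grid(g, ranges = list(c(-5, 13), c(-5, 5)))
  expect_equal(ls$quadrature, 1, tolerance = 1e-3)
  expect_true(all(ls$F >= 0, na.rm = TRUE))
  # minima at the two means differ by ln(w1/w2)
  ls <- find_core_states(ls)
  expect_equal(length(ls$populations), 2)
  f_min <- sort(vapply(1:2, function(s) min(ls$F[ls$states == s],
                                            na.rm = TRUE), numeric(1)))
  expect_equal(f_min[2] - f_min[1], log(0.7 / 0.3), tolerance = 0.02)
  ls2 <- free_energy_grid(g, ranges = list(c(-5, 13), c(-5, 5)), kT = 2)
  expect_equal(ls2$F, 2 * ls$F, tolerance = 1e-9)
  expect_equal(ls$populations[order(ls$populations)], c(0.3, 0.7),
               tolerance = 0.005)
})

test_that("core-state detection handles single basins and flat grids", {
  g1 <- structure(list(weights = 1, means = rbind(c(0, 0)),
                       covs = array(diag(2), c(2, 2, 1)), k = 1L),
                  class = "abc_gmm")
  ls <- find_core_states(free_energy_grid(g1, ranges = list(c(-4, 4),
                                                            c(-4, 4))))
  expect_equal(length(ls$populations), 1)
  expect_equal(ls$populations, 1)
  # minimum cell is at the mean
  ix <- which(ls$F == 0, arr.ind = TRUE)
  expect_lt(abs(ls$x[ix[1]]), 0.1)
  expect_lt(abs(ls$y[ix[2]]), 0.1)
  expect_equal(sum(ls$populations), 1)
})

test_that("mixture recovery: free-energy gaps match log weight ratios", {
  for (w1 in c(0.7, 0.9)) {
    x <- two_gauss_sample(50000, w1, seed = round(100 * w1))
    g <- fit_density(x, k_min = 2, k_max = 3, seed = 1)
    ls <- find_core_states(free_energy_grid(g, ranges = list(c(-5, 13),
                                                             c(-5, 5))))
    expect_equal(length(ls$populations), 2)
    f_min <- vapply(1:2, function(s) min(ls$F[ls$states == s],
                                         na.rm = TRUE), numeric(1))
    expect_equal(abs(diff(f_min)), log(w1 / (1 - w1)), tolerance = 0.1)
  }
})

test_that("EM log-likelihood agrees with an independent GMM implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attach
  x <- two_gauss_sample(4000, 0.7, seed = 10)
  g <- fit_density(x, k_min = 2, k_max = 2, max_iter = 200, seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "VVV", verbose = FALSE)
  # both converge to the same two-component optimum
  expect_lt(abs(g$loglik - mc$loglik) / abs(mc$loglik), 1e-3)
  expect_equal(sort(g$weights), sort(mc$parameters$pro), tolerance = 0.01)
})

test_that("convergence profiles flag drift and accept stationary series", {
  set.seed(6)
  iid <- rnorm(5000, 10, 2)
  cp <- convergence_profile(iid, 5)
  expect_true(cp$converged)
  expect_lt(abs(tail(cp$cumulative_mean, 1) - 10), 3 * 2 / sqrt(5000))
  drift <- seq(0, 50, length.out = 5000) + rnorm(5000, 0, 0.5)
  expect_false(convergence_profile(drift, 5)$converged)
  const <- rep(3, 100)
  cpc <- convergence_profile(const, 4)
  expect_true(all(cpc$blocks$mean == 3))
  expect_error(convergence_profile(1:5, 4), "fewer than 2")
})
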