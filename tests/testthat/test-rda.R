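test_that("standardize centres and scales, and names offending columns", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(m)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(unname(colMeans(z)), c(0, 0))
  expect_equal(unname(apply(z, 2, stats::sd)), c(1, 1))
  # idempotent up to numerical tolerance
  expect_equal(unclass(standardize(z)), unclass(z), ignore_attr = TRUE)

  expect_error(standardize(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("rda collapses to simple-regression r-squared in the univariate case", {
  set.seed(21)
  x <- rnorm(40)
  y <- 1.5 * x + rnorm(40)
  r2 <- summary(stats::lm(y ~ x))$r.squared
  expect_lt(abs(rda(y, x)$constrained_fraction - r2), 1e-10)
})

test_that("rda explains nothing for orthogonal constraints and everything for exact ones", {
  n <- 32
  x <- rep(c(-1, 1), n / 2)
  y <- rep(c(-1, -1, 1, 1), n / 4)  # orthogonal to x by construction
  expect_lt(rda(y, x)$constrained_fraction, 1e-20)

  z <- rnorm(n)
  expect_equal(rda(2 * z - 1, z)$constrained_fraction, 1)
})

test_that("rda matches the explicit projection-matrix oracle on a multivariate fixture", {
  set.seed(50)
  n <- 50
  X <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("x1", "x2")))
  Y <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("y1", "y2", "y3")))
  r <- rda(Y, X)
  expect_lt(abs(r$constrained_fraction - projector_fraction(Y, X)), 1e-12)
  # eigenvalue sum over total variance equals the constrained fraction
  expect_equal(sum(r$canonical_eigenvalues) / r$total_variance,
               r$constrained_fraction, tolerance = 1e-12)
  expect_true(all(diff(r$canonical_eigenvalues) <= 1e-12))
})

test_that("rda agrees with the vegan reference implementation", {
  set.seed(60)
  n <- 45
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  Y <- cbind(y1 = X$a + rnorm(n), y2 = 0.5 * X$b + rnorm(n))
  ours <- rda(Y, X)
  ref <- vegan::rda(Y ~ a + b, data = X)
  expect_equal(ours$constrained_fraction,
               vegan::RsquareAdj(ref)$r.squared, tolerance = 1e-10)
  expect_equal(ours$canonical_eigenvalues, unname(ref$CCA$eig), tolerance = 1e-10)

  ref_F <- vegan::anova.cca(ref, permutations = 49)$F[1]
  expect_equal(ours$pseudo_F, ref_F, tolerance = 1e-8)
})

test_that("rda is invariant to affine rescaling of constraints and flags collinearity", {
  set.seed(61)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("p", "q")))
  y <- X[, 1] - X[, 2] + rnorm(30)
  f1 <- rda(y, X)$constrained_fraction
  X2 <- X
  X2[, 1] <- 100 * X[, 1] - 7
  X2[, 2] <- -0.01 * X[, 2] + 3
  expect_equal(rda(y, X2)$constrained_fraction, f1, tolerance = 1e-12)

  Xdup <- cbind(X, r = X[, 1])
  expect_error(rda(y, Xdup), "collinear")
})

test_that("partial_rda with no covariates reduces to rda and handles nested constraints", {
  set.seed(62)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(40)
  expect_equal(unclass(partial_rda(y, X))[names(unclass(rda(y, X)))],
               unclass(rda(y, X)))

  # constraints inside the covariate span explain nothing further
  Z <- cbind(z1 = X[, 1], z2 = rnorm(40))
  pr <- partial_rda(y, X[, 1, drop = FALSE], Z = Z)
  expect_equal(pr$constrained_fraction, 0)
})

test_that("partial_rda matches the closed-form partial correlation", {
  set.seed(63)
  n <- 200
  z <- rnorm(n)
  x1 <- 0.5 * z + rnorm(n)
  y <- x1 + z + rnorm(n)
  pr <- partial_rda(y, x1, Z = z)
  # squared partial correlation of y and x1 given z
  rxy <- cor(y, x1); rxz <- cor(y, z); r12 <- cor(x1, z)
  partial_r2 <- ((rxy - rxz * r12) / sqrt((1 - rxz^2) * (1 - r12^2)))^2
  expect_equal(pr$constrained_fraction, partial_r2, tolerance = 1e-10)

  # and the total-scale fraction is the semipartial (part) correlation squared
  semipartial_r2 <- ((rxy - rxz * r12) / sqrt(1 - r12^2))^2
  expect_equal(pr$constrained_fraction_total, semipartial_r2, tolerance = 1e-10)
})

test_that("variance partitioning recovers orthogonal contributions exactly", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)           # orthogonal to x1
  y <- 0.8 * x1 + 0.4 * x2 + rep(c(0.1, -0.1), each = n / 2)
  vp <- variance_partition(y, cbind(x1 = x1, x2 = x2), permutations = 99, seed = 3)
  r2_1 <- summary(stats::lm(scale(y) ~ scale(x1)))$r.squared
  r2_2 <- summary(stats::lm(scale(y) ~ scale(x2)))$r.squared
  expect_equal(vp$unique_fraction, c(r2_1, r2_2), tolerance = 1e-10)
  expect_equal(vp$shared_fraction, c(0, 0), tolerance = 1e-10)
  expect_equal(attr(vp, "total_explained"), r2_1 + r2_2, tolerance = 1e-10)
  # additivity: total = sum of uniques + jointly shared
  expect_equal(attr(vp, "total_explained"),
               sum(vp$unique_fraction) + attr(vp, "shared_total"),
               tolerance = 1e-12)

  expect_error(variance_partition(y, cbind(x1 = x1, x1b = x1), permutations = 9),
               "collinear")
  expect_error(variance_partition(y, cbind(x1 = x1), permutations = 9),
               "at least two")
})

test_that("correlated predictors yield a positive shared fraction that sums correctly", {
  set.seed(64)
  n <- 120
  z <- rnorm(n)
  x1 <- z + 0.5 * rnorm(n)
  x2 <- z + 0.5 * rnorm(n)
  y <- x1 + x2 + rnorm(n)
  vp <- variance_partition(y, cbind(x1 = x1, x2 = x2), permutations = 99, seed = 5)
  expect_true(all(vp$shared_fraction > 0))
  expect_equal(vp$marginal_fraction, vp$unique_fraction + vp$shared_fraction,
               tolerance = 1e-12)
  expect_true(all(vp$p_value <= 0.05))  # both effects are strong
})

test_that("permutation p-values have the add-one support and detect strong signal", {
  set.seed(65)
  x <- rnorm(50)
  strong <- 2 * x + 0.01 * rnorm(50)
  pt <- permutation_test(strong, x, n_perm = 999, seed = 9)
  expect_equal(pt$p_value, 1 / 1000)

  # support check at 19 permutations: p in {1/20, ..., 20/20}
  ps <- vapply(1:40, function(i) {
    permutation_test(rnorm(20), rnorm(20), n_perm = 19, seed = i)$p_value
  }, numeric(1))
  expect_true(all(abs(ps * 20 - round(ps * 20)) < 1e-12))
  expect_true(all(ps >= 1 / 20 & ps <= 1))
})

test_that("permutation test is deterministic in its seed", {
  set.seed(66)
  y <- rnorm(40); x <- rnorm(40); z <- rnorm(40)
  a <- permutation_test(y, x, Z = z, n_perm = 199, seed = 12)
  b <- permutation_test(y, x, Z = z, n_perm = 199, seed = 12)
  expect_identical(a, b)
})
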