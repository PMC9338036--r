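test_that("bin_means uses half-open classes and conserves counts", {
  b <- bin_means(c(0.2, 0.7), c(0.4, 0.6), bin_width = 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$bin_left, 0)
  expect_equal(b$mean_y, 0.5)

  # a value on the boundary belongs to the right-hand class
  b2 <- bin_means(c(0.5, 1.0), c(1, 2), bin_width = 1)
  expect_equal(b2$bin_left, c(0, 1))
  expect_equal(b2$n, c(1L, 1L))

  set.seed(8)
  x <- runif(500, 0, 10)
  b3 <- bin_means(x, x / 10, bin_width = 1)
  expect_equal(sum(b3$n), 500)
  # mean of y = x/10 within [k, k+1) is close to the class centre / 10
  expect_equal(b3$mean_y, b3$bin_center / 10, tolerance = 0.02)

  expect_error(bin_means(1:3, 1:2, 1), "same length")
})

test_that("loess_fit reproduces constants and straight lines", {
  x <- seq(0, 10, length.out = 25)
  const <- loess_fit(x, rep(3.5, 25), span = 0.4, degree = 2,
                     eval_x = c(0, 2.7, 10))
  expect_equal(const$fitted, rep(3.5, 3), tolerance = 1e-10)

  lin <- loess_fit(x, 2 * x + 1, span = 0.6, degree = 1,
                   eval_x = seq(0.5, 9.5, length.out = 19))
  expect_equal(lin$fitted, 2 * seq(0.5, 9.5, length.out = 19) + 1,
               tolerance = 1e-9)

  expect_error(loess_fit(c(1, 1, 2), c(1, 2, 3), degree = 2), "distinct x")
})

test_that("loess_fit agrees with the brute-force weighted-least-squares oracle", {
  set.seed(31)
  x <- sort(runif(45, 0, 6))
  y <- sin(x) + rnorm(45, 0, 0.05)
  grid <- seq(0.1, 5.9, length.out = 40)
  for (conf in list(list(span = 0.3, degree = 2), list(span = 0.5, degree = 1))) {
    fit <- loess_fit(x, y, span = conf$span, degree = conf$degree, eval_x = grid)
    expected <- vapply(grid, function(x0)
      loess_oracle(x, y, conf$span, conf$degree, x0), numeric(1))
    expect_lt(max(abs(fit$fitted - expected)), 1e-8)
  }
})

test_that("loess at span 1, degree 1 on linear data equals the OLS line", {
  x <- seq(1, 20)
  y <- -0.7 * x + 3
  ols <- stats::lm(y ~ x)
  fit <- loess_fit(x, y, span = 1, degree = 1, eval_x = c(2.5, 10, 17.5))
  expect_equal(fit$fitted, unname(predict(ols, data.frame(x = c(2.5, 10, 17.5)))),
               tolerance = 1e-9)
})

test_that("pearson_correlation matches hand-computed values and is symmetric", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_correlation(1:10, -(1:10))$r, -1)

  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 3, 5, 4)
  expect_equal(pearson_correlation(x, y)$r, 0.8)

  set.seed(4)
  a <- rnorm(30); b <- rnorm(30)
  r1 <- pearson_correlation(a, b)
  r2 <- pearson_correlation(b, a)
  expect_equal(r1$r, r2$r)
  expect_equal(r1$p_value, r2$p_value)
  # affine invariance, sign follows the slope
  expect_equal(pearson_correlation(3 * a - 2, b)$r, r1$r)
  expect_equal(pearson_correlation(-a, b)$r, -r1$r)

  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "three")
})

test_that("percentile_trim keeps the interpolated central band", {
  v <- 1:100
  kept <- percentile_trim(v, 2, 98)
  expect_equal(range(attr(kept, "bounds")), c(2.98, 98.02))
  expect_equal(as.integer(kept), 3:98)

  expect_equal(as.numeric(percentile_trim(v, 0, 100)), v)
  same <- percentile_trim(rep(0.4, 20), 2, 98)
  expect_length(same, 20)

  df <- data.frame(id = 1:100, val = v)
  expect_equal(percentile_trim(v, 2, 98, data = df)$id, 3:98)
})

test_that("family_summary applies the strict size threshold and correct statistics", {
  one_fam <- data.frame(family = "Asteraceae", lifeform = "herb",
                        dcwl = rep(0.42, 26))
  fs <- family_summary(one_fam, min_species = 25)
  expect_equal(nrow(fs), 1)
  expect_equal(fs$median, 0.42)
  expect_equal(fs$iqr, 0)
  expect_equal(fs$n, 26L)

  # exactly at the threshold: excluded ("more than" is strict)
  at_threshold <- one_fam[1:25, ]
  expect_equal(nrow(family_summary(at_threshold, min_species = 25)), 0)

  sp <- generate_study(seed = 7)$species
  fs2 <- family_summary(sp)
  # independent group-by oracle for the retained family set
  tab <- table(sp$family)
  expect_setequal(attr(fs2, "families"), names(tab)[tab > 25])
  asters <- sp$dcwl[sp$family == attr(fs2, "families")[1] &
                      sp$lifeform == "herb"]
  if (length(asters)) {
    row <- fs2[fs2$family == attr(fs2, "families")[1] & fs2$group == "herbs", ]
    expect_equal(row$median, unname(stats::median(asters)))
  }
})

test_that("lifeform comparison is a Welch test with sane degenerate behaviour", {
  df <- data.frame(lifeform = rep(c("tree", "herb"), each = 4),
                   dcwl = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  # identical groups with zero variance make t undefined; perturb minimally
  df$dcwl <- df$dcwl + rep(c(0, 1e-9, 0, -1e-9), 2)
  cmp <- lifeform_comparison(df)
  expect_equal(cmp$t_stat, 0)

  df2 <- data.frame(lifeform = rep(c("tree", "herb"), each = 2),
                    dcwl = c(0, 1, 0, 1))
  cmp2 <- lifeform_comparison(df2)
  expect_equal(cmp2$mean_a - cmp2$mean_b, 0)
  expect_equal(cmp2$t_stat, 0)

  expect_error(lifeform_comparison(
    data.frame(lifeform = c("tree", "herb", "herb"), dcwl = c(0.5, 0.4, 0.6))),
    "at least two")

  # cross-check against stats::t.test on a generated study
  sp <- generate_study(study_params(n_species = 300, n_sites = 50), seed = 2)$species
  cmp3 <- lifeform_comparison(sp)
  tt <- stats::t.test(sp$dcwl[sp$lifeform != "herb"], sp$dcwl[sp$lifeform == "herb"])
  expect_equal(cmp3$t_stat, unname(tt$statistic))
  expect_equal(cmp3$p_value, tt$p.value)
  expect_equal(cmp3$df, unname(tt$parameter))
})

test_that("Welch p-values are uniform under label permutation", {
  set.seed(55)
  n <- 60
  vals <- stats::rnorm(n)
  labs <- rep(c("tree", "herb"), each = n / 2)
  pvals <- replicate(2000, {
    lifeform_comparison(data.frame(lifeform = sample(labs), dcwl = vals))$p_value
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("gradient_curve combines class means with a loess on those means", {
  sp <- generate_study(seed = 7)$species
  gc <- gradient_curve(sp, "temp_warmest_quarter")
  expect_equal(attr(gc$bins, "bin_width"), 1)
  expect_equal(sum(gc$bins$n), nrow(sp))
  expect_true(all(is.finite(gc$loess$fitted)))
  # curve ends reflect the rising trend
  expect_gt(utils::tail(gc$loess$fitted, 1), gc$loess$fitted[1])
  expect_error(gradient_curve(sp, "annual_precip"), "bin width")
})
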