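test_that("outlier detection uses an inclusive k-SD cut on the sample moments", {
  # 20 points at 0 and one far point: choose it to sit exactly at 3 SD
  x <- c(rep(0, 10), rep(1, 10), 10)
  m <- mean(x); s <- sd(x)
  d <- abs(x - m) / s
  expect_true(d[21] > 3)
  expect_identical(detect_outliers(x, k = 3), 21L)
  # inclusive boundary: c(-1, 0, 1) has mean 0 and SD exactly 1, so at
  # k = 1 the extreme points sit exactly on the cut and are flagged
  expect_identical(detect_outliers(c(-1, 0, 1), k = 1), c(1L, 3L))
  # no variance: nothing is an outlier
  expect_identical(detect_outliers(rep(5, 10)), integer(0))
  expect_error(detect_outliers(c(1, 2)), "at least 3")
})

test_that("log10 transform maps the documented clinical range", {
  expect_equal(apply_transform_log10(c(0.01, 4.01)),
               c(-2, log10(4.01)))
  expect_equal(apply_transform_log10(4.01), 0.60314437, tolerance = 1e-6)
  expect_error(apply_transform_log10(c(1, 0)), "positive")
  expect_error(apply_transform_log10(c(1, -2)), "positive")
})

test_that("transform selection prefers identity for normal data and log10 for lognormal", {
  set.seed(41)
  xn <- rnorm(200)
  expect_identical(select_transform(xn)$label, "identity")
  xl <- exp(rnorm(200, 0, 1.5))
  sel <- select_transform(xl)
  expect_true(sel$label %in% c("log10", "inverse"))
  # log10 of lognormal is exactly normal in distribution; check it wins
  expect_identical(sel$label, "log10")
  expect_false(sel$reverses_order)
  expect_equal(sel$x, log10(xl))
})

test_that("pearson matches cor.test to machine precision", {
  set.seed(42)
  x <- rnorm(60)
  y <- 0.5 * x + rnorm(60)
  res <- pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_identical(res$n, 60L)
  expect_equal(res$df, 58)
  # NA pairs are dropped pairwise
  x[3] <- NA
  expect_identical(pearson(x, y)$n, 59L)
})

test_that("published correlation strengths reproduce their significance levels", {
  # r = 0.344 at n = 51 -> p ~= 0.013 (two-tailed)
  r <- 0.344; n <- 51
  t <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t), n - 2)
  expect_equal(round(p, 3), 0.013)
  # partial r = -0.433 at df = 49 -> p ~= 0.002
  r2 <- -0.433; df <- 49
  t2 <- r2 * sqrt(df / (1 - r2^2))
  p2 <- 2 * pt(-abs(t2), df)
  expect_lt(p2, 0.0025)
  expect_gt(p2, 0.0015)
})

test_that("partial correlation with no covariates reduces to pearson", {
  set.seed(43)
  x <- rnorm(40); y <- rnorm(40)
  a <- pearson(x, y)
  b <- partial_corr(x, y, covariates = NULL)
  expect_equal(a, b)
  # constant covariate is rejected as collinear with the intercept
  expect_error(partial_corr(x, y, covariates = rep(1, 40)), "collinear")
})

test_that("partial correlation uses df = n - 2 - k and removes a linear confound", {
  set.seed(44)
  n <- 52
  age <- rnorm(n, 50, 10)
  x <- 2 * age + rnorm(n)
  y <- -3 * age + rnorm(n)
  # marginally strongly correlated through age alone
  expect_lt(pearson(x, y)$r, -0.9)
  res <- partial_corr(x, y, covariates = age)
  expect_equal(res$df, 49)  # n - 2 - k with one covariate
  expect_lt(abs(res$r), 0.3)
  # oracle: correlation of lm residuals with manual t-test
  rx <- resid(lm(x ~ age)); ry <- resid(lm(y ~ age))
  r_o <- cor(rx, ry)
  expect_equal(res$r, r_o, tolerance = 1e-12)
  t_o <- r_o * sqrt((n - 3) / (1 - r_o^2))
  expect_equal(res$p, 2 * pt(-abs(t_o), n - 3), tolerance = 1e-12)
})

test_that("single-block HMR equals the squared Pearson correlation", {
  set.seed(45)
  x <- rnorm(50); y <- 1.2 * x + rnorm(50)
  h <- hmr(y, list(cbind(x = x)))
  expect_equal(h$stages$r_squared[1], cor(x, y)^2, tolerance = 1e-12)
  expect_equal(h$stages$r_squared_change[1], h$stages$r_squared[1])
  # F change test equals the overall model F test for one block
  f_oracle <- summary(lm(y ~ x))$fstatistic
  expect_equal(h$stages$f_change[1], unname(f_oracle[1]), tolerance = 1e-10)
  expect_equal(h$overall_p, h$stages$p_f_change[1], tolerance = 1e-12)
})

test_that("HMR stages match the anova() nested-model oracle", {
  set.seed(46)
  n <- 80
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 0.5 * d$a - 0.7 * d$b + 0.3 * d$c + rnorm(n)
  h <- hmr("y", list("a", "b", "c"), data = d)
  m1 <- lm(y ~ a, d); m2 <- lm(y ~ a + b, d); m3 <- lm(y ~ a + b + c, d)
  expect_equal(h$stages$r_squared,
               c(summary(m1)$r.squared, summary(m2)$r.squared,
                 summary(m3)$r.squared), tolerance = 1e-12)
  expect_equal(h$stages$adj_r_squared,
               c(summary(m1)$adj.r.squared, summary(m2)$adj.r.squared,
                 summary(m3)$adj.r.squared), tolerance = 1e-12)
  # pairwise anova uses the larger model's residual variance, exactly the
  # F-change denominator at each stage
  a12 <- anova(m1, m2); a23 <- anova(m2, m3)
  expect_equal(h$stages$f_change[2:3], c(a12$F[2], a23$F[2]),
               tolerance = 1e-10)
  expect_equal(h$stages$p_f_change[2:3],
               c(a12$`Pr(>F)`[2], a23$`Pr(>F)`[2]), tolerance = 1e-10)
})

test_that("an orthogonal added block contributes zero R-squared change", {
  set.seed(49)
  n <- 64
  a <- rep(c(-1, 1), n / 2)
  b <- rep(c(-1, -1, 1, 1), n / 4)   # orthogonal to a
  e <- resid(lm(rnorm(n) ~ b))       # noise orthogonal to b
  y <- a + e
  h <- hmr(y, list(cbind(a = a), cbind(b = b)))
  expect_equal(h$stages$r_squared_change[2], 0, tolerance = 1e-12)
})

test_that("standardized betas are invariant to predictor and response rescaling", {
  set.seed(47)
  n <- 70
  d <- data.frame(a = rnorm(n, 100, 15), b = rnorm(n, 0, 0.01))
  d$y <- 0.4 * scale(d$a)[, 1] - 0.5 * scale(d$b)[, 1] + rnorm(n)
  h1 <- hmr("y", list(c("a", "b")), data = d)
  d2 <- transform(d, a = a / 1000, b = b * 500, y = y * 7)
  h2 <- hmr("y", list(c("a", "b")), data = d2)
  expect_equal(h1$final$beta_std, h2$final$beta_std, tolerance = 1e-10)
  expect_equal(h1$final$p, h2$final$p, tolerance = 1e-10)
})

test_that("adjusted R-squared follows the small-sample correction", {
  # published table: R2 = 0.322, n = 52, 3 predictors -> adj ~= 0.280
  adj <- 1 - (1 - 0.322) * (52 - 1) / (52 - 3 - 1)
  expect_equal(round(adj, 3), 0.280)
})

test_that("HMR rejects collinear blocks with a stage-numbered error", {
  set.seed(48)
  a <- rnorm(30)
  expect_error(hmr(rnorm(30), list(cbind(a = a), cbind(a2 = 2 * a))),
               "stage 2")
})
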