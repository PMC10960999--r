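test_that("correlation matrix is exact, symmetric and starred correctly", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 1, 2))
  p <- pcc_matrix(d, c("x", "y", "z"))
  expect_equal(p$r["x", "y"], 1)
  expect_identical(p$r, t(p$r))
  expect_equal(diag(p$r), c(x = 1, y = 1, z = 1))
  expect_true(all(abs(p$r) <= 1 + 1e-12, na.rm = TRUE))
  td <- tidy(p)
  expect_equal(nrow(td), 3)
  expect_equal(td$signif[td$var1 == "x" & td$var2 == "y"], "**")
})

test_that("zero-variance variables are masked with a message", {
  d <- tibble::tibble(x = 1:5, y = rep(2, 5))
  expect_message(p <- pcc_matrix(d, c("x", "y")), "masked")
  expect_true(is.na(p$r["x", "y"]))
})

test_that("null correlations reject near the nominal 5 percent rate", {
  set.seed(31)
  hits <- replicate(400, {
    d <- tibble::tibble(x = rnorm(40), y = rnorm(40))
    tidy(pcc_matrix(d, c("x", "y")))$p_value < 0.05
  })
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.11)
})

test_that("covariate ranking recovers a planted correlation order", {
  set.seed(7)
  n <- 400
  lwc <- runif(n, 0.6, 0.8)
  d <- tibble::tibble(
    stage = rep(c("booting", "flowering"), each = n / 2),
    LWC = lwc,
    A = lwc + rnorm(n, 0, 0.03),   # strong
    B = -lwc + rnorm(n, 0, 0.08),  # medium, negative
    C = rnorm(n)                   # none
  )
  rk <- rank_covariates(d, c("A", "B", "C"), k = 3)
  expect_equal(rk$covariate, c("A", "B", "C"))
  expect_lt(rk$mean_r[rk$covariate == "B"], 0) # sign preserved
  rk1 <- rank_covariates(d, c("A", "B", "C"), k = 1)
  expect_equal(nrow(rk1), 1)
})

test_that("descriptive statistics match a naive re-computation", {
  expect_equal(
    descriptive_stats(tibble::tibble(v = c(1, 2, 3)), "v")[-1],
    tibble::tibble(n = 3L, min = 1, max = 3, mean = 2, sd = 1, cv = 0.5))
  d <- tibble::tibble(a = rnorm(20), b = runif(20))
  ds <- descriptive_stats(d, c("a", "b"))
  expect_equal(ds$sd[1], sqrt(sum((d$a - mean(d$a))^2) / 19))
  expect_equal(ds$cv[2], sd(d$b) / mean(d$b))
  dc <- descriptive_stats(tibble::tibble(k = rep(4, 6)), "k")
  expect_equal(dc$sd, 0)
  expect_equal(dc$cv, 0)
})

test_that("outlier flags catch a planted spike and nothing else", {
  d <- tibble::tibble(x = rep(1, 20), y = rnorm(20))
  expect_false(any(flag_outliers(d, "x")))
  d2 <- tibble::tibble(x = c(rnorm(30), 10 * sd(rnorm(30))))
  d2$x[31] <- mean(d2$x[1:30]) + 10 * sd(d2$x[1:30])
  fl <- flag_outliers(d2, "x")
  expect_equal(which(fl), 31L)
  # flag count equals a naive scan
  set.seed(12)
  d3 <- tibble::tibble(a = rt(100, df = 2), b = rnorm(100))
  fl3 <- flag_outliers(d3, c("a", "b"))
  naive <- vapply(seq_len(100), function(i) {
    any(vapply(c("a", "b"), function(v) {
      x <- d3[[v]]
      abs(x[i] - mean(x)) > 3 * sd(x)
    }, logical(1)))
  }, logical(1))
  expect_equal(fl3, naive, ignore_attr = TRUE)
  # IQR rule also runs
  expect_type(flag_outliers(d3, "a", rule = "iqr"), "logical")
})

test_that("normality check behaves under Gaussian and skewed data", {
  set.seed(21)
  expect_equal(nrow(normality_check(tibble::tibble(v = rnorm(3)), "v")), 1)
  rej_norm <- mean(replicate(100, {
    normality_check(tibble::tibble(v = rnorm(200)), "v")$p_value < 0.05
  }))
  rej_skew <- mean(replicate(100, {
    normality_check(tibble::tibble(v = rexp(200)), "v")$p_value < 0.05
  }))
  expect_lt(rej_norm, 0.15)
  expect_gt(rej_skew, 0.9)
  cc <- normality_check(tibble::tibble(v = rep(1, 10)), "v")
  expect_true(is.na(cc$statistic))
})

test_that("VIF and tolerance satisfy their identities and match a refit oracle", {
  set.seed(5)
  n <- 60
  d <- tibble::tibble(x1 = rnorm(n))
  d$x2 <- 0.8 * d$x1 + rnorm(n, 0, 0.5)
  d$x3 <- rnorm(n)
  cl <- collinearity(d, c("x1", "x2", "x3"))
  expect_equal(cl$tolerance * cl$vif, rep(1, 3))
  expect_true(all(cl$vif >= 1))
  # oracle: independent refit of each predictor on the others
  for (k in 1:3) {
    r2j <- summary(lm(d[[k]] ~ ., data = d[-k]))$r.squared
    expect_equal(cl$vif[k], 1 / (1 - r2j), tolerance = 1e-8)
  }
  # orthogonal predictors by construction
  x <- c(-1, 1, -1, 1, -1, 1)
  z <- c(-1, -1, 1, 1, -1, 1) # not orthogonal; use residualized pair
  d2 <- tibble::tibble(x = x, z = resid(lm(z ~ x)))
  cl2 <- collinearity(d2, c("x", "z"))
  expect_equal(cl2$vif, c(1, 1), tolerance = 1e-10)
  # perfect collinearity is flagged as infinite
  d3 <- tibble::tibble(a = rnorm(10))
  d3$b <- d3$a
  cl3 <- collinearity(d3, c("a", "b"))
  expect_true(all(cl3$perfect))
  expect_true(all(is.infinite(cl3$vif)))
})

test_that("Durbin-Watson matches hand values and the lmtest implementation", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(rep(2, 4)), 0)
  expect_error(durbin_watson(rep(0, 4)), class = "ricelwc_error_ratio")
  set.seed(17)
  dw_mean <- mean(replicate(200, durbin_watson(rnorm(200))))
  expect_equal(dw_mean, 2, tolerance = 0.05)
  # cross-check against lmtest on a fitted model's residuals
  d <- tibble::tibble(x = rnorm(50))
  d$y <- 1 + 2 * d$x + rnorm(50, 0, 0.3)
  fit <- lm(y ~ x, data = d)
  expect_equal(durbin_watson(resid(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})
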