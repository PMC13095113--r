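test_that("the ln(x+1) transform is exact and monotone", {
  expect_equal(log1p_transform(0), 0)
  expect_equal(log1p_transform(exp(1) - 1), 1)
  v <- sort(abs(rnorm(50)) * 100)
  expect_true(all(diff(log1p_transform(v)) >= 0))
  expect_error(log1p_transform(c(1, -2)), "negative")
  expect_error(log1p_transform("a"), "numeric")
})

test_that("exact linear data is interpolated with unit weights", {
  x <- 1:20
  X <- cbind(1, x)
  y <- 2 + 3 * x
  fit <- fit_huber_rlm(X, y)
  expect_equal(unname(fit$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$weights, rep(1, 20))
  expect_true(fit$converged)
})

test_that("the Huber fit tracks OLS on clean Gaussian data", {
  withr::with_seed(7, {
    x <- rnorm(200)
    y <- 1 + 2 * x + rnorm(200, sd = 0.5)
  })
  X <- cbind(`(Intercept)` = 1, x = x)
  huber <- fit_huber_rlm(X, y)
  ols <- coef(lm(y ~ x))
  expect_lt(max(abs(huber$coefficients - ols)), 0.05)
})

test_that("the fit agrees with an independent M-estimation implementation", {
  skip_if_not_installed("MASS")
  withr::with_seed(8, {
    x <- rnorm(150)
    y <- 1 + 2 * x + rnorm(150, sd = 0.4)
    y[1:8] <- y[1:8] + 6
  })
  X <- cbind(`(Intercept)` = 1, x = x)
  ours <- fit_huber_rlm(X, y)
  ref <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                   scale.est = "MAD", maxit = 100)
  expect_lt(max(abs(ours$coefficients - coef(ref))), 0.01)
})

test_that("rank-deficient or undersized designs are rejected", {
  X <- cbind(1, 1:10, 2 * (1:10))
  expect_error(fit_huber_rlm(X, rnorm(10)), "rank deficient")
  expect_error(fit_huber_rlm(cbind(1, 1:3, 3:1), rnorm(3)), "more observations")
})

test_that("nested-model F-test: degenerate, OLS-limit and detection cases", {
  withr::with_seed(10, {
    x1 <- rnorm(10); x2 <- rnorm(10)
    y <- 1 + x1 + 2 * x2 + rnorm(10, sd = 0.3)
  })
  Xf <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
  Xr <- Xf[, 1:2, drop = FALSE]
  # identical models give exactly zero
  big <- fit_config(huber_c = 1e9)
  full <- fit_huber_rlm(Xf, y, big)
  same <- compare_models_f(full, full)
  expect_identical(same$fStatistic, 0)
  expect_identical(same$pValue, 1)

  # with unit weights the statistic equals the textbook nested F
  reduced <- fit_huber_rlm(Xr, y, big)
  ours <- compare_models_f(full, reduced)
  rss_f <- sum(resid(lm(y ~ x1 + x2))^2)
  rss_r <- sum(resid(lm(y ~ x1))^2)
  f_hand <- ((rss_r - rss_f) / 1) / (rss_f / (10 - 3))
  expect_equal(ours$fStatistic, f_hand, tolerance = 1e-8)
  expect_equal(ours$dfNumerator, 1)
  expect_equal(ours$dfDenominator, 7)
  expect_equal(ours$pValue, pf(f_hand, 1, 7, lower.tail = FALSE),
               tolerance = 1e-8)

  expect_error(compare_models_f(reduced, full), "not nested")
})

test_that("a strong extra predictor is detected in most replicates", {
  hits <- vapply(1:40, function(s) {
    withr::with_seed(1000 + s, {
      x1 <- rnorm(60); x2 <- rnorm(60)
      y <- 1 + x1 + 1.5 * x2 + rnorm(60, sd = 0.5)
    })
    Xf <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
    full <- fit_huber_rlm(Xf, y)
    reduced <- fit_huber_rlm(Xf[, 1:2], y)
    compare_models_f(full, reduced)$pValue < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Durbin-Watson matches hand evaluation and stays in [0, 4]", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(c(1, 1, 1, 1)), 0)
  expect_error(durbin_watson(c(0, 0, 0)), "all-zero")
  expect_error(durbin_watson(1), "at least two")
  for (s in 1:20) {
    withr::with_seed(s, e <- rnorm(50))
    dw <- durbin_watson(e)
    expect_gte(dw, 0); expect_lte(dw, 4)
  }
})

test_that("Breusch-Pagan equals the auxiliary-regression statistic", {
  # constant squared residuals: exactly zero
  X <- cbind(1, 1:8)
  expect_equal(breusch_pagan(rep(c(1, -1), 4), X)$statistic, 0)

  # six-point fixture against the closed-form auxiliary regression
  x <- c(1, 2, 3, 4, 5, 6)
  e <- c(0.1, -0.2, 0.3, -0.6, 0.8, -1.1)
  got <- breusch_pagan(e, cbind(1, x))
  r2 <- summary(lm(I(e^2) ~ x))$r.squared
  expect_equal(got$statistic, 6 * r2, tolerance = 1e-12)
  expect_equal(got$pValue, pchisq(6 * r2, 1, lower.tail = FALSE))

  skip_if_not_installed("lmtest")
  withr::with_seed(3, {
    xx <- rnorm(100)
    yy <- 1 + xx + rnorm(100) * (1 + 0.6 * abs(xx))
  })
  fit <- lm(yy ~ xx)
  ours <- breusch_pagan(resid(fit), cbind(1, xx))
  ref <- lmtest::bptest(fit, studentize = TRUE)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$pValue, unname(ref$p.value), tolerance = 1e-10)
})

test_that("Shapiro-Wilk wrapper mirrors the reference routine", {
  q <- qnorm(ppoints(50))
  sw <- shapiro_wilk(q)
  expect_gt(sw$W, 0.99)
  bimodal <- c(rnorm(25, -4, 0.2), rnorm(25, 4, 0.2))
  expect_lt(shapiro_wilk(bimodal)$pValue, 0.01)
  expect_error(shapiro_wilk(rep(1, 10)), "zero-variance")
  expect_error(shapiro_wilk(c(1, 2)), "out of range")
})

test_that("outlier flagging matches a direct filter and sorts by magnitude", {
  withr::with_seed(5, {
    x <- rnorm(40)
    y <- 1 + x + rnorm(40, sd = 0.2)
    y[7] <- y[7] + 10
  })
  fit <- fit_huber_rlm(cbind(1, x), y)
  out <- flag_outliers(fit, 3)
  expect_true("7" %in% out$rowLabel)
  direct <- which(abs(fit$residuals / fit$scale) > 3)
  expect_setequal(out$rowLabel, as.character(direct))
  expect_true(all(diff(abs(out$standardizedResidual)) <= 0))
  expect_equal(nrow(flag_outliers(fit, Inf)), 0)

  # single dominant spike is flagged first
  withr::with_seed(6, y2 <- 2 + 3 * (1:30) + rnorm(30, sd = 0.3))
  y2[11] <- y2[11] + 50
  fit2 <- fit_huber_rlm(cbind(1, 1:30), y2)
  out2 <- flag_outliers(fit2, 3)
  expect_equal(out2$rowLabel[1], "11")

  # an interpolating fit has zero scale: outliers undefined
  exact <- fit_huber_rlm(cbind(1, 1:10), 2 + 3 * (1:10))
  expect_error(flag_outliers(exact), "zero scale")
})

test_that("taxonomist-per-species ratios and the population correlation", {
  expect_equal(taxonomists_per_species(59, 1000), 0.059)
  expect_equal(taxonomists_per_species(0, 50), 0)
  expect_warning(r <- taxonomists_per_species(5, 0), "missing")
  expect_true(is.na(r))
  # ordering preserved under common scaling
  expect_lt(taxonomists_per_species(35, 1000), taxonomists_per_species(59, 1000))
  expect_lt(taxonomists_per_species(350, 10000), taxonomists_per_species(590, 10000))

  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  expect_equal(pearson_correlation(1:10, 7 - 2 * (1:10))$r, -1)
  x <- c(1, 2, 4, 5, 9)
  y <- c(2, 1, 5, 6, 8)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  hand_t <- hand_r * sqrt(3 / (1 - hand_r^2))
  got <- pearson_correlation(x, y)
  expect_equal(got$r, hand_r, tolerance = 1e-12)
  expect_equal(got$pValue, 2 * pt(-abs(hand_t), 3), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero-variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
})

test_that("regression_dataset builds the transformed design", {
  g <- generate_regression_data(generator_config(seed = 2, n_orders = 30))
  ds <- regression_dataset(g$matrix)
  expect_equal(ds$y, log1p(g$matrix$authorCount))
  expect_equal(unname(ds$X_full[, "speciesRichness"]),
               log1p(g$matrix$speciesRichness))
  expect_equal(colnames(ds$X_full),
               c("(Intercept)", "speciesRichness", policy_ids()))
  expect_equal(colnames(ds$X_reduced), c("(Intercept)", "speciesRichness"))
  expect_error(regression_dataset(g$matrix[, 1:4]), "lacks column")
})
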