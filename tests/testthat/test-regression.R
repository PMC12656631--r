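# brute-force OLS via the normal equations, for oracle comparisons
ols_oracle <- function(y, x) {
  xm <- cbind(1, as.matrix(x))
  solve(t(xm) %*% xm, t(xm) %*% y)[, 1]
}

make_features <- function(n = 60, seed = 21, noise_sd = 0,
                          b = c(constant = 1.0, wt = 0.9, wtv = 5, cpr = 1.5)) {
  set.seed(seed)
  wt <- runif(n, 5, 12)
  wtv <- rnorm(n, 0.3, 0.1)
  cpr <- checkpoint_percentile_rank(runif(n))
  tibble::tibble(
    runner_id = sprintf("r%03d", seq_len(n)),
    WT_1 = wt, WTV_13 = wtv, CPR_1 = cpr,
    TT = b[["constant"]] + b[["wt"]] * wt + b[["wtv"]] * wtv +
      b[["cpr"]] * cpr + rnorm(n, 0, noise_sd))
}

test_that("segment fit recovers an exactly linear generating model", {
  ft <- make_features(noise_sd = 0)
  fit <- fit_segment_model(ft, "ascent1")
  expect_equal(fit$coefficients$B, c(1.0, 0.9, 5, 1.5), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_used, 60)
  expect_equal(length(fit$excluded_cases), 0)
})

test_that("segment fit equals the normal-equation oracle and its summary identities hold", {
  ft <- make_features(n = 80, seed = 3, noise_sd = 0.4)
  fit <- fit_segment_model(ft, "ascent1", exclude_influential = FALSE)
  oracle <- ols_oracle(ft$TT, ft[c("WT_1", "WTV_13", "CPR_1")])
  expect_equal(fit$coefficients$B, unname(oracle), tolerance = 1e-10)
  # adjusted R2 and SEE identities, brute force
  e <- residuals(fit$fit)
  n <- length(e); k <- 3
  r2 <- 1 - sum(e^2) / sum((ft$TT - mean(ft$TT))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
  expect_equal(fit$adj_r_squared, 1 - (1 - r2) * (n - 1) / (n - k - 1),
               tolerance = 1e-12)
  expect_equal(fit$see^2, sum(e^2) / (n - k - 1), tolerance = 1e-12)
  expect_equal(fit$r, sqrt(r2), tolerance = 1e-12)
  # standardized betas: B * sd(x) / sd(y), invariant to predictor rescaling
  expect_equal(fit$coefficients$beta[2],
               fit$coefficients$B[2] * sd(ft$WT_1) / sd(ft$TT),
               tolerance = 1e-12)
  ft2 <- ft; ft2$WT_1 <- ft2$WT_1 * 100 + 7
  fit2 <- fit_segment_model(ft2, "ascent1", exclude_influential = FALSE)
  expect_equal(fit2$coefficients$beta, fit$coefficients$beta, tolerance = 1e-10)
})

test_that("rank-deficient designs and short tables are refused", {
  ft <- make_features(n = 40)
  ft$WTV_13 <- 2 * ft$WT_1 # exact collinearity
  expect_error(fit_segment_model(ft, "ascent1"), "collinear")
  expect_error(fit_segment_model(make_features(n = 8), "ascent1"),
               "at least 10")
})

test_that("influential-case screening is a single pass that names the cases", {
  ft <- make_features(n = 50, seed = 8, noise_sd = 0.2)
  ft$TT[17] <- ft$TT[17] + 40
  ft$WT_1[17] <- 40
  fit <- fit_segment_model(ft, "ascent1")
  expect_true("r017" %in% fit$excluded_cases)
  expect_equal(fit$n_used, 50 - length(fit$excluded_cases))
  noexcl <- fit_segment_model(ft, "ascent1", exclude_influential = FALSE)
  expect_equal(noexcl$n_used, 50)
  # removing the gross outlier shrinks the residual scale
  expect_lt(fit$see, noexcl$see)
})

test_that("Durbin-Watson follows its definition across regimes", {
  expect_equal(durbin_watson(c(1, -1, 1, -1)), 3)
  expect_equal(durbin_watson(rep(2, 10)), 0)
  expect_error(durbin_watson(rep(0, 5)), "undefined")
  expect_error(durbin_watson(1), "at least 2")
  set.seed(10)
  e <- rnorm(5000)
  expect_equal(durbin_watson(e), 2, tolerance = 0.1)
  expect_equal(durbin_watson(e), sum(diff(e)^2) / sum(e^2), tolerance = 1e-12)
  skip_if_not_installed("lmtest")
  ft <- make_features(n = 60, seed = 5, noise_sd = 0.3)
  fit <- lm(TT ~ WT_1 + WTV_13 + CPR_1, data = ft)
  expect_equal(durbin_watson(residuals(fit)),
               unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})

test_that("VIF equals the brute-force auxiliary regressions", {
  set.seed(17)
  n <- 100
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  x[, "c"] <- x[, "a"] + rnorm(n, 0, 0.05) # near-collinear pair
  v <- vif(x)
  oracle <- vapply(1:3, function(j) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(unname(v), oracle, tolerance = 1e-10)
  expect_gt(v[["c"]], 10)
  # orthogonal (and centred) design: all VIF exactly 1
  xo <- unclass(poly(1:20, 3))
  expect_equal(unname(vif(xo)), rep(1, 3), tolerance = 1e-10)
  # perfect collinearity flagged infinite
  xc <- cbind(a = rnorm(20), b = rnorm(20))
  xc <- cbind(xc, c = xc[, 1] + xc[, 2])
  expect_warning(vc <- vif(xc), "collinearity")
  expect_true(any(is.infinite(vc)))
  skip_if_not_installed("car")
  dfr <- as.data.frame(x); dfr$y <- rnorm(n)
  expect_equal(unname(v), unname(car::vif(lm(y ~ a + b + c, data = dfr))),
               tolerance = 1e-8)
})

test_that("Cook's distance matches the leave-one-out refit definition", {
  ft <- make_features(n = 25, seed = 13, noise_sd = 0.5)
  fit <- lm(TT ~ WT_1 + WTV_13 + CPR_1, data = ft)
  cd <- cooks_distance(fit)
  p <- 4
  s2 <- sum(residuals(fit)^2) / (25 - p)
  yhat <- fitted(fit)
  loo <- vapply(1:25, function(i) {
    fi <- lm(TT ~ WT_1 + WTV_13 + CPR_1, data = ft[-i, ])
    yhat_i <- predict(fi, newdata = ft)
    sum((yhat - yhat_i)^2) / (p * s2)
  }, numeric(1))
  expect_equal(cd$cooks_d, loo, tolerance = 1e-10)
  expect_false(any(cd$influential))
  # a gross outlier in x and y becomes influential
  ft$WT_1[1] <- 60; ft$TT[1] <- 300
  cd2 <- cooks_distance(lm(TT ~ WT_1 + WTV_13 + CPR_1, data = ft))
  expect_true(cd2$influential[1])
})

test_that("Bland-Altman agreement: identity, shift, and Gaussian coverage", {
  y <- seq(8, 20, length.out = 10)
  expect_warning(ba0 <- bland_altman(y, y), "degenerate")
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  expect_equal(ba0$pct_outside, 0)
  expect_warning(bas <- bland_altman(y + 0.5, y), "degenerate")
  expect_equal(bas$bias, 0.5)
  expect_true(bas$degenerate)
  expect_error(bland_altman(1:2, 1:2), "at least 3")
  set.seed(19)
  act <- rnorm(1000, 12, 2)
  pred <- act + rnorm(1000, 0.2, 0.5)
  ba <- bland_altman(pred, act)
  expect_equal(ba$bias, 0.2, tolerance = 0.06)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff,
               tolerance = 1e-12)
  expect_lt(abs(ba$pct_outside - 0.05), 0.02)
  expect_equal(ba$loa_low, ba$bias - 1.96 * sd(ba$differences),
               tolerance = 1e-12)
})
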