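lin_data <- function(X, y) tibble::tibble(x = X, y = y)

test_that("OLS recovers an exact linear map and the intercept", {
  X <- cbind(x1 = c(0, 1, 2, 3, 4, 5), x2 = c(1, 0, 2, 1, 3, 2))
  y <- 2 * X[, 1] + 3
  fit <- fit_ee_linear(lin_data(X, y), quiet = TRUE)
  expect_equal(unname(fit$a[1]), 2, tolerance = 1e-6)
  expect_equal(unname(fit$a[2]), 0, tolerance = 1e-6)
  expect_equal(fit$b, 3, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("constant labels give the minimum-norm solution a = 0, b = c", {
  X <- matrix(rnorm(30), 10, 3)
  fit <- fit_ee_linear(lin_data(X, rep(42, 10)), quiet = TRUE)
  expect_equal(unname(fit$a), rep(0, 3), tolerance = 1e-9)
  expect_equal(fit$b, 42)

  # under-determined designs warn and return the minimum-norm interpolant
  Xwide <- matrix(rnorm(5 * 12), 5, 12)
  ywide <- rnorm(5) + 300
  expect_warning(fitw <- fit_ee_linear(lin_data(Xwide, ywide)),
                 "minimum-norm")
  expect_equal(predict(fitw, Xwide), ywide, tolerance = 1e-8)
})

test_that("OLS residuals are orthogonal to the design and the intercept", {
  withr::with_seed(14, {
    X <- matrix(rnorm(200 * 7), 200, 7)
    y <- as.numeric(X %*% rnorm(7)) + 5 + rnorm(200)
    fit <- fit_ee_linear(lin_data(X, y), quiet = TRUE)
    res <- y - predict(fit, X)
    expect_lt(abs(sum(res)), 1e-8 * sd(y) * 200)
    for (j in 1:7) expect_lt(abs(sum(res * X[, j])), 1e-8 * sd(y) * 200)
  })
})

test_that("linear prediction checks dimensions", {
  fit <- fit_ee_linear(lin_data(matrix(rnorm(20), 10, 2), rnorm(10)),
                       quiet = TRUE)
  expect_error(predict(fit, matrix(1, 3, 5)), "expects 2")
  expect_error(fit_ee_linear(lin_data(matrix(c(NA, rnorm(19)), 10, 2),
                                      rnorm(10))), "finite")
})

test_that("tidy and glance summarise linear fits", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  fit <- fit_ee_linear(lin_data(X, rnorm(20) + 300), quiet = TRUE)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "f1", "f2"))
  gl <- glance(fit)
  expect_identical(gl$nobs, 20L)
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})

test_that("the feedforward network learns and beats the mean predictor", {
  withr::with_seed(2, {
    X <- matrix(rnorm(400 * 10), 400, 10)
    y <- as.numeric(X %*% rnorm(10)) * 20 + 300
  })
  d <- lin_data(X, y)
  fit <- fit_ee_mlp(d, hidden = c(32, 32, 32), epochs = 40, seed = 4)
  mlp_mae <- mean(abs(predict(fit, d) - y))
  mean_mae <- mean(abs(mean(y) - y))
  expect_lt(mlp_mae, mean_mae)
})

test_that("with no dropout/L2 and adequate width, training MAE falls below 2% of label range", {
  withr::with_seed(2, {
    X <- matrix(rnorm(400 * 10), 400, 10)
    y <- as.numeric(X %*% rnorm(10)) * 20 + 300
  })
  d <- lin_data(X, y)
  fit <- fit_ee_mlp(d, hidden = c(64, 64, 64), dropout = 0, l2 = 0,
                    epochs = 200, validation_frac = 0, learning_rate = 2e-3,
                    seed = 3)
  expect_lt(mean(abs(predict(fit, d) - y)), 0.02 * diff(range(y)))
})

test_that("network training is deterministic under a fixed seed", {
  withr::with_seed(3, {
    X <- matrix(rnorm(120 * 6), 120, 6)
    y <- rnorm(120) + 350
  })
  d <- lin_data(X, y)
  f1 <- fit_ee_mlp(d, hidden = c(16, 16, 16), epochs = 8, seed = 5)
  f2 <- fit_ee_mlp(d, hidden = c(16, 16, 16), epochs = 8, seed = 5)
  expect_identical(predict(f1, d), predict(f2, d))
  f3 <- fit_ee_mlp(d, hidden = c(16, 16, 16), epochs = 8, seed = 6)
  expect_false(identical(predict(f1, d), predict(f3, d)))
})

test_that("network rejects invalid configs and inputs", {
  d <- lin_data(matrix(rnorm(40), 20, 2), rnorm(20))
  expect_error(fit_ee_mlp(d, dropout = 1), "dropout")
  fit <- fit_ee_mlp(d, hidden = c(8, 8, 8), epochs = 2, seed = 1)
  expect_error(predict(fit, matrix(1, 2, 5)), "expects 2")
})
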