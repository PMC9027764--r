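# Frozen oracle values computed with scikit-learn's SVR (LIBSVM), linear
# kernel, C = 1, epsilon = 0.1, tol = 1e-8, on the fixture below.
svr_fixture <- function() {
  X <- matrix(c(0.305, -1.04, 0.75, 0.941, -1.951, -1.302,
                0.128, -0.316, -0.017, -0.853, 0.879, 0.778,
                0.066, 1.127, 0.468, -0.859, 0.369, -0.959,
                0.878, -0.05, -0.185, -0.681, 1.223, -0.155),
              ncol = 3, byrow = TRUE)
  y <- c(1.227, 1.821, 0.688, -0.725, 0.002, -0.897, 1.585, -1.113)
  list(X = X, y = y,
       w = c(1.07327179, -0.45906688, 0.23010044),
       b = 0.31500251,
       loo = c(1.29235529, 2.20661376, 0.59353472, -0.83595277,
               -0.02384292, -1.04702422, 1.00748318, -0.81397225))
}

test_that("svr_fit reproduces the reference LIBSVM solution", {
  fx <- svr_fixture()
  fit <- svr_fit(fx$X, fx$y)
  expect_equal(fit$w, fx$w, tolerance = 1e-4)
  expect_equal(fit$b, fx$b, tolerance = 1e-4)
  expect_equal(svr_loo_predict(fx$X, fx$y), fx$loo, tolerance = 1e-4)
})

test_that("svr_fit satisfies the epsilon-SVR KKT conditions", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(6:15, 1); p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 0.3)
    fit <- svr_fit(X, y, cost = 1, epsilon = 0.1)
    beta <- fit$beta
    expect_true(all(beta >= -1 - 1e-8 & beta <= 1 + 1e-8))
    expect_lt(abs(sum(beta)), 1e-8)
    resid <- y - fit$fitted
    # interior dual coefficients sit on the epsilon tube
    interior <- abs(beta) > 1e-6 & abs(beta) < 1 - 1e-6
    if (any(interior))
      expect_equal(abs(resid[interior]), rep(0.1, sum(interior)),
                   tolerance = 1e-4)
    # points strictly inside the tube have zero dual coefficients
    expect_true(all(abs(beta[abs(resid) < 0.1 - 1e-4]) < 1e-6))
    # residuals beyond the tube imply coefficients at the box bound
    out <- abs(resid) > 0.1 + 1e-4
    expect_true(all(abs(abs(beta[out]) - 1) < 1e-6))
  }
})

test_that("LOO pooled R2 is order-invariant and solver is deterministic", {
  set.seed(72)
  X <- matrix(rnorm(12 * 5), 12, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(12, sd = 0.2)
  arr <- array(X, dim = c(12, 5, 1))
  r2 <- timewise_svr_r2(arr, y)
  perm <- sample(12)
  r2p <- timewise_svr_r2(arr[perm, , , drop = FALSE], y[perm])
  expect_equal(as.numeric(r2), as.numeric(r2p), tolerance = 1e-6)
  # duplicating subjects leaves fitted fold models' predictions unchanged
  # for identical training sets (determinism of the solver contract)
  f1 <- svr_fit(X, y); f2 <- svr_fit(X, y)
  expect_identical(f1$w, f2$w)
})

test_that("planted linear signal is recovered, noise is not", {
  # informative-sample regime: the 3 signal labels dominate the feature
  # scale (with 147 iid unit-variance nuisance labels instead, LOO-SVR is
  # honestly pessimistic and R^2 goes negative -- see the decode null test)
  set.seed(73)
  n <- 15; L <- 150
  X <- cbind(matrix(rnorm(n * 3), n, 3),
             matrix(rnorm(n * (L - 3), sd = 0.05), n, L - 3))
  y <- 0.8 * X[, 1] + 0.5 * X[, 2] - 0.6 * X[, 3]
  arr <- array(X, dim = c(n, L, 1))
  expect_gt(as.numeric(timewise_svr_r2(arr, y)), 0.95)
  # pure noise features: LOO R2 is pessimistic (<= 0 on average)
  r2n <- replicate(12, {
    Xn <- matrix(rnorm(n * L), n, L)
    as.numeric(timewise_svr_r2(array(Xn, dim = c(n, L, 1)), rnorm(n)))
  })
  expect_lte(mean(r2n), 0)
  expect_error(timewise_svr_r2(arr, rep(1, n)), "constant response")
})
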