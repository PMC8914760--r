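# brute-force oracle: dense inverse, no Cholesky, independent of the
# package's linear-algebra path
dense_gp_oracle <- function(X, y, q, params) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    K[i, j] <- kernel_eval(X[i, ], X[j, ], params)
  Ky_inv <- solve(K + params$sigma_n2 * diag(n))
  kq <- vapply(1:n, function(i) kernel_eval(q, X[i, ], params), numeric(1))
  list(mean = drop(kq %*% Ky_inv %*% y),
       var = params$sigma_f^2 - drop(kq %*% Ky_inv %*% kq),
       lml = as.numeric(-0.5 * t(y) %*% Ky_inv %*% y -
                          0.5 * determinant(K + params$sigma_n2 * diag(n))$modulus -
                          0.5 * n * log(2 * pi)))
}

test_that("kernel closed forms hold", {
  p <- kernel_params(sigma_f = 2, sigma_l = 1)
  x <- c(0.3, -1, 2)
  expect_equal(kernel_eval(x, x, p), 4.0)
  p1 <- kernel_params(1, 1)
  a <- c(1, 0); b <- c(0, 0)          # squared distance 1
  expect_equal(kernel_eval(a, b, p1), exp(-1))
  for (i in 1:5) {
    u <- rnorm(4); v <- rnorm(4)
    expect_equal(kernel_eval(u, v, p), kernel_eval(v, u, p))
    expect_lte(kernel_eval(u, v, p), p$sigma_f^2)
  }
  expect_error(kernel_eval(c(1, NaN), c(0, 0), p1), "non-finite")
  # conventional (euclidean) variant
  pe <- kernel_params(1, 2, distance = "euclidean")
  expect_equal(kernel_eval(c(2, 0), c(0, 0), pe), exp(-1))
})

test_that("log marginal likelihood matches the scalar and dense oracles", {
  p <- kernel_params(1.5, 2, sigma_n2 = 0.3)
  y1 <- 0.7
  v <- 1.5^2 + 0.3
  expect_equal(log_marginal_likelihood(matrix(1, 1, 1), y1, p),
               -0.5 * y1^2 / v - 0.5 * log(v) - 0.5 * log(2 * pi))
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:20, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- rnorm(n)
    o <- dense_gp_oracle(X, y, rnorm(3), p)
    expect_equal(log_marginal_likelihood(X, y, p), unname(o$lml),
                 tolerance = 1e-8)
    perm <- sample(n)
    expect_equal(log_marginal_likelihood(X[perm, , drop = FALSE], y[perm], p),
                 log_marginal_likelihood(X, y, p), tolerance = 1e-9)
  }
})

test_that("prediction matches the dense oracle and its limits", {
  set.seed(7)
  p <- kernel_params(1.2, 3, sigma_n2 = 0.2)
  X <- matrix(rnorm(24), 8, 3)
  y <- rnorm(8)
  m <- gpr_model(X, y, p, standardize = FALSE)
  q <- rnorm(3)
  o <- dense_gp_oracle(X, y, q, p)
  pr <- predict(m, q)
  expect_equal(pr$mean, o$mean, tolerance = 1e-8)
  expect_equal(pr$variance, o$var, tolerance = 1e-8)
  # noise-free interpolation
  m0 <- gpr_model(X, y, kernel_params(1.2, 3, sigma_n2 = 1e-12),
                  standardize = FALSE)
  expect_equal(predict(m0, X[4, ])$mean, y[4], tolerance = 1e-6)
  # far query reverts to the prior: zero mean (here raw scale), var sigma_f^2
  far <- predict(m, q + 100)
  expect_equal(far$mean, 0, tolerance = 1e-8)
  expect_equal(far$variance, p$sigma_f^2, tolerance = 1e-8)
  expect_error(predict(m, c(1, 2)), "features")
})

test_that("predictive variance is bounded and shrinks with data", {
  set.seed(11)
  p <- kernel_params(2, 2, sigma_n2 = 0.1)
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  m <- gpr_model(X, y, p, standardize = FALSE)
  Q <- matrix(rnorm(40), 20, 2)
  v <- predict(m, Q)$variance
  expect_true(all(v >= 0 & v <= p$sigma_f^2 + 1e-12))
  # conditioning on one more point cannot raise variance anywhere
  m2 <- gpr_augment(m, rnorm(2), 0.5)
  v2 <- predict(m2, Q)$variance
  expect_true(all(v2 <= v + 1e-10))
})

test_that("fitting handles degenerate targets and recovers known functions", {
  set.seed(3)
  X <- matrix(runif(40), 20, 2)
  m0 <- fit_gpr(X, rep(0, 20))
  expect_equal(predict(m0, c(0.5, 0.5))$mean, 0, tolerance = 1e-6)
  # noisy smooth 1-D function: held-out error beats the noise floor
  x <- matrix(seq(0, 10, length.out = 120), ncol = 1)
  y <- 5 * sin(x[, 1]) + rnorm(120, 0, 0.5)
  hold <- seq(3, 120, by = 5)
  m <- fit_gpr(x[-hold, , drop = FALSE], y[-hold])
  pr <- predict(m, x[hold, , drop = FALSE])$mean
  expect_lt(sqrt(mean((pr - 5 * sin(x[hold, 1]))^2)), 0.5)
  expect_error(fit_gpr(x[1, , drop = FALSE], y[1]), "at least 2")
  expect_error(fit_gpr(x[1:5, , drop = FALSE], c(1, 2, NA, 4, 5)), "finite")
})

test_that("hyperparameter recovery from GP draws is usually within 2x", {
  true <- kernel_params(sigma_f = 2, sigma_l = 1.5, sigma_n2 = 0.04)
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    X <- matrix(runif(100, -2, 2), 100, 1)
    K <- outer(X[, 1], X[, 1], function(a, b) 4 * exp(-(a - b)^2 / 1.5))
    y <- drop(t(chol(K + 0.04 * diag(100) + 1e-10 * diag(100))) %*% rnorm(100))
    m <- fit_gpr(X, y)
    # compare in standardized space via the ratio of fitted to true scales
    sf_ratio <- (m$params$sigma_f * m$standardizer$y_sd) / true$sigma_f
    sl_ratio <- m$params$sigma_l * stats::sd(X[, 1])^2 / true$sigma_l
    (sf_ratio > 0.5 && sf_ratio < 2) && (sl_ratio > 0.5 && sl_ratio < 2)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("fitting is deterministic and permutation-stable", {
  set.seed(5)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] * 2 + rnorm(30, 0, 0.2)
  m1 <- fit_gpr(X, y)
  m2 <- fit_gpr(X, y)
  expect_identical(m1$params, m2$params)
  perm <- sample(30)
  m3 <- fit_gpr(X[perm, ], y[perm])
  q <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(m1, q)$mean, predict(m3, q)$mean, tolerance = 1e-6)
})
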