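# Shared fixture: 8 well-separated classes in 40 informative variables
# plus noise variables, 56 samples.
separable_data <- function(seed = 9, n = 56, p_noise = 60) {
  set.seed(seed)
  y <- rep(1:8, length.out = n)
  mu <- matrix(rnorm(8 * 40, 0, 1), 8, 40)
  X <- cbind(mu[y, ] + matrix(rnorm(n * 40, 0, 0.3), n, 40),
             matrix(rnorm(n * p_noise), n, p_noise))
  list(X = X, y = y)
}

test_that("autoscaling centers and scales on the fit rows only", {
  set.seed(1)
  X <- matrix(rnorm(40, mean = 5, sd = 3), 10, 4)
  sc <- autoscale(X)
  expect_equal(colMeans(sc$X), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(sc$X, 2, sd), rep(1, 4), tolerance = 1e-12)

  Xc <- cbind(X, 7)  # constant column
  expect_warning(sc2 <- autoscale(Xc), "zero-variance")
  expect_equal(sc2$X[, 5], rep(0, 10))
  expect_true(sc2$zero_var[5])

  # validation rows scaled with calibration stats are generally off-center
  sc3 <- autoscale(X, fit_rows = 1:5)
  expect_equal(colMeans(sc3$X[1:5, ]), rep(0, 4), tolerance = 1e-12)
  expect_gt(max(abs(colMeans(sc3$X[6:10, ]))), 0.05)
})

test_that("separable classes give a perfectly calibrated model", {
  d <- separable_data()
  m <- fit_plsda(d$X, d$y, folds = 7, A_max = 10)
  expect_equal(m$status, "fitted")
  expect_gte(m$A, 1)
  expect_equal(mean(predict(m, d$X) == d$y), 1)
  expect_gt(m$Q2cum, 0.5)
  # R2Y(cum) is non-decreasing in the component count
  expect_true(all(diff(m$r2y_cum) >= -1e-12))
  expect_lte(m$Q2cum, 1)
})

test_that("shuffled labels usually fail or lose predictive power", {
  d <- separable_data()
  bad <- 0
  for (r in 1:20) {
    set.seed(100 + r)
    yp <- sample(d$y)
    m <- fit_plsda(d$X, yp, folds = 7, A_max = 10)
    if (m$status == "failed" || m$Q2cum <= 0.05) bad <- bad + 1
  }
  expect_gte(bad / 20, 0.75)
})

test_that("NIPALS matches the eigendecomposition oracle on small matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 10; p <- 8; m <- 3
    X <- scale(matrix(rnorm(n * p), n, p))
    Y <- scale(matrix(rnorm(n * m), n, m), scale = FALSE)
    A <- 3
    fit <- fusefinger:::nipals_pls2(X, Y, A)
    orc <- pls2_eigen_oracle(X, Y, A)
    expect_equal_up_to_sign(fit$W, orc$W, tol = 1e-8)
    expect_equal_up_to_sign(fit$T, orc$T, tol = 1e-8)
    expect_equal_up_to_sign(fit$P, orc$P, tol = 1e-8)
    # deflation correctness: X residual orthogonal to all scores
    Xr <- X - fit$T %*% t(fit$P)
    expect_lt(max(abs(crossprod(fit$T, Xr))), 1e-8)
    # weights are unit norm
    expect_equal(colSums(fit$W^2), rep(1, A), tolerance = 1e-12)
  }
})

test_that("prediction assigns by argmax with lowest-index ties", {
  d <- separable_data()
  m <- fit_plsda(d$X, d$y, A_max = 8)
  resp <- predict(m, d$X[1:3, , drop = FALSE], type = "response")
  cls <- predict(m, d$X[1:3, , drop = FALSE])
  expect_equal(cls, m$classes[max.col(resp, ties.method = "first")])
  expect_length(predict(m, d$X[1, , drop = FALSE]), 1)
  # argmax rule on an explicit response row
  expect_equal(which.max(c(0.1, 0.7, 0.2)), 2L)
})

test_that("VIP scores satisfy their normalisation and ranking", {
  d <- separable_data()
  m <- fit_plsda(d$X, d$y, A_max = 10)
  v <- vip(m)
  expect_length(v, ncol(d$X))
  expect_equal(mean(v^2), 1, tolerance = 1e-8)  # sum VIP^2 = p
  # informative variables dominate the noise block
  expect_gt(mean(v[1:40]), mean(v[41:100]))

  # one informative variable among 50 noise variables is the maximum
  set.seed(21)
  y2 <- rep(1:2, each = 14)
  X2 <- cbind(ifelse(y2 == 1, -2, 2) + rnorm(28, 0, 0.4),
              matrix(rnorm(28 * 50), 28, 50))
  m2 <- fit_plsda(X2, y2, A_max = 3)
  v2 <- vip(m2)
  expect_equal(which.max(v2), 1L)
  expect_gt(v2[1], 1)
})

test_that("exchangeable variables all have VIP near 1", {
  set.seed(31)
  y <- rep(1:2, each = 10)
  base <- ifelse(y == 1, -1, 1)
  X <- sapply(1:12, function(j) base + rnorm(20, 0, 0.2))
  m <- fit_plsda(X, y, A_max = 2)
  expect_lt(max(abs(vip(m) - 1)), 0.1)
})

test_that("the permutation test separates real from random labelling", {
  d <- separable_data(seed = 5)
  pt <- permutation_test(d$X, d$y, n_iter = 30, seed = 3, folds = 7,
                         A_max = 6)
  expect_equal(pt$n_iter, 30)
  expect_length(pt$permuted_R2, 30)
  expect_length(pt$label_correlations, 30)
  expect_true(pt$passed)
  expect_lt(mean(pt$permuted_Q2), 0.2)

  # the identity permutation recovers the original statistics
  pt_id <- permutation_test(d$X, d$y, folds = 7, A_max = 6,
                            permutations = list(seq_along(d$y)))
  expect_equal(pt_id$permuted_R2[1], pt_id$original_R2)
  expect_equal(pt_id$permuted_Q2[1], pt_id$original_Q2)
  expect_equal(pt_id$label_correlations[1], 1)
  expect_false(pt_id$passed)  # equality is not strictly below
})

test_that("degenerate inputs are rejected", {
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fit_plsda(X, rep(1, 10)), "two classes")
  expect_error(fit_plsda(X, rep(1:2, 5), folds = 20), "fewer samples")
  m <- fit_plsda(separable_data()$X, separable_data()$y, A_max = 5)
  expect_error(predict(m, matrix(0, 2, 3)), "wrong number of columns")
})
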