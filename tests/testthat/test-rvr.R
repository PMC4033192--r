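test_that("fit_rvr collapses to a bias-only model for constant targets", {
  set.seed(1)
  X <- matrix(rnorm(30), 15, 2)
  m <- fit_rvr(X, rep(50, 15))
  pred <- predict_age(m, matrix(rnorm(10), 5, 2))
  expect_equal(pred, rep(50, 5), tolerance = 1e-6)
  # zero-vector input with a bias-dominated model returns the bias weight
  expect_equal(predict_age(m, matrix(0, 1, 2))[1], 50, tolerance = 1e-6)
})

test_that("fit_rvr nails a noiseless linear law and prunes most bases", {
  set.seed(2)
  X <- matrix(rnorm(20), 20, 1)
  ages <- 2 * X[, 1] + 10
  m <- fit_rvr(X, ages)
  held <- matrix(rnorm(12), 12, 1)
  expect_lt(max(abs(predict_age(m, held) - (2 * held[, 1] + 10))), 1e-4)
  # solution sparsity: at least half the kernel bases pruned
  expect_lte(length(m$relevance_indices), 10L)
  # stored relevance vectors predict their own training ages
  if (length(m$relevance_indices) > 0) {
    rv <- X[m$relevance_indices, , drop = FALSE]
    expect_lt(max(abs(predict_age(m, rv) - ages[m$relevance_indices])), 1e-4)
  }
})

test_that("posterior solve with frozen hyperparameters equals the ridge oracle", {
  set.seed(3)
  n <- 5
  X <- matrix(rnorm(n * 2), n, 2)
  t_vec <- rnorm(n, 50, 10)
  Phi <- cbind(1, tcrossprod(X))
  alpha <- runif(n + 1, 0.01, 2)
  beta <- 3.7
  post <- brainage:::rvr_posterior(Phi, alpha, beta, t_vec)
  mu_oracle <- solve(diag(alpha) / beta + crossprod(Phi), crossprod(Phi, t_vec))
  expect_lt(max(abs(post$mu - mu_oracle)), 1e-8)
})

test_that("predictions are linear: batch equals per-row, age shift propagates", {
  set.seed(4)
  X <- matrix(rnorm(90), 30, 3)
  ages <- as.vector(X %*% c(3, -1, 2)) + 55
  m <- suppressWarnings(fit_rvr(X, ages))
  Xt <- matrix(rnorm(15), 5, 3)
  batch <- predict_age(m, Xt)
  single <- vapply(1:5, function(i)
    predict_age(m, Xt[i, , drop = FALSE]), numeric(1))
  expect_equal(batch, single)

  # +c on all training ages shifts every prediction by +c (linear kernel + bias)
  m2 <- suppressWarnings(fit_rvr(X, ages + 7))
  expect_equal(predict_age(m2, Xt), predict_age(m, Xt) + 7, tolerance = 1e-3)
})

test_that("fit_rvr validates inputs", {
  X <- matrix(rnorm(9), 3, 3)
  expect_error(fit_rvr(X, 1:2), "match")
  expect_error(fit_rvr(X[1:2, ], 1:2), "at least 3")
  m <- fit_rvr(matrix(rnorm(20), 10, 2), rnorm(10, 50, 5))
  expect_error(predict_age(m, matrix(0, 1, 5)), "dimension")
})
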