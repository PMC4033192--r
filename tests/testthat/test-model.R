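test_that("brainage_scores implements estimated minus chronological", {
  s <- brainage_scores(c(75, 60, 72), c(70, 60, 80), c("a", "b", "c"))
  expect_equal(s$brainage, c(5, 0, -8))
  expect_equal(s$brainage, s$estimated_age - s$chronological_age,
               tolerance = 1e-9)
  expect_error(brainage_scores(1:3, 1:2), "equal length")
})

test_that("train_brainage recovers age on a noiseless synthetic cohort", {
  cfg <- small_synth(seed = 21, n_train = 24, noise_sd = 0)
  tr <- generate_training_cohort(cfg)
  model <- suppressWarnings(train_brainage(tr$volumes, tr$ages$age))
  est <- estimate_brainage(model, tr$volumes)
  expect_lt(mean(abs(est - tr$ages$age)), 0.5)

  expect_error(train_brainage(tr$volumes[1:5], tr$ages$age[1:5]),
               "at least 10")
})

test_that("model persistence roundtrips to identical predictions", {
  cfg <- small_synth(seed = 22, n_train = 20)
  tr <- generate_training_cohort(cfg)
  model <- suppressWarnings(train_brainage(tr$volumes, tr$ages$age))
  ho <- generate_training_cohort(small_synth(seed = 23, n_train = 6))
  p <- tempfile(fileext = ".rds")
  write_brainage_model(model, p)
  model2 <- read_brainage_model(p)
  expect_identical(estimate_brainage(model, ho$volumes),
                   estimate_brainage(model2, ho$volumes))
  unlink(p)
})

test_that("PCA reduction does not change linear-kernel RVR predictions", {
  set.seed(30)
  X <- matrix(runif(40 * 12, 0.2, 0.8), 40, 12)
  ages <- rnorm(40, 50, 10)
  pca <- fit_pca(X, "all")
  S <- pca_transform(pca, X)
  m_raw <- fit_rvr(sweep(X, 2, colMeans(X)), ages)
  m_red <- fit_rvr(S, ages)
  Xt <- matrix(runif(5 * 12, 0.2, 0.8), 5, 12)
  p_raw <- predict_age(m_raw, sweep(Xt, 2, colMeans(X)))
  p_red <- predict_age(m_red, pca_transform(pca, Xt))
  expect_equal(p_raw, p_red, tolerance = 1e-6)
})

test_that("evaluate_model computes MAE and Pearson r", {
  cfg <- small_synth(seed = 24, n_train = 20, noise_sd = 0)
  tr <- generate_training_cohort(cfg)
  model <- suppressWarnings(train_brainage(tr$volumes, tr$ages$age))
  ev <- evaluate_model(model, tr$volumes, tr$ages$age)
  expect_lt(ev$mae, 0.5)
  expect_gt(ev$r, 0.99)

  # hand-computed 4-pair toy via brainage_scores arithmetic
  est <- c(71, 59, 83, 65); chron <- c(70, 62, 80, 66)
  expect_equal(mean(abs(est - chron)), 2)
  # r = 237 / sqrt(179 * 315) from the deviation sums
  expect_equal(cor(chron, est), 237 / sqrt(179 * 315), tolerance = 1e-12)

  expect_error(evaluate_model(model, tr$volumes[1:2], tr$ages$age[1:2]),
               "at least 3")
  expect_warning(evaluate_model(model, tr$volumes[1:3], rep(50, 3)),
                 "constant")
})
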