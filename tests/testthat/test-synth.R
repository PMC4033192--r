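test_that("gm_template renders the atrophy model deterministically", {
  field <- atrophy_field(c(10, 12, 10), template_seed = 5)
  v20 <- gm_template(20, field, noise_sd = 0, seed = 1)
  expect_equal(v20$data, field$baseline)  # age 20 = baseline exactly

  # mean GM strictly decreasing in age at zero noise
  means <- vapply(c(20, 40, 60, 80), function(a)
    mean(gm_template(a, field, 0, 1)$data), numeric(1))
  expect_true(all(diff(means) < 0))

  # bit-identical on repeat, different under another seed
  a <- gm_template(55, field, 0.05, seed = 9)
  b <- gm_template(55, field, 0.05, seed = 9)
  c2 <- gm_template(55, field, 0.05, seed = 10)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c2$data))

  expect_error(gm_template(10, field, 0, 1), ">= 20")
})

test_that("generator output respects GM range even for extreme brain ages", {
  field <- atrophy_field(c(10, 10, 10), template_seed = 7)
  v <- gm_template(110, field, noise_sd = 0.1, seed = 3)
  expect_true(all(v$data >= 0 & v$data <= 1))
  # slope construction keeps the noiseless signal strictly positive
  expect_true(all(field$baseline - field$slope * 90 > 0))
})

test_that("generate_training_cohort matches the configured age distribution", {
  cfg <- synth_config(seed = 31, n_train = 561, effects = NULL,
                      grid_dim = c(6L, 6L, 6L))
  tr <- generate_training_cohort(cfg)
  expect_equal(nrow(tr$ages), 561)
  expect_lt(abs(mean(tr$ages$age) - 48.6), 1.5)
  expect_lt(abs(sd(tr$ages$age) - 16.5), 1.5)
  expect_true(all(tr$ages$age >= 20 & tr$ages$age <= 86))

  empty <- generate_training_cohort(
    synth_config(seed = 1, n_train = 0, effects = NULL))
  expect_equal(nrow(empty$ages), 0)

  tr2 <- generate_training_cohort(cfg)
  expect_identical(tr$ages, tr2$ages)
  expect_identical(tr$volumes[[5]]$data, tr2$volumes[[5]]$data)
  tr3 <- generate_training_cohort(
    synth_config(seed = 32, n_train = 561, effects = NULL,
                 grid_dim = c(6L, 6L, 6L)))
  expect_false(identical(tr$ages$age, tr3$ages$age))
})

test_that("generate_test_cohort reproduces marker distributions and coupling", {
  cfg <- small_synth(seed = 33, n_male = 118)
  tm <- generate_test_cohort(cfg, "male", render = FALSE)
  bmi <- tm$subjects$bmi
  expect_lt(abs(mean(bmi, na.rm = TRUE) - 26.76), 1.0)
  expect_lt(abs(sd(bmi, na.rm = TRUE) - 3.75), 1.0)
  expect_true(all(is.finite(as.matrix(
    tm$subjects[, marker_names()])) | is.na(as.matrix(
      tm$subjects[, marker_names()]))))

  # no coupling, no residual -> brain age equals chronological age
  expect_equal(tm$truth$brain_age, tm$subjects$age)

  # planted gamma recovered within 3 SE by OLS on the latent z-scores
  eff <- list(male = list(gamma = c(bmi = 3, ggt = -1.5), residual_sd = 2),
              female = list(gamma = numeric(0), residual_sd = 0))
  cfg2 <- synth_config(seed = 34, n_male = 400, effects = eff,
                       grid_dim = c(6L, 6L, 6L))
  t2 <- generate_test_cohort(cfg2, "male", render = FALSE)
  fit <- summary(lm(t2$truth$gap ~ t2$truth$bmi + t2$truth$ggt))
  co <- fit$coefficients
  expect_lt(abs(co["t2$truth$bmi", 1] - 3), 3 * co["t2$truth$bmi", 2])
  expect_lt(abs(co["t2$truth$ggt", 1] + 1.5), 3 * co["t2$truth$ggt", 2])
})

test_that("marker sample moments converge at n = 10^4", {
  ref <- marker_reference()
  ref_m <- ref[ref$gender == "male", ]
  mk <- brainage:::draw_markers(1e4, ref_m, seed = 99)
  for (m in c("bmi", "ggt", "vitamin_b12", "albumin")) {
    i <- which(ref_m$marker == m)
    expect_lt(abs(mean(mk$values[, m]) - ref_m$mean[i]),
              0.02 * ref_m$mean[i] + 0.05 * ref_m$sd[i])
    expect_lt(abs(sd(mk$values[, m]) - ref_m$sd[i]), 0.06 * ref_m$sd[i])
  }
})

test_that("calibrate_effects converts contrasts to per-SD couplings", {
  z <- calibrate_effects(c(bmi = 0), "male")
  expect_equal(unname(z$gamma), 0)
  expect_equal(z$residual_sd, 0)

  # normal family: gamma = target / (2 phi(z_.75) / .25)
  cal <- calibrate_effects(c(bmi = 7.5), "male")
  factor_closed <- 2 * dnorm(qnorm(0.75)) / 0.25
  expect_equal(unname(cal$gamma), 7.5 / factor_closed, tolerance = 1e-6)
  expect_equal(unname(cal$gamma), 2.950, tolerance = 1e-3)

  # lognormal: monotone transform of z, so the Monte-Carlo factor agrees
  call <- calibrate_effects(c(ggt = 7.5), "male")
  expect_equal(unname(call$factors), factor_closed, tolerance = 0.02)

  # protective sign is preserved
  calb <- calibrate_effects(c(vitamin_b12 = -4.8), "female")
  expect_lt(unname(calb$gamma), 0)

  expect_error(calibrate_effects(c(nope = 1), "male"), "unknown marker")
  # a lognormal marker's raw value correlates imperfectly with its latent z,
  # capping the explainable fraction below 1
  expect_error(
    calibrate_effects(c(ggt = 7.5), "male", r2_target = 0.95,
                      finite_sample = FALSE),
    "infeasible")
})

test_that("null generator yields Holm-nonsignificant quartile contrasts", {
  # planted-null: gap is pure residual-free zero, add iid residual only
  hits <- 0L
  for (s in 1:60) {
    cfg <- synth_config(seed = 4000 + s, n_male = 60,
                        effects = list(
                          male = list(gamma = numeric(0), residual_sd = 5),
                          female = list(gamma = numeric(0), residual_sd = 5)),
                        grid_dim = c(6L, 6L, 6L))
    tm <- generate_test_cohort(cfg, "male", render = FALSE)
    ps <- vapply(c("bmi", "dbp", "ggt", "uric_acid"), function(m)
      suppressWarnings(
        quartile_contrast(tm$truth$gap, tm$subjects[[m]], m))$p_raw,
      numeric(1))
    if (any(holm_adjust(ps) < 0.05)) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.10)
})
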