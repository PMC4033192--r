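# Synthetic cohort generator. Emulates the data structure the analysis
# assumes: a smooth spatial atrophy field that thins GM linearly with
# "brain age", marker distributions calibrated to the published baseline
# table, and marker-coupled acceleration of brain aging at the published
# quartile-contrast effect sizes.

# The default calibration is deterministic (fixed internal seed) but not
# free, so it is computed once per session.
.calibration_cache <- new.env(parent = emptyenv())

default_calibration <- function() {
  if (!exists("default", envir = .calibration_cache)) {
    assign("default", list(
      male = calibrate_effects(default_effect_targets("male"), "male",
                               r2_target = default_r2_target("male")),
      female = calibrate_effects(default_effect_targets("female"), "female",
                                 r2_target = default_r2_target("female"))),
      envir = .calibration_cache)
  }
  get("default", envir = .calibration_cache)
}

# Deterministic per-stage seed derivation from one top-level seed.
# Lehmer-style step keeps everything inside 32-bit integer range.
seed_stream <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k) %% 2147483629 + 1)
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Inverse-CDF truncated normal draws (exact, vectorized).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# Closed-form moments of N(mu, sigma) truncated to [lo, hi].
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# Parent (mu, sigma) whose truncation to [lo, hi] has the published
# sample mean/SD; without this the truncated SD undershoots the target.
truncnorm_params <- function(mean_t, sd_t, lo, hi) {
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), lo, hi)
    (mo[1] - mean_t)^2 + (mo[2] - sd_t)^2
  }
  fit <- stats::optim(c(mean_t, log(sd_t)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Synthetic cohort configuration
#'
#' Defaults encode the study design being emulated: a 561-subject training
#' cohort aged 20-86 years (mean 48.6, SD 16.5), elderly test cohorts of
#' 118 men (75.8 +/- 5.3 years, range 60-88) and 110 women
#' (76.1 +/- 4.8 years, range 62-90), 17 markers per the reference table,
#' about 45 study sites, and marker-coupled brain-age acceleration
#' calibrated by [calibrate_effects()] to the published quartile contrasts
#' and PLS R-squared values.
#'
#' @param seed top-level integer seed; all stage seeds derive from it.
#' @param n_train training cohort size.
#' @param n_male,n_female test cohort sizes.
#' @param grid_dim native grid dimensions (3 integers).
#' @param voxel_size_mm native voxel edge (mm).
#' @param noise_sd voxel noise SD added to rendered GM volumes.
#' @param template_seed seed of the fixed atrophy template (shared by
#'   training and test rendering so the trained model transfers).
#' @param n_sites number of categorical study sites.
#' @param effects `"default"` (calibrate both genders to published
#'   targets), `NULL` (null generator: no marker coupling, zero residual
#'   acceleration), or a list with `male`/`female` entries as returned by
#'   [calibrate_effects()].
#' @param apply_missingness apply per-marker missingness at the published
#'   rates.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_train = 561L, n_male = 118L,
                         n_female = 110L, grid_dim = c(24L, 28L, 24L),
                         voxel_size_mm = 4, noise_sd = 0.05,
                         template_seed = 42L, n_sites = 45L,
                         effects = "default", apply_missingness = TRUE) {
  if (identical(effects, "default")) {
    effects <- default_calibration()
  } else if (is.null(effects)) {
    effects <- list(
      male = list(gamma = numeric(0), residual_sd = 0),
      female = list(gamma = numeric(0), residual_sd = 0))
  }
  structure(
    list(seed = as.integer(seed), n_train = as.integer(n_train),
         n_male = as.integer(n_male), n_female = as.integer(n_female),
         train_age = list(mean = 48.6, sd = 16.5, min = 20, max = 86),
         test_age = list(
           male = list(mean = 75.8, sd = 5.3, min = 60, max = 88),
           female = list(mean = 76.1, sd = 4.8, min = 62, max = 90)),
         grid_dim = as.integer(grid_dim),
         voxel_size_mm = voxel_size_mm, noise_sd = noise_sd,
         template_seed = as.integer(template_seed),
         n_sites = as.integer(n_sites),
         effects = effects,
         apply_missingness = isTRUE(apply_missingness),
         markers = marker_reference()),
    class = "synth_config")
}

# Smooth random field as a mixture of Gaussian blobs on the grid,
# rescaled to [0, 1].
blob_field <- function(grid_dim, n_blobs, seed) {
  with_seed(seed, {
    ax <- lapply(grid_dim, seq_len)
    g <- array(0, grid_dim)
    for (b in seq_len(n_blobs)) {
      ctr <- stats::runif(3, 1, grid_dim)
      width <- stats::runif(3, 2, 5)
      amp <- stats::runif(1, 0.4, 1)
      gx <- exp(-(ax[[1]] - ctr[1])^2 / (2 * width[1]^2))
      gy <- exp(-(ax[[2]] - ctr[2])^2 / (2 * width[2]^2))
      gz <- exp(-(ax[[3]] - ctr[3])^2 / (2 * width[3]^2))
      g <- g + amp * (gx %o% gy %o% gz)
    }
    rng <- range(g)
    (g - rng[1]) / max(rng[2] - rng[1], 1e-12)
  })
}

#' Build the fixed atrophy template
#'
#' Baseline GM density `b(v)` at reference age 20 and annual loss rate
#' `s(v)`, both smooth Gaussian-blob mixtures. The slope is tied to the
#' baseline (`s = r (b - 0.05) / 100` with `r` in \[0, 1\]) so densities
#' remain strictly positive for brain ages beyond 110 years without
#' clipping.
#'
#' @param grid_dim grid dimensions.
#' @param template_seed template seed (fixed per study world).
#' @return list with arrays `baseline` and `slope` (per-year density loss).
#' @export
atrophy_field <- function(grid_dim, template_seed = 42L) {
  b <- 0.15 + 0.75 * blob_field(grid_dim, 25L, seed_stream(template_seed, 1L))
  r <- blob_field(grid_dim, 18L, seed_stream(template_seed, 2L))
  list(baseline = b, slope = r * (b - 0.05) / 100)
}

#' Render one GM volume at a given brain age
#'
#' `clip(b(v) - s(v) (age - 20) + noise, 0, 1)` with iid Gaussian voxel
#' noise. Bit-identical for identical `(age, field, noise_sd, seed)`.
#'
#' @param age brain age in years (>= 20).
#' @param field an [atrophy_field()].
#' @param noise_sd voxel noise SD.
#' @param seed integer seed for the noise draw.
#' @param voxel_size_mm voxel edge (mm).
#' @param subject_id identifier.
#' @return A [gm_volume].
#' @export
gm_template <- function(age, field, noise_sd, seed, voxel_size_mm = 4,
                        subject_id = "synth") {
  if (age < 20) stop("brain age must be >= 20 years", call. = FALSE)
  a <- field$baseline - field$slope * (age - 20)
  if (noise_sd > 0)
    a <- a + with_seed(seed, array(stats::rnorm(length(a), 0, noise_sd),
                                   dim(a)))
  gm_volume(pmin(pmax(a, 0), 1), voxel_size_mm, subject_id)
}

render_volumes <- function(brain_ages, config, seed, id_prefix) {
  field <- atrophy_field(config$grid_dim, config$template_seed)
  lapply(seq_along(brain_ages), function(i)
    gm_template(brain_ages[i], field, config$noise_sd,
                seed_stream(seed, 100L + i), config$voxel_size_mm,
                sprintf("%s%04d", id_prefix, i)))
}

#' Generate the healthy training cohort
#'
#' Ages are truncated-normal draws matching the configured mean/SD/range;
#' each subject's volume is rendered at brain age equal to chronological
#' age (healthy aging by construction).
#'
#' @param config a [synth_config()].
#' @return list with `volumes` (list of [gm_volume]) and `ages` data.frame
#'   (`subject_id`, `age`).
#' @export
generate_training_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_train
  if (n == 0L)
    return(list(volumes = list(),
                ages = data.frame(subject_id = character(0),
                                  age = numeric(0))))
  ta <- config$train_age
  par <- truncnorm_params(ta$mean, ta$sd, ta$min, ta$max)
  ages <- with_seed(seed_stream(config$seed, 1L),
                    rtruncnorm(n, par[1], par[2], ta$min, ta$max))
  vols <- render_volumes(ages, config, seed_stream(config$seed, 2L), "train")
  list(volumes = vols,
       ages = data.frame(subject_id = vapply(vols, `[[`, "", "subject_id"),
                         age = ages, stringsAsFactors = FALSE))
}

draw_markers <- function(n, ref_g, seed) {
  with_seed(seed, {
    vals <- matrix(NA_real_, n, nrow(ref_g),
                   dimnames = list(NULL, ref_g$marker))
    zs <- vals
    for (i in seq_len(nrow(ref_g))) {
      z <- stats::rnorm(n)
      if (ref_g$family[i] == "lognormal") {
        s2 <- log(1 + (ref_g$sd[i] / ref_g$mean[i])^2)
        vals[, i] <- exp(log(ref_g$mean[i]) - s2 / 2 + sqrt(s2) * z)
      } else {
        x <- ref_g$mean[i] + ref_g$sd[i] * z
        # truncate to positive by redraw (negligible mass for these markers)
        while (any(x <= 0)) {
          bad <- x <= 0
          z[bad] <- stats::rnorm(sum(bad))
          x[bad] <- ref_g$mean[i] + ref_g$sd[i] * z[bad]
        }
        vals[, i] <- x
      }
      zs[, i] <- z
    }
    list(values = vals, z = zs)
  })
}

draw_cognitive <- function(n, gender, seed) {
  mm <- if (gender == "male") c(29.0, 1.1) else c(29.2, 0.9)
  ad <- if (gender == "male") c(10.3, 4.0) else c(8.9, 4.2)
  with_seed(seed, {
    out <- data.frame(row.names = seq_len(n))
    for (v in c("bl", "m12", "m24", "m36")) {
      out[[paste0("mmse_", v)]] <-
        pmin(30, round(rtruncnorm(n, mm[1], mm[2], 24, 30)))
      out[[paste0("cdr_", v)]] <-
        if (v == "bl") rep(0, n) else 0.5 * (stats::runif(n) < 0.08)
      out[[paste0("adas_", v)]] <-
        round(rtruncnorm(n, ad[1], ad[2], 0.5, Inf), 1)
    }
    out
  })
}

#' Generate a gender-specific elderly test cohort
#'
#' Markers are drawn per the configured family (moment-matched lognormal
#' for right-skewed markers, truncated normal otherwise) and site labels
#' uniformly over the configured sites. Each subject's latent brain age is
#' `chronological + sum_m gamma_m z_m + eps` where `z_m` is the marker's
#' z-score within its generating distribution and
#' `eps ~ N(0, residual_sd)`; volumes are rendered at that brain age.
#' Missingness is then applied per marker at the published rates (the
#' latent coupling is unaffected — biology does not depend on whether the
#' lab value was recorded).
#'
#' @param config a [synth_config()].
#' @param gender `"male"` or `"female"`.
#' @param render set `FALSE` to skip volume rendering (`volumes = NULL`);
#'   useful for statistics-only simulations on the latent gap.
#' @return list with `volumes`, `subjects` (id, age, gender, site, the 17
#'   markers, cognitive scores) and `truth` (latent brain age, gap and
#'   marker z-scores).
#' @export
generate_test_cohort <- function(config, gender = c("male", "female"),
                                 render = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  gender <- match.arg(gender)
  n <- if (gender == "male") config$n_male else config$n_female
  ref_g <- config$markers[config$markers$gender == gender, ]
  ta <- config$test_age[[gender]]
  base <- if (gender == "male") 10000L else 20000L
  par <- truncnorm_params(ta$mean, ta$sd, ta$min, ta$max)
  ages <- with_seed(seed_stream(config$seed, base + 1L),
                    rtruncnorm(n, par[1], par[2], ta$min, ta$max))
  mk <- draw_markers(n, ref_g, seed_stream(config$seed, base + 2L))
  eff <- config$effects[[gender]]
  accel <- rep(0, n)
  if (length(eff$gamma) > 0)
    accel <- as.vector(mk$z[, names(eff$gamma), drop = FALSE] %*% eff$gamma)
  eps <- if (eff$residual_sd > 0)
    with_seed(seed_stream(config$seed, base + 3L),
              stats::rnorm(n, 0, eff$residual_sd)) else rep(0, n)
  brain_age <- ages + accel + eps
  site <- with_seed(seed_stream(config$seed, base + 4L),
                    sample.int(config$n_sites, n, replace = TRUE))
  cog <- draw_cognitive(n, gender, seed_stream(config$seed, base + 5L))
  values <- mk$values
  if (config$apply_missingness) {
    # missingness is subject-concentrated, as in the emulated cohort: the
    # per-marker observed ns coexist with a complete-case n of ~107/118
    # (male) and ~104/110 (female), so missing cells cluster in a small
    # pool of incomplete subjects rather than scattering independently
    complete_rate <- if (gender == "male") 107 / 118 else 104 / 110
    n_pool <- min(n, max(0L, round(n * (1 - complete_rate))))
    if (n_pool > 0L) {
      values <- with_seed(seed_stream(config$seed, base + 6L), {
        pool <- sample.int(n, n_pool)
        for (i in seq_len(nrow(ref_g))) {
          k <- min(n_pool, round(ref_g$miss_rate[i] * n))
          if (k > 0L)
            values[sample(pool, k), ref_g$marker[i]] <- NA
        }
        values
      })
    }
  }
  ids <- sprintf("%s%04d", substr(gender, 1, 1), seq_len(n))
  vols <- NULL
  if (render) {
    vols <- render_volumes(brain_age, config,
                           seed_stream(config$seed, base + 7L),
                           substr(gender, 1, 1))
    ids <- vapply(vols, `[[`, "", "subject_id")
  }
  subjects <- cbind(
    data.frame(subject_id = ids, age = ages, gender = gender,
               site = paste0("site", site), stringsAsFactors = FALSE),
    as.data.frame(values), cog)
  truth <- data.frame(subject_id = ids, brain_age = brain_age,
                      gap = brain_age - ages, stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(mk$z)[
    , names(eff$gamma), drop = FALSE])
  list(volumes = vols, subjects = subjects, truth = truth)
}

#' Calibrate marker effect sizes and residual acceleration
#'
#' Converts target 1st-vs-4th-quartile BrainAGE contrasts (years) into
#' per-SD coupling coefficients `gamma`, and sets the residual
#' acceleration SD so the in-sample PLS R-squared of the brain-age gap on
#' the 17 standardized markers, at the design complete-case cohort size,
#' matches `r2_target`. (The published R-squared is the in-sample
#' statistic at n of about 107, which exceeds the population fraction by a
#' finite-sample optimism of roughly p/n; calibrating the population value
#' instead would make the generator overshoot.) A closed-form population
#' solve brackets a root search over simulated cohorts drawn once under a
#' fixed calibration seed, so the result is deterministic.
#'
#' For a marker whose value is a monotone transform of a standard normal
#' z, the expected planted contrast per unit gamma is
#' `E[z | top quartile] - E[z | bottom quartile] = 2 phi(z_0.75)/0.25`
#' (about 2.5426). The normal family uses this closed form; lognormal
#' families compute the factor by Monte Carlo (1e6 draws, fixed internal
#' seed), as the transform only needs to be monotone, not linear.
#'
#' @param targets named numeric vector: target contrast (years) per
#'   marker; negative values encode protective (reversed) coupling.
#' @param gender `"male"` or `"female"` (selects the reference table).
#' @param r2_target target in-sample PLS R-squared; `NA` fixes
#'   `residual_sd = 0`.
#' @param n_mc Monte Carlo size for lognormal contrast factors.
#' @param mc_seed fixed internal calibration seed.
#' @param n_cohort complete-case cohort size for the finite-sample solve
#'   (defaults to the published complete-case n: 107 male, 104 female).
#' @param n_cal_reps simulated cohorts averaged per candidate residual SD.
#' @param finite_sample set `FALSE` to calibrate the population fraction
#'   only (closed form, no simulation).
#' @return list with `gamma` (years per SD), `residual_sd` (years),
#'   `factors`, and the `r2_target` echo.
#' @export
calibrate_effects <- function(targets, gender = "male", r2_target = NA,
                              n_mc = 1e6, mc_seed = 20140523L,
                              n_cohort = NULL, n_cal_reps = 8L,
                              finite_sample = TRUE) {
  if (any(!is.finite(targets))) stop("targets must be finite", call. = FALSE)
  ref_g <- marker_reference()
  ref_g <- ref_g[ref_g$gender == gender, ]
  if (!all(names(targets) %in% ref_g$marker))
    stop("unknown marker(s): ",
         paste(setdiff(names(targets), ref_g$marker), collapse = ", "),
         call. = FALSE)
  factor_normal <- 2 * stats::dnorm(stats::qnorm(0.75)) / 0.25
  factors <- vapply(names(targets), function(m) {
    fam <- ref_g$family[ref_g$marker == m]
    if (fam == "normal") return(factor_normal)
    with_seed(mc_seed, {
      z <- stats::rnorm(n_mc)
      i <- ref_g$marker == m
      s2 <- log(1 + (ref_g$sd[i] / ref_g$mean[i])^2)
      val <- exp(log(ref_g$mean[i]) - s2 / 2 + sqrt(s2) * z)
      q <- stats::quantile(val, c(0.25, 0.75), type = 7)
      mean(z[val >= q[2]]) - mean(z[val <= q[1]])
    })
  }, numeric(1))
  gamma <- targets / factors
  residual_sd <- 0
  if (!is.na(r2_target)) {
    if (r2_target <= 0 || r2_target >= 1)
      stop("r2_target must lie in (0, 1)", call. = FALSE)
    n_res <- 2e5
    mk <- draw_markers(n_res, ref_g, seed_stream(mc_seed, 99L))
    planted <- as.vector(mk$z[, names(gamma), drop = FALSE] %*% gamma)
    xs <- scale(mk$values)
    fit <- stats::lm.fit(cbind(1, xs), planted)
    v_exp <- stats::var(planted - fit$residuals)
    v_planted <- stats::var(planted)
    s2 <- v_exp / r2_target - v_planted
    if (s2 <= 0)
      stop("infeasible r2_target: exceeds the variance the markers explain",
           call. = FALSE)
    residual_sd <- sqrt(s2)
    if (finite_sample) {
      if (is.null(n_cohort))
        n_cohort <- if (gender == "male") 107L else 104L
      # fixed replicate cohorts, shared across candidate SDs so the
      # objective is smooth and monotone in sigma
      reps <- lapply(seq_len(n_cal_reps), function(r) {
        mkr <- draw_markers(n_cohort, ref_g,
                            seed_stream(mc_seed, 200L + r))
        list(values = mkr$values,
             planted = as.vector(mkr$z[, names(gamma), drop = FALSE] %*%
                                   gamma),
             eps0 = with_seed(seed_stream(mc_seed, 300L + r),
                              stats::rnorm(n_cohort)))
      })
      mean_r2 <- function(sg) mean(vapply(reps, function(r)
        pls_regression(r$values, r$planted + sg * r$eps0)$r_squared,
        numeric(1)))
      lo <- residual_sd * 0.5; hi <- residual_sd * 3
      if (mean_r2(lo) > r2_target && mean_r2(hi) < r2_target) {
        residual_sd <- stats::uniroot(function(sg) mean_r2(sg) - r2_target,
                                      c(lo, hi),
                                      tol = residual_sd * 0.02)$root
      }
    }
  }
  list(gamma = gamma, residual_sd = residual_sd, factors = factors,
       r2_target = r2_target)
}
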