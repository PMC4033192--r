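# Gender-stratified statistics of BrainAGE against the 17 health markers:
# normality branching, site ANOVA, per-marker ANCOVA with gender
# interaction, PLS regression with VIP ranking, covariate-adjusted
# correlations, quartile contrasts with Holm correction, and the combined
# healthy/risky median-split analysis.

#' Shapiro-Wilk normality branch
#'
#' @param values numeric vector (n >= 3 after NA removal).
#' @param alpha significance level (default 0.05).
#' @return `"normal"` if the Shapiro-Wilk p-value exceeds `alpha`,
#'   otherwise `"non_normal"`. A constant vector is degenerate and returns
#'   `"non_normal"` with a warning.
#' @export
normality_test <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("normality test needs at least 3 observations", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("constant vector: treating as non-normal", call. = FALSE)
    return("non_normal")
  }
  # shapiro.test caps n at 5000; subsample deterministically if ever needed
  if (length(values) > 5000L)
    values <- values[round(seq(1L, length(values), length.out = 5000L))]
  p <- stats::shapiro.test(values)$p.value
  if (p > alpha) "normal" else "non_normal"
}

#' One-way fixed-effects ANOVA of scores across sites
#'
#' @param scores numeric outcome vector.
#' @param sites site labels (>= 2 non-empty levels).
#' @return list with `F`, `p`, `df` (c(between, within)), `n`.
#' @export
site_anova <- function(scores, sites) {
  ok <- !is.na(scores) & !is.na(sites)
  scores <- scores[ok]
  sites <- droplevels(factor(sites[ok]))
  if (nlevels(sites) < 2L)
    stop("site ANOVA needs at least 2 sites", call. = FALSE)
  fit <- stats::lm(scores ~ sites)
  an <- stats::anova(fit)
  list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
       df = c(an$Df[1], an$Df[2]), n = length(scores))
}

#' ANCOVA of BrainAGE on one marker with gender interaction
#'
#' Fits `score ~ gender + value + gender:value` (separate lines per
#' gender). Main effects are tested Type-II (each adjusted for the other,
#' excluding the interaction); the interaction is tested as the increment
#' over the main-effects model. All F denominators use the full-model MSE.
#'
#' @param scores BrainAGE scores (years).
#' @param values marker values (NA allowed; complete cases used).
#' @param gender two-level factor/character.
#' @param marker marker name for the result row.
#' @return data.frame row with `marker`, `F_gender`, `p_gender`,
#'   `F_value`, `p_value`, `F_interaction`, `p_interaction`, `n`.
#' @export
ancova_gender <- function(scores, values, gender, marker = "marker") {
  ok <- !is.na(scores) & !is.na(values) & !is.na(gender)
  scores <- scores[ok]; values <- values[ok]
  gender <- droplevels(factor(gender[ok]))
  if (nlevels(gender) != 2L)
    stop("both genders must be present", call. = FALSE)
  n <- length(scores)
  if (stats::sd(values) == 0) {
    warning("constant marker values: value effect undefined", call. = FALSE)
    return(data.frame(marker = marker, F_gender = NA_real_,
                      p_gender = NA_real_, F_value = NA_real_,
                      p_value = NA_real_, F_interaction = NA_real_,
                      p_interaction = NA_real_, n = n))
  }
  rss <- function(fml) sum(stats::lm(fml)$residuals^2)
  rss_full <- rss(scores ~ gender * values)
  rss_main <- rss(scores ~ gender + values)
  rss_nog  <- rss(scores ~ values)
  rss_nov  <- rss(scores ~ gender)
  df_res <- n - 4L
  mse <- rss_full / df_res
  tss <- sum((scores - mean(scores))^2)
  # a numerically zero SS is an exact zero effect even when the full model
  # is saturated (mse = 0), e.g. identical noiseless lines in both genders
  f_of <- function(ss) {
    ss <- max(ss, 0)
    if (ss <= 1e-12 * max(tss, 1)) return(0)
    ss / mse
  }
  F_g <- f_of(rss_nog - rss_main)
  F_v <- f_of(rss_nov - rss_main)
  F_i <- f_of(rss_main - rss_full)
  data.frame(marker = marker,
             F_gender = F_g, p_gender = stats::pf(F_g, 1, df_res, lower.tail = FALSE),
             F_value = F_v, p_value = stats::pf(F_v, 1, df_res, lower.tail = FALSE),
             F_interaction = F_i,
             p_interaction = stats::pf(F_i, 1, df_res, lower.tail = FALSE),
             n = n)
}

# NIPALS PLS1 with A components on pre-scaled X and centered y.
nipals_pls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  Tt <- matrix(0, n, A)
  Xa <- X; ya <- y
  a_done <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- Xa %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12) break
    pp <- crossprod(Xa, tt) / tt2
    qq <- sum(ya * tt) / tt2
    Xa <- Xa - tt %*% t(pp)
    ya <- ya - qq * tt
    W[, a] <- w; P[, a] <- pp; Q[a] <- qq; Tt[, a] <- tt
    a_done <- a
  }
  list(W = W[, seq_len(a_done), drop = FALSE],
       P = P[, seq_len(a_done), drop = FALSE],
       Q = Q[seq_len(a_done)],
       scores = Tt[, seq_len(a_done), drop = FALSE],
       n_components = a_done)
}

pls_coefficients <- function(fit) {
  # regression weights on the (scaled) predictors
  R <- fit$W %*% solve(crossprod(fit$P, fit$W))
  as.vector(R %*% fit$Q)
}

pls_vip <- function(fit) {
  ssy <- fit$Q^2 * colSums(fit$scores^2)       # per-component explained SS
  wn2 <- sweep(fit$W^2, 2, colSums(fit$W^2), "/")
  p <- nrow(fit$W)
  sqrt(p * as.vector(wn2 %*% ssy) / sum(ssy))
}

#' Partial least squares regression of BrainAGE on the markers
#'
#' NIPALS PLS1 on z-scored predictors and a centered response, over
#' complete cases only. `n_components = "auto"` minimizes leave-one-out
#' PRESS. Reports in-sample R-squared, regression weights on the
#' standardized predictors, VIP scores (mean square 1), and each marker's
#' contribution to the explained variance.
#'
#' @param markers numeric matrix/data.frame (subjects x markers).
#' @param scores BrainAGE scores (years).
#' @param n_components `"auto"` or a positive count.
#' @return An object of class `pls_result`: `n_components`, `r_squared`,
#'   `weights`, `vip`, `contribution`, `n_complete_cases`, `degenerate`.
#' @export
pls_regression <- function(markers, scores, n_components = "auto") {
  X0 <- as.matrix(markers)
  ok <- stats::complete.cases(X0) & !is.na(scores)
  X0 <- X0[ok, , drop = FALSE]
  y0 <- scores[ok]
  n <- nrow(X0); p <- ncol(X0)
  if (n < 3L) stop("PLS needs at least 3 complete cases", call. = FALSE)
  if (any(apply(X0, 2, stats::sd) == 0))
    stop("constant predictor column(s) in PLS input", call. = FALSE)
  if (stats::sd(y0) == 0) {
    warning("constant response: PLS degenerate", call. = FALSE)
    return(structure(list(n_components = 0L, r_squared = 0,
                          weights = stats::setNames(rep(0, p), colnames(X0)),
                          vip = stats::setNames(rep(NA_real_, p), colnames(X0)),
                          contribution = stats::setNames(rep(0, p), colnames(X0)),
                          n_complete_cases = n, degenerate = TRUE),
                     class = "pls_result"))
  }
  a_max <- min(n - 1L, p)
  scale_fit <- function(Xtr, ytr) {
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    list(mu = mu, sd = sdv, ym = mean(ytr),
         X = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"), y = ytr - mean(ytr))
  }
  if (identical(n_components, "auto")) {
    press <- numeric(a_max)
    for (i in seq_len(n)) {
      sc <- scale_fit(X0[-i, , drop = FALSE], y0[-i])
      fit <- nipals_pls1(sc$X, sc$y, a_max)
      xi <- (X0[i, ] - sc$mu) / sc$sd
      # cumulative prediction over components
      tpred <- numeric(fit$n_components)
      xres <- xi
      for (a in seq_len(fit$n_components)) {
        tpred[a] <- sum(xres * fit$W[, a])
        xres <- xres - tpred[a] * fit$P[, a]
      }
      cumpred <- sc$ym + cumsum(tpred * fit$Q)
      if (fit$n_components < a_max)
        cumpred <- c(cumpred, rep(cumpred[length(cumpred)],
                                  a_max - fit$n_components))
      press <- press + (y0[i] - cumpred)^2
    }
    A <- which.min(press)
  } else {
    A <- min(as.integer(n_components), a_max)
    if (A < 1L) stop("n_components must be >= 1", call. = FALSE)
  }
  sc <- scale_fit(X0, y0)
  fit <- nipals_pls1(sc$X, sc$y, A)
  yhat <- fit$scores %*% fit$Q
  tss <- sum(sc$y^2)
  r2 <- 1 - sum((sc$y - yhat)^2) / tss
  # per-component R2 increments attributed to markers by normalized
  # squared loading weights
  ssy <- fit$Q^2 * colSums(fit$scores^2)
  wn2 <- sweep(fit$W^2, 2, colSums(fit$W^2), "/")
  contribution <- as.vector(wn2 %*% (ssy / tss))
  weights <- pls_coefficients(fit)
  vip <- pls_vip(fit)
  nm <- colnames(X0)
  structure(list(n_components = fit$n_components, r_squared = r2,
                 weights = stats::setNames(weights, nm),
                 vip = stats::setNames(vip, nm),
                 contribution = stats::setNames(contribution, nm),
                 n_complete_cases = n, degenerate = FALSE),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("<pls_result> %d components, R^2 = %.3f, n = %d\n",
              x$n_components, x$r_squared, x$n_complete_cases))
  invisible(x)
}

#' Covariate-adjusted correlation
#'
#' Residualizes `x` and `y` on the covariates by least squares (site
#' columns one-hot encoded with singleton sites pooled), then correlates
#' the residuals with Pearson when both residual vectors pass the
#' Shapiro-Wilk branch, otherwise Spearman. The p-value uses the t
#' approximation on the residual degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame of numeric covariates and/or factors
#'   (e.g. age and site); NULL or empty for a plain correlation.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `method`, `n`, `df`.
#' @export
adjusted_correlation <- function(x, y, covariates = NULL,
                                 method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  design <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    covariates <- as.data.frame(covariates)
    cols <- lapply(names(covariates), function(nm) {
      v <- covariates[[nm]]
      if (is.numeric(v)) {
        m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
        return(m)
      }
      f <- factor(v)
      counts <- table(f)
      singleton <- names(counts)[counts == 1L]
      lv <- as.character(f)
      lv[lv %in% singleton] <- ".pooled"
      f <- factor(lv)
      stats::model.matrix(~ f)[, -1, drop = FALSE]
    })
    design <- do.call(cbind, cols)
  }
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(design)) ok <- ok & stats::complete.cases(design)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- 0L
  if (!is.null(design)) {
    design <- design[ok, , drop = FALSE]
    X <- cbind(`(Intercept)` = 1, design)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("collinear covariate column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    x <- qr.resid(qx, x)
    y <- qr.resid(qx, y)
    k <- ncol(X) - 1L
  } else {
    x <- x - mean(x); y <- y - mean(y)
  }
  if (n < k + 4L) stop("too few complete cases for adjustment", call. = FALSE)
  if (method == "auto") {
    method <- if (normality_test(x) == "normal" &&
                  normality_test(y) == "normal") "pearson" else "spearman"
  }
  r <- if (method == "pearson") stats::cor(x, y) else
    stats::cor(x, y, method = "spearman")
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, 1e-15))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(r = r, p = min(p, 1), method = method, n = n, df = df)
}

#' Quartile contrast of BrainAGE for one marker
#'
#' Splits the (complete-case) marker values at the type-7 Q1/Q3 quantiles;
#' the contrast groups are `value <= Q1` vs `value >= Q3`. The two-sample
#' test is Student's t when both groups' scores pass the normality branch,
#' otherwise Mann-Whitney. The reported effect is the absolute difference
#' of group mean BrainAGE in years.
#'
#' @param scores BrainAGE scores (years).
#' @param values marker values.
#' @param marker,gender labels for the result row.
#' @return data.frame row: group means/SDs/sizes, `abs_diff`, `test`,
#'   `p_raw` (Holm adjustment is applied across a marker family by the
#'   caller).
#' @export
quartile_contrast <- function(scores, values, marker = "marker",
                              gender = NA_character_) {
  ok <- !is.na(scores) & !is.na(values)
  scores <- scores[ok]; values <- values[ok]
  if (length(scores) < 8L)
    stop("quartile contrast needs at least 8 complete cases", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  g1 <- values <= q[1]
  g4 <- values >= q[2]
  if (!any(g1) || !any(g4) || q[1] == q[2])
    stop("degenerate quartile split for ", marker, call. = FALSE)
  s1 <- scores[g1]; s4 <- scores[g4]
  tst <- compare_groups(s1, s4)
  data.frame(marker = marker, gender = gender,
             n1 = length(s1), mean1 = mean(s1), sd1 = stats::sd(s1),
             n4 = length(s4), mean4 = mean(s4), sd4 = stats::sd(s4),
             abs_diff = abs(mean(s4) - mean(s1)),
             test = tst$test, p_raw = tst$p, stringsAsFactors = FALSE)
}

#' Holm step-down multiple-testing adjustment
#'
#' Sort ascending, multiply the k-th smallest p by `m - k + 1`, enforce a
#' running maximum and cap at 1; values are returned in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Combined healthy/risky median-split groups
#'
#' Per-marker medians are taken over the sample's non-missing values.
#' "Healthy" subjects lie at or below the median on every non-flipped
#' marker and at or above it on every flipped one; "risky" is the mirrored
#' condition. Both definitions are inclusive, so subjects sitting exactly
#' at all medians belong to both groups and are flagged.
#'
#' @param records data.frame containing the marker columns.
#' @param markers character vector of marker column names.
#' @param flip subset of `markers` where high values are healthy.
#' @return list with logical vectors `healthy`, `risky`, `both` (row-wise,
#'   NA-complete rows only are eligible), and the `medians` used.
#' @export
combined_group_split <- function(records, markers, flip = character(0)) {
  if (!all(markers %in% names(records)))
    stop("missing marker column(s): ",
         paste(setdiff(markers, names(records)), collapse = ", "),
         call. = FALSE)
  if (!all(flip %in% markers))
    stop("`flip` must be a subset of `markers`", call. = FALSE)
  vals <- as.matrix(records[, markers, drop = FALSE])
  med <- apply(vals, 2, stats::median, na.rm = TRUE)
  complete <- stats::complete.cases(vals)
  low <- sweep(vals, 2, med, "<=")
  high <- sweep(vals, 2, med, ">=")
  hd <- low; rd <- high
  hd[, flip] <- high[, flip, drop = FALSE]
  rd[, flip] <- low[, flip, drop = FALSE]
  healthy <- complete & apply(hd, 1, all)
  risky <- complete & apply(rd, 1, all)
  healthy[is.na(healthy)] <- FALSE
  risky[is.na(risky)] <- FALSE
  if (!any(healthy) || !any(risky))
    stop("degenerate combined split; medians: ",
         paste(sprintf("%s=%.3g", names(med), med), collapse = ", "),
         call. = FALSE)
  list(healthy = healthy, risky = risky, both = healthy & risky,
       medians = med)
}

#' Two-sample comparison with normality branching
#'
#' Student's t-test (equal variances) when both groups pass the
#' Shapiro-Wilk branch, Mann-Whitney otherwise. Groups of fewer than 3
#' observations fall back to the Mann-Whitney branch (normality is
#' untestable). Two constant equal groups return p = 1 by convention.
#'
#' @param a,b numeric outcome vectors (each n >= 2).
#' @return list with `test`, `statistic`, `p`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`.
#' @export
compare_groups <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  desc <- list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("zero variance in both groups with equal means: p = 1",
              call. = FALSE)
      return(c(list(test = "t", statistic = 0, p = 1), desc))
    }
    return(c(list(test = "t", statistic = Inf, p = 0), desc))
  }
  normal <- length(a) >= 3L && length(b) >= 3L &&
    normality_test(a) == "normal" && normality_test(b) == "normal"
  if (normal) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    c(list(test = "t", statistic = unname(tt$statistic), p = tt$p.value),
      desc)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    c(list(test = "mann_whitney", statistic = unname(wt$statistic),
           p = wt$p.value), desc)
  }
}
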