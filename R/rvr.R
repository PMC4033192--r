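# Relevance vector regression (sparse Bayesian learning) with a degree-1
# polynomial kernel. The kernel is realized as the homogeneous dot product
# K_ij = x_i . x_j with an explicit bias column in the design matrix, which
# is equivalent to the inhomogeneous linear kernel up to reparameterization.
#
# Hyperparameter iteration (evidence maximization):
#   Sigma = (A + beta Phi' Phi)^-1,   mu = beta Sigma Phi' t
#   gamma_i = 1 - alpha_i Sigma_ii
#   alpha_i <- gamma_i / mu_i^2,      beta <- (N - sum gamma) / ||t - Phi mu||^2
# Basis functions whose alpha exceeds `prune_alpha` are removed; iteration
# stops when max |delta log alpha| over surviving bases falls below `tol`.

# Posterior solve for fixed hyperparameters: Sigma = (A + beta Phi'Phi)^-1,
# mu = beta Sigma Phi' t. Equals the ridge solve (A/beta + Phi'Phi)^-1 Phi' t.
rvr_posterior <- function(Phi, alpha, beta, t_vec) {
  H <- crossprod(Phi) * beta
  diag(H) <- diag(H) + alpha
  Sigma <- tryCatch(chol2inv(chol(H)), error = function(e) {
    diag(H) <- diag(H) + max(diag(H)) * 1e-10
    chol2inv(chol(H))
  })
  list(Sigma = Sigma, mu = beta * (Sigma %*% crossprod(Phi, t_vec)))
}

#' Fit a relevance vector regression model
#'
#' @param X numeric matrix of reduced features (subjects in rows, >= 3).
#' @param ages numeric target vector (years), one per row of `X`.
#' @param tol convergence tolerance on `max |delta log alpha|`.
#' @param max_iter maximum number of update sweeps.
#' @param prune_alpha precision threshold above which a basis is pruned.
#' @return An object of class `rvr_model` with the retained kernel bases
#'   (`relevance_indices`, `training_points`), posterior mean weights
#'   (`weights_mu`), hyperparameters (`alpha`, `beta`), `has_bias`, and
#'   bookkeeping (`n_iter`, `converged`).
#' @export
fit_rvr <- function(X, ages, tol = 1e-6, max_iter = 1000L,
                    prune_alpha = 1e12) {
  X <- as.matrix(X)
  t_vec <- as.numeric(ages)
  n <- nrow(X)
  if (length(t_vec) != n) stop("rows of X must match ages length", call. = FALSE)
  if (n < 3L) stop("RVR needs at least 3 training subjects", call. = FALSE)
  K <- tcrossprod(X)                       # K_ij = x_i . x_j
  Phi_full <- cbind(bias = 1, K)           # column 1 = bias, j+1 = basis j
  m_full <- ncol(Phi_full)
  active <- seq_len(m_full)
  alpha <- rep(1 / n^2, m_full)
  beta <- 10 / max(stats::var(t_vec), 1e-8)
  converged <- FALSE
  it <- 0L
  mu <- NULL
  repeat {
    it <- it + 1L
    Phi <- Phi_full[, active, drop = FALSE]
    post <- rvr_posterior(Phi, alpha[active], beta, t_vec)
    Sigma <- post$Sigma
    mu <- post$mu
    gam <- 1 - alpha[active] * diag(Sigma)
    alpha_new <- pmax(gam, 1e-12) / pmax(mu[, 1]^2, 1e-300)
    resid <- t_vec - Phi %*% mu
    beta_new <- max(n - sum(gam), 1e-6) / max(sum(resid^2), 1e-12)
    keep <- alpha_new <= prune_alpha
    if (!any(keep))
      stop("degenerate RVR model: all bases pruned", call. = FALSE)
    delta <- max(abs(log(alpha_new[keep]) - log(alpha[active][keep])))
    alpha[active] <- alpha_new
    active <- active[keep]
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning("RVR did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  # final posterior solve on the surviving set
  Phi <- Phi_full[, active, drop = FALSE]
  mu <- rvr_posterior(Phi, alpha[active], beta, t_vec)$mu
  has_bias <- 1L %in% active
  rel <- setdiff(active, 1L) - 1L          # training-sample indices
  structure(
    list(kernel_spec = "poly1_dot_plus_bias",
         relevance_indices = rel,
         weights_mu = mu[, 1],
         alpha = alpha[active],
         beta = beta,
         has_bias = has_bias,
         training_points = X[rel, , drop = FALSE],
         n_train = n,
         n_iter = it,
         converged = converged),
    class = "rvr_model")
}

#' Predict ages with a fitted RVR model
#'
#' `y_hat = w0 + sum_j w_j (x . x_j)` over the retained relevance vectors
#' (the bias term is present only if it survived pruning).
#'
#' @param model an `rvr_model`.
#' @param X matrix of reduced features with the training dimension.
#' @return Numeric vector of estimated ages (years).
#' @export
predict_age <- function(model, X) {
  stopifnot(inherits(model, "rvr_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$training_points) &&
      nrow(model$training_points) > 0)
    stop("feature dimension does not match the trained model", call. = FALSE)
  w <- model$weights_mu
  out <- numeric(nrow(X))
  j <- 1L
  if (model$has_bias) { out <- out + w[1L]; j <- 2L }
  if (length(model$relevance_indices) > 0) {
    Kt <- X %*% t(model$training_points)
    out <- out + as.vector(Kt %*% w[j:length(w)])
  }
  out
}

#' @export
print.rvr_model <- function(x, ...) {
  cat(sprintf(paste0("<rvr_model> %d/%d relevance vectors%s, beta %.4g, ",
                     "%d iterations (%s)\n"),
              length(x$relevance_indices), x$n_train,
              if (x$has_bias) " + bias" else "", x$beta, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
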