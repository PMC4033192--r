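# Principal component reduction of the voxel feature matrix. With the
# model's linear kernel, full retention is information-lossless (orthonormal
# rotation preserves the Gram matrix), so the default keeps every
# non-degenerate component.

#' Fit a PCA model to a feature matrix
#'
#' Centered SVD decomposition. `n_components = "all"` retains every
#' component whose variance exceeds machine tolerance relative to the
#' leading one.
#'
#' @param features numeric matrix, subjects in rows (>= 2 rows).
#' @param n_components `"all"` or a positive integer
#'   (capped at `min(n - 1, p)`).
#' @return An object of class `pca_model` with fields `mean_vector`,
#'   `components` (columns are orthonormal loadings), `explained_variance`.
#' @export
fit_pca <- function(features, n_components = "all") {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  mu <- colMeans(features)
  xc <- sweep(features, 2L, mu, "-")
  sv <- svd(xc, nu = 0)
  var_all <- sv$d^2 / (n - 1)
  keep_max <- min(n - 1L, ncol(features))
  tol <- max(var_all[1], 0) * 1e-12
  nz <- sum(var_all[seq_len(keep_max)] > tol)
  k <- if (identical(n_components, "all")) nz else {
    if (!is.numeric(n_components) || n_components < 1)
      stop("`n_components` must be \"all\" or a positive count", call. = FALSE)
    min(as.integer(n_components), keep_max)
  }
  k <- max(k, 1L)
  structure(
    list(mean_vector = mu,
         components = sv$v[, seq_len(k), drop = FALSE],
         explained_variance = var_all[seq_len(k)]),
    class = "pca_model")
}

#' Project features onto a fitted PCA basis
#'
#' @param model a `pca_model`.
#' @param features matrix with the training feature dimension.
#' @return Score matrix (rows = subjects, columns = components).
#' @export
pca_transform <- function(model, features) {
  stopifnot(inherits(model, "pca_model"))
  features <- as.matrix(features)
  if (ncol(features) != length(model$mean_vector))
    stop("feature dimension does not match the PCA model", call. = FALSE)
  sweep(features, 2L, model$mean_vector, "-") %*% model$components
}
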