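# Preprocessing of registered GM density maps: Gaussian smoothing at the
# native grid, block-mean downsampling to the working resolution, mask
# construction from the training sample, and vectorization into the
# subjects-by-voxels feature matrix.

# Discrete Gaussian kernel sampled at integer offsets, normalized to sum 1.
# Radius covers +/- 4 sigma (minimum 1) so truncation error is negligible.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# 1D convolution along dimension `along` of a 3D array with replicate
# (nearest-value) boundary handling. Implemented as a weighted sum of
# index-shifted copies; clamped indices realize the replication.
convolve_axis <- function(a, kernel, along) {
  n <- dim(a)[along]
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(a))
  idx_all <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    idx <- idx_all
    idx[[along]] <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + kernel[j] * a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  out
}

#' Smooth a GM volume with a Gaussian kernel of given FWHM
#'
#' Separable 3D Gaussian smoothing with `sigma = fwhm_mm / (2 sqrt(2 ln 2))`
#' converted to voxel units through the volume's voxel size. Boundaries are
#' handled by nearest-value replication, so a constant field is an exact
#' fixed point. The output is clipped back to \[0, 1\].
#'
#' @param vol a [gm_volume].
#' @param fwhm_mm full width at half maximum of the kernel, in mm (>= 0;
#'   0 returns the input unchanged).
#' @return Smoothed [gm_volume] on the same grid.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "gm_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm < 0)
    stop("`fwhm_mm` must be a non-negative scalar", call. = FALSE)
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size_mm
  k <- gaussian_kernel_1d(sigma_vox)
  a <- vol$data
  for (axis in 1:3) if (dim(a)[axis] > 1L) a <- convolve_axis(a, k, axis)
  gm_volume(pmin(pmax(a, 0), 1), vol$voxel_size_mm, vol$subject_id)
}

#' Downsample a GM volume by block-mean pooling
#'
#' Pools non-overlapping cubes of edge `target_mm / voxel_size_mm` voxels by
#' their arithmetic mean; trailing partial blocks are averaged over the
#' voxels available. The target edge must be a positive integer multiple of
#' the current voxel size.
#'
#' @param vol a [gm_volume].
#' @param target_mm output voxel edge length (mm).
#' @return [gm_volume] at the target resolution.
#' @export
resample_to_grid <- function(vol, target_mm) {
  stopifnot(inherits(vol, "gm_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a positive scalar", call. = FALSE)
  f <- target_mm / vol$voxel_size_mm
  if (abs(f - round(f)) > 1e-8 || round(f) < 1)
    stop("`target_mm` must be a positive integer multiple of voxel_size_mm",
         call. = FALSE)
  f <- as.integer(round(f))
  if (f == 1L) return(gm_volume(vol$data, target_mm, vol$subject_id))
  d <- dim(vol$data)
  dn <- ceiling(d / f)
  blk <- lapply(1:3, function(ax) (seq_len(d[ax]) - 1L) %/% f + 1L)
  # mean per block = sum / count, accumulated via tapply-free rowsum folds
  a <- vol$data
  sums <- a
  cnts <- array(1, d)
  for (ax in 1:3) {
    sums <- fold_axis(sums, blk[[ax]], ax, dn[ax])
    cnts <- fold_axis(cnts, blk[[ax]], ax, dn[ax])
  }
  gm_volume(sums / cnts, target_mm, vol$subject_id)
}

# Sum-reduce a 3D array along one axis according to a block index vector.
fold_axis <- function(a, blocks, along, n_out) {
  d <- dim(a)
  perm <- c(along, setdiff(1:3, along))
  m <- matrix(aperm(a, perm), nrow = d[along])
  s <- rowsum(m, group = blocks, reorder = TRUE)
  out <- array(s, dim = c(n_out, d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Build a voxel inclusion mask from training volumes
#'
#' A voxel is retained when its mean GM density across the training volumes
#' exceeds `threshold` (a conventional VBM-style analysis mask).
#'
#' @param training_vols non-empty list of [gm_volume]s sharing one grid.
#' @param threshold scalar in \[0, 1).
#' @return A [voxel_mask].
#' @export
build_mask <- function(training_vols, threshold = 0.1) {
  if (length(training_vols) == 0L)
    stop("`training_vols` must be non-empty", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1)
    stop("`threshold` must lie in [0, 1)", call. = FALSE)
  d <- dim(training_vols[[1]]$data)
  acc <- array(0, d)
  for (v in training_vols) {
    stopifnot(inherits(v, "gm_volume"))
    if (!identical(dim(v$data), d))
      stop("all training volumes must share a grid shape", call. = FALSE)
    acc <- acc + v$data
  }
  flags <- (acc / length(training_vols)) > threshold
  if (!any(flags))
    stop("degenerate mask: no voxel exceeds the threshold", call. = FALSE)
  voxel_mask(flags)
}

#' Vectorize volumes through a mask into a feature matrix
#'
#' Row i holds the masked voxels of volume i in R's column-major array scan
#' order (first axis fastest); this order is the package-wide contract and
#' is inverted exactly by [scatter_to_volume()].
#'
#' @param vols list of [gm_volume]s matching the mask grid.
#' @param mask a [voxel_mask].
#' @return Numeric matrix with `subject_order` attribute (row ids).
#' @export
vectorize <- function(vols, mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(vols) == 0L) {
    out <- matrix(numeric(0), nrow = 0, ncol = mask$n_active)
    attr(out, "subject_order") <- character(0)
    return(out)
  }
  sel <- which(mask$flags)
  out <- matrix(0, nrow = length(vols), ncol = length(sel))
  ids <- character(length(vols))
  for (i in seq_along(vols)) {
    v <- vols[[i]]
    stopifnot(inherits(v, "gm_volume"))
    if (!identical(dim(v$data), dim(mask$flags)))
      stop("volume grid does not match mask grid", call. = FALSE)
    out[i, ] <- v$data[sel]
    ids[i] <- v$subject_id
  }
  attr(out, "subject_order") <- ids
  out
}

#' Scatter one feature row back into a volume
#'
#' Inverse of [vectorize()] for a single row: masked voxels receive the row
#' values (same scan order), unmasked voxels get `fill`.
#'
#' @param row numeric vector of length `mask$n_active`.
#' @param mask a [voxel_mask].
#' @param voxel_size_mm voxel size of the reconstructed volume.
#' @param fill value for unmasked voxels.
#' @param subject_id identifier for the reconstructed volume.
#' @return A [gm_volume].
#' @export
scatter_to_volume <- function(row, mask, voxel_size_mm, fill = 0,
                              subject_id = "scatter") {
  stopifnot(inherits(mask, "voxel_mask"))
  if (length(row) != mask$n_active)
    stop("row length must equal mask n_active", call. = FALSE)
  a <- array(fill, dim(mask$flags))
  a[which(mask$flags)] <- row
  gm_volume(a, voxel_size_mm, subject_id)
}
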