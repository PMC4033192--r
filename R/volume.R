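#' Gray-matter density volume
#'
#' A `gm_volume` wraps a 3D array of gray-matter density values (unitless
#' proportions in \[0, 1\]) on an isotropic grid, together with its voxel edge
#' length in millimetres and a subject identifier. All preprocessing
#' operations consume and produce this container.
#'
#' @param data 3D numeric array of GM density, all values in \[0, 1\].
#' @param voxel_size_mm positive scalar voxel edge length (mm).
#' @param subject_id identifier string.
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(data, voxel_size_mm, subject_id = "subj") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L))
    stop("grid dimensions must each be >= 1", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      !is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar", call. = FALSE)
  if (anyNA(data) || any(data < 0) || any(data > 1))
    stop("GM density values must be finite and within [0, 1]", call. = FALSE)
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         subject_id = as.character(subject_id)),
    class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<gm_volume> %s: %dx%dx%d @ %g mm, mean GM %.4f\n",
              x$subject_id, d[1], d[2], d[3], x$voxel_size_mm,
              mean(x$data)))
  invisible(x)
}

#' Voxel inclusion mask
#'
#' Boolean grid marking the voxels that enter the feature matrix.
#'
#' @param flags logical 3D array.
#' @return An object of class `voxel_mask` with fields `flags` and
#'   `n_active`.
#' @export
voxel_mask <- function(flags) {
  if (!is.array(flags) || length(dim(flags)) != 3L || !is.logical(flags))
    stop("`flags` must be a logical 3D array", call. = FALSE)
  if (anyNA(flags)) stop("mask flags must not contain NA", call. = FALSE)
  n_active <- sum(flags)
  if (n_active < 1L)
    stop("degenerate mask: zero active voxels", call. = FALSE)
  structure(list(flags = flags, n_active = n_active), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$flags)
  cat(sprintf("<voxel_mask> %dx%dx%d, %d/%d active\n",
              d[1], d[2], d[3], x$n_active, prod(d)))
  invisible(x)
}
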