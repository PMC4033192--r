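# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O for isotropic 3D
# volumes. No NIfTI package is assumed; only the fields this package needs
# are honored: dim, datatype, pixdim, scl_slope/scl_inter, vox_offset.
# Written volumes are float32, little-endian, with the identity sform.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Supports uncompressed `.nii` and gzipped `.nii.gz` single-file NIfTI-1
#' with uint8/int16/int32/float32/float64 payloads. The voxel size is taken
#' from the header `pixdim` diagonal, which must be isotropic to 1e-6.
#'
#' @param path file path.
#' @param subject_id identifier attached to the returned volume (defaults
#'   to the file base name).
#' @param clip clip values into \[0, 1\] (default TRUE; GM density contract).
#' @return A [gm_volume].
#' @export
read_nifti_volume <- function(path, subject_id = NULL, clip = TRUE) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header: ", path, call. = FALSE)
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4, endian = "big")
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
    endian <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path, call. = FALSE)
  dims <- readBin(hdr[41:56], "integer", n = 8, size = 2, endian = endian)
  if (dims[1] < 3L) stop("expected a 3D volume: ", path, call. = FALSE)
  if (dims[1] > 3L && any(dims[(5:(dims[1] + 1))] > 1L))
    stop("only single-frame 3D volumes are supported: ", path, call. = FALSE)
  d <- dims[2:4]
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  spec <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(spec))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- readBin(hdr[77:108], "double", n = 8, size = 4, endian = endian)
  vox <- pixdim[2:4]
  if (diff(range(vox)) > 1e-6 * max(vox))
    stop("anisotropic voxels are not supported (pixdim ",
         paste(signif(vox, 6), collapse = "x"), ")", call. = FALSE)
  vox_offset <- readBin(hdr[109:112], "double", size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "double", size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "double", size = 4, endian = endian)
  skip <- max(as.integer(round(vox_offset)), 348L) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI payload: ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (clip) vals <- pmin(pmax(vals, 0), 1)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  gm_volume(array(vals, d), vox[1], subject_id)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' Writes single-file NIfTI-1 (`n+1` magic), float32 little-endian, with
#' the voxel size on the pixdim diagonal.
#'
#' @param vol a [gm_volume] (or a logical/numeric 3D array plus
#'   `voxel_size_mm`).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm required when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, voxel_size_mm = NULL) {
  if (inherits(vol, "voxel_mask"))
    vol <- list(data = array(as.double(vol$flags), dim(vol$flags)),
                voxel_size_mm = voxel_size_mm)
  if (is.array(vol))
    vol <- list(data = vol, voxel_size_mm = voxel_size_mm)
  if (is.null(vol$voxel_size_mm))
    stop("voxel size required to write NIfTI", call. = FALSE)
  d <- dim(vol$data)
  stopifnot(length(d) == 3L)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                      # sizeof_hdr
  w_raw(36)                        # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L)) # dim[8]
  w_f32(c(0, 0, 0))                # intent_p1..p3
  w_i16(0L)                        # intent_code
  w_i16(16L)                       # datatype = float32
  w_i16(32L)                       # bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, rep(vol$voxel_size_mm, 3), 0, 0, 0, 0))  # pixdim[8]
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); writeBin(as.raw(c(0L, 2L)), con)  # slice_end, slice_code, xyzt_units (mm)
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  w_raw(80 + 24)                   # descrip, aux_file
  w_i16(c(0L, 1L))                 # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                 # quatern b,c,d, qoffset x,y,z
  w_f32(c(vol$voxel_size_mm, 0, 0, 0))  # srow_x
  w_f32(c(0, vol$voxel_size_mm, 0, 0))  # srow_y
  w_f32(c(0, 0, vol$voxel_size_mm, 0))  # srow_z
  w_raw(16)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4)                         # extension flag
  w_f32(as.vector(vol$data))
  invisible(path)
}
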