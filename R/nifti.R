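# Minimal NIfTI-1 I/O (single-file .nii, uncompressed). Covers the subset
# of the format the pipeline needs: 3-D/4-D images, dtypes uint8 / int16 /
# int32 / float32 / float64, sform affine, pixdim with TR in pixdim[4].
# Little- and big-endian files are read; files are always written
# little-endian with sform_code = 1.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

#' Read a NIfTI-1 volume
#'
#' @param path path to an uncompressed `.nii` file.
#' @return a list with `data` (3-D or 4-D numeric array), `grid`
#'   (a [volume_grid()]), `tr_s` (pixdim\[4\], seconds; `NA` for 3-D files)
#'   and `datatype` (NIfTI datatype code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path))
    fp_stop("funcphen_file_not_found", "NIfTI file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int32(sizeof_hdr) != 348L)
      fp_stop("funcphen_bad_nifti", "not a NIfTI-1 file (sizeof_hdr): %s", path)
  }
  seek(con, 40)
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 254)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 280)
  srow <- matrix(readBin(con, "double", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!magic %in% c("n+1", "ni1"))
    fp_stop("funcphen_bad_nifti", "missing NIfTI magic in %s", path)

  ndim <- dim8[1]
  if (ndim < 3L || ndim > 4L)
    fp_stop("funcphen_bad_nifti", "unsupported NIfTI dimensionality %d", ndim)
  dims <- dim8[2:(1 + ndim)]
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec))
    fp_stop("funcphen_bad_nifti", "unsupported NIfTI datatype %d", datatype)

  n <- prod(as.double(dims))
  seek(con, as.integer(round(vox_offset)))
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n)
    fp_stop("funcphen_bad_nifti", "truncated NIfTI data in %s", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = dims)

  vox <- abs(pixdim[2:4])
  vox[vox == 0] <- 1
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(vox, 1))
  # guard against header affines whose column norms drifted in float32
  cn <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(cn - vox) > 1e-6)) vox <- cn
  grid <- volume_grid(dims[1:3], vox, affine)
  tr_s <- if (ndim == 4L) pixdim[5] else NA_real_
  list(data = data, grid = grid, tr_s = tr_s, datatype = datatype)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3-D or 4-D numeric array.
#' @param path output `.nii` path.
#' @param grid a [volume_grid()] matching `dim(data)[1:3]`.
#' @param tr_s repetition time in seconds, stored in pixdim\[4\] (4-D data).
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64, the default — lossless for R doubles).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, grid, tr_s = 0, datatype = 64L) {
  stopifnot(inherits(grid, "volume_grid"))
  dims <- dim(data)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    fp_stop("funcphen_bad_nifti", "data must be a 3-D or 4-D array")
  if (!all(dims[1:3] == grid$shape))
    fp_stop("funcphen_bad_nifti", "data dims do not match grid shape")
  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec))
    fp_stop("funcphen_bad_nifti", "unsupported NIfTI datatype %d", datatype)

  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                  # sizeof_hdr
  w_raw(36L)                                   # data_type..dim_info
  dim8 <- rep(1L, 8L)
  dim8[1] <- length(dims)
  dim8[2:(1 + length(dims))] <- dims
  w_i16(dim8)                                  # dim
  w_f32(c(0, 0, 0)); w_i16(0L)                 # intent
  w_i16(datatype); w_i16(spec$bitpix); w_i16(0L)
  pixdim <- c(1, grid$voxel_size_mm, tr_s, 0, 0, 0)
  w_f32(pixdim)                                # pixdim
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope / scl_inter
  w_i16(0L); w_raw(2L)                         # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i32(c(0L, 0L))                             # glmax, glmin
  w_raw(104L)                                  # descrip + aux_file
  w_i16(0L); w_i16(1L)                         # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                             # quatern / qoffset
  w_f32(t(grid$affine[1:3, ]))                 # srow_x/y/z
  w_raw(16L)                                   # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); w_raw(1L)
  w_raw(4L)                                    # extension indicator

  vals <- as.vector(data)
  if (spec$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L, endian = "little")
  readBin(rev(b), "integer", 1L, size = 4L, endian = "little")
}

#' Read a 4-D BOLD NIfTI file into a [bold_series()]
#'
#' Columns are ordered lexicographically by voxel index; with a mask, only
#' in-mask voxels are kept.
#'
#' @param path path to a 4-D NIfTI file.
#' @param mask optional [roi_mask()] restricting the voxels; must lie
#'   inside the volume grid.
#' @param tr_s repetition time override in seconds; defaults to the file's
#'   pixdim\[4\].
#' @param subject_id subject identifier; defaults to the file base name.
#' @return a [bold_series()].
#' @export
read_bold <- function(path, mask = NULL, tr_s = NULL, subject_id = NULL) {
  vol <- read_nifti(path)
  if (length(dim(vol$data)) != 4L)
    fp_stop("funcphen_not_4d", "expected a 4-D NIfTI volume: %s", path)
  shape <- vol$grid$shape
  if (is.null(mask)) {
    idx <- lex_order_voxels(as.matrix(expand.grid(
      i = 0:(shape[1] - 1), j = 0:(shape[2] - 1), k = 0:(shape[3] - 1))))
  } else {
    if (any(t(mask$voxel_index) >= shape))
      fp_stop("funcphen_mask_out_of_bounds",
              "mask '%s' does not fit inside the volume grid", mask$label)
    idx <- mask$voxel_index        # already lexicographic
  }
  nt <- dim(vol$data)[4]
  flat <- matrix(vol$data, nrow = prod(shape), ncol = nt)
  data <- t(flat[voxel_linear_index(idx, shape), , drop = FALSE])
  if (is.null(tr_s)) tr_s <- vol$tr_s
  if (is.null(subject_id))
    subject_id <- sub("\\.nii$", "", basename(path))
  bold_series(subject_id, data, idx, tr_s, vol$grid)
}

#' Write a [bold_series()] as a 4-D NIfTI file
#'
#' Voxels outside the series' `voxel_index` are written as zero.
#'
#' @param series a [bold_series()].
#' @param path output `.nii` path.
#' @param datatype NIfTI datatype code (default 64, float64 — lossless).
#' @return `path`, invisibly.
#' @export
write_bold <- function(series, path, datatype = 64L) {
  shape <- series$grid$shape
  nt <- n_timepoints(series)
  flat <- matrix(0, nrow = prod(shape), ncol = nt)
  flat[voxel_linear_index(series$voxel_index, shape), ] <- t(series$data)
  write_nifti(array(flat, dim = c(shape, nt)), path, series$grid,
              tr_s = series$tr_s, datatype = datatype)
}

#' Write / read an ROI mask as a NIfTI label volume plus JSON sidecar
#'
#' The mask is stored as a uint8 volume (1 inside, 0 outside) with a
#' `.json` sidecar holding the label.
#'
#' @param mask an [roi_mask()].
#' @param path output `.nii` path; the sidecar is `path` with `.json`
#'   substituted.
#' @return `path` (write) or an [roi_mask()] (read).
#' @export
write_mask <- function(mask, path) {
  vol <- array(0L, dim = mask$grid$shape)
  vol[voxel_linear_index(mask$voxel_index, mask$grid$shape)] <- 1L
  write_nifti(vol, path, mask$grid, datatype = 2L)
  sidecar <- sub("\\.nii$", ".json", path)
  jsonlite::write_json(list(label = mask$label), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  vol <- read_nifti(path)
  sidecar <- sub("\\.nii$", ".json", path)
  label <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar)$label else sub("\\.nii$", "", basename(path))
  lin <- which(vol$data != 0)
  shape <- vol$grid$shape
  lin0 <- lin - 1L
  idx <- cbind(lin0 %% shape[1],
               (lin0 %/% shape[1]) %% shape[2],
               lin0 %/% (shape[1] * shape[2]))
  roi_mask(label, idx, vol$grid)
}
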