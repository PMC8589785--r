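# Minimal NIfTI-1 I/O.
#
# The package reads and writes single-file NIfTI-1 (.nii / .nii.gz) volumes
# with axis-aligned affines. This is deliberately small: the measurement
# pipeline only needs voxel data, voxel spacing, and enough of the sform to
# confirm a right-anterior-superior (RAS) axis order. Oblique or permuted
# affines are rejected rather than silently resampled.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_connection <- function(path, open) {
  gz <- grepl("\\.gz$", path)
  if (gz) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array with spacing metadata. Only axis-aligned RAS-oriented volumes are
#' accepted; anything else raises an error so the caller never works in an
#' ambiguous frame.
#'
#' @param path file path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array, 3D or 4D), `spacing` (mm per
#'   voxel along the first three axes) and `orientation` (`"RAS"`).
#' @export
nifti_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L)
  if (sizeof_hdr != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  endian <- "little"
  rb <- function(what, n, size) readBin(con, what, n, size = size, endian = endian)
  invisible(rb("raw", 36L, 1L))                    # data_type..dim_info
  dim0 <- rb("integer", 8L, 2L)
  ndim <- dim0[1L]
  if (ndim < 3L || ndim > 4L) stop("only 3D/4D NIfTI volumes are supported")
  dims <- dim0[2L:(1L + ndim)]
  invisible(rb("double", 3L, 4L))                  # intent_p1..p3
  invisible(rb("integer", 1L, 2L))                 # intent_code
  datatype <- rb("integer", 1L, 2L)
  invisible(rb("integer", 1L, 2L))                 # bitpix
  invisible(rb("integer", 1L, 2L))                 # slice_start
  pixdim <- rb("double", 8L, 4L)
  vox_offset <- rb("double", 1L, 4L)
  scl_slope <- rb("double", 1L, 4L)
  scl_inter <- rb("double", 1L, 4L)
  invisible(rb("raw", 24L, 1L))                    # slice_end..glmin
  invisible(rb("raw", 96L, 1L))                    # descrip + aux_file
  qform_code <- rb("integer", 1L, 2L)
  sform_code <- rb("integer", 1L, 2L)
  invisible(rb("double", 6L, 4L))                  # quatern
  srow <- matrix(rb("double", 12L, 4L), nrow = 3L, byrow = TRUE)
  invisible(rb("raw", 16L, 1L))                    # intent_name
  magic <- rawToChar(rb("raw", 4L, 1L)[1:3])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- vox_offset - 348
  if (skip > 0) invisible(rb("raw", as.integer(skip), 1L))
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  if (sform_code > 0L) {
    rot <- srow[, 1:3]
    offdiag <- rot; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(rot))) || any(diag(rot) < 0)) {
      stop("ambiguous orientation: only axis-aligned RAS sforms are supported")
    }
    spacing <- abs(diag(rot))
  }
  list(data = array(as.double(vals), dim = dims), spacing = spacing,
       orientation = "RAS")
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D numeric array as a single-file float32 NIfTI-1 image in
#' the canonical RAS frame with an axis-aligned sform.
#'
#' @param data numeric array, 3D or 4D.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param spacing voxel spacing in mm along the first three axes.
#' @return `path`, invisibly.
#' @export
nifti_write <- function(data, path, spacing = c(1, 1, 1)) {
  dims <- dim(data)
  stopifnot(length(dims) %in% c(3L, 4L), length(spacing) == 3L)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb_i <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wb_d <- function(x, size) writeBin(as.double(x), con, size = size, endian = "little")
  wb_i(348L, 4L)
  writeBin(raw(36L), con)
  dim0 <- rep(1L, 8L); dim0[1L] <- length(dims); dim0[2:(1 + length(dims))] <- dims
  wb_i(dim0, 2L)
  wb_d(c(0, 0, 0), 4L)
  wb_i(0L, 2L)
  wb_i(16L, 2L)        # float32
  wb_i(32L, 2L)        # bitpix
  wb_i(0L, 2L)
  pixdim <- rep(1, 8L); pixdim[2:4] <- spacing
  wb_d(pixdim, 4L)
  wb_d(352, 4L)        # vox_offset
  wb_d(c(1, 0), 4L)    # scl_slope, scl_inter
  writeBin(raw(24L), con)
  writeBin(raw(96L), con)
  wb_i(c(0L, 1L), 2L)  # qform_code = 0, sform_code = 1
  wb_d(rep(0, 6L), 4L)
  srow <- rbind(c(spacing[1], 0, 0, 0), c(0, spacing[2], 0, 0),
                c(0, 0, spacing[3], 0))
  wb_d(as.double(t(srow)), 4L)
  writeBin(raw(16L), con)
  writeBin(c(charToRaw("n+1"), raw(1L)), con)
  writeBin(raw(4L), con)   # pad to 352
  wb_d(as.double(data), 4L)
  invisible(path)
}

# FSL-style plain-text gradient sidecars: one row per axis (bvecs), a single
# row of b-values (bvals), whitespace separated.
read_bvals_bvecs <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, what = double(), quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) == length(bvals)) bv <- t(bv)
  if (ncol(bv) != 3L || nrow(bv) != length(bvals)) {
    stop("bvec/bval dimensions disagree")
  }
  list(bvals = bvals, bvecs = unname(bv))
}

write_bvals_bvecs <- function(bvals, bvecs, bval_path, bvec_path) {
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(bvecs), 1L, function(r) paste(format(r, trim = TRUE),
                                                   collapse = " ")), bvec_path)
  invisible(NULL)
}
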