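#' Minimal NIfTI-1 input/output
#'
#' The package reads and writes single-file NIfTI-1 (`.nii` / `.nii.gz`)
#' volumes with a 4x4 sform affine. Only the datatypes the package itself
#' emits or commonly meets are supported (uint8, int16, int32, float32,
#' float64). This is deliberately a small, self-contained codec: volumes
#' produced here round-trip exactly and are readable by standard
#' neuroimaging tools.
#'
#' @name nifti-io
NULL

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),
  `4`   = list(what = "integer", size = 2, signed = TRUE),
  `8`   = list(what = "integer", size = 4, signed = TRUE),
  `16`  = list(what = "double",  size = 4, signed = TRUE),
  `64`  = list(what = "double",  size = 8, signed = TRUE)
)

#' Construct an rCBF volume object
#'
#' @param data 3D numeric array of intensities.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm coordinates.
#' @param scan_key optional named list or character vector identifying the scan
#'   (participant, session, condition, replicate).
#' @return An object of class `rcbf_volume`.
#' @export
rcbf_volume <- function(data, affine, scan_key = NULL) {
  stopifnot(length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine is singular")
  structure(list(data = data, affine = affine, scan_key = scan_key),
            class = "rcbf_volume")
}

#' @export
print.rcbf_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<rcbf_volume> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  if (!is.null(x$scan_key))
    cat("  scan:", paste(unlist(x$scan_key), collapse = "/"), "\n")
  invisible(x)
}

#' Voxel sizes (mm) from an affine
#' @param affine 4x4 voxel-to-mm matrix.
#' @return length-3 numeric of per-axis spacings.
#' @export
voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' Millimetre coordinates of every voxel centre
#'
#' @param dim length-3 integer grid shape.
#' @param affine 4x4 voxel-to-mm matrix (0-based voxel convention).
#' @return n_voxel x 3 matrix of mm coordinates, voxels in R array order.
#' @export
voxel_coords_mm <- function(dim, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim[1]) - 1L,
                               j = seq_len(dim[2]) - 1L,
                               k = seq_len(dim[3]) - 1L))
  t(affine[1:3, 1:3] %*% t(idx) + affine[1:3, 4])
}

.pad_char <- function(s, n) {
  r <- charToRaw(substr(s, 1L, n))
  c(r, raw(n - length(r)))
}

#' Write a volume as NIfTI-1
#'
#' @param vol `rcbf_volume`, or a 3D array (then `affine` is required).
#' @param path output path; `.gz` suffix selects gzip compression.
#' @param affine affine override when `vol` is a bare array.
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, affine = NULL, datatype = "float32") {
  if (is.array(vol) && !inherits(vol, "rcbf_volume")) {
    if (is.null(affine)) stop("affine required when writing a bare array")
    vol <- rcbf_volume(vol, affine)
  }
  data <- vol$data
  aff <- vol$affine
  dt_code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L,
                    stop("unsupported datatype: ", datatype))
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, int16 = 16L)
  d <- dim(data)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(35), con)                              # data_type..regular
  writeBin(as.raw(0L), con)                           # dim_info
  writeBin(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), con, size = 2)  # dim[8]
  writeBin(numeric(3), con, size = 4)                 # intent_p1..p3
  writeBin(0L, con, size = 2)                         # intent_code
  writeBin(dt_code, con, size = 2)                    # datatype
  writeBin(bitpix, con, size = 2)                     # bitpix
  writeBin(0L, con, size = 2)                         # slice_start
  vs <- voxel_sizes(aff)
  writeBin(c(1, vs, 1, 1, 1, 1), con, size = 4)       # pixdim[8], qfac=1
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  writeBin(as.raw(c(0L, 2L)), con)                    # slice_code, xyzt_units (mm)
  writeBin(numeric(4), con, size = 4)                 # cal_max..toffset
  writeBin(integer(2), con, size = 4)                 # glmax, glmin
  writeBin(.pad_char("petfc rCBF volume", 80), con)   # descrip
  writeBin(raw(24), con)                              # aux_file
  writeBin(c(0L, 2L), con, size = 2)                  # qform_code, sform_code
  writeBin(numeric(6), con, size = 4)                 # quatern/qoffset
  writeBin(as.numeric(t(aff[1:3, ])), con, size = 4)  # srow_x/y/z
  writeBin(raw(16), con)                              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)      # magic
  writeBin(raw(4), con)                               # extension flag

  storage <- if (datatype == "int16") as.integer(round(data)) else as.numeric(data)
  writeBin(storage, con, size = bitpix / 8L)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param scan_key optional scan identifier to attach.
#' @return An `rcbf_volume`.
#' @export
read_nifti <- function(path, scan_key = NULL) {
  con <- gzfile(path, "rb")  # gzfile transparently reads plain files too
  on.exit(close(con))

  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size, signed = TRUE, endian) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4, endian = endian) != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian = endian) != 348L)
      stop(path, " is not a NIfTI-1 file (bad sizeof_hdr)")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": unsupported magic '", magic, "'")
  if (magic == "ni1") stop(path, ": two-file NIfTI (.hdr/.img) not supported")

  dims <- rd(40, "integer", 8, 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop(path, ": expected a 3D volume")
  d <- dims[2:4]
  n_extra <- if (ndim > 3L) prod(pmax(dims[5:(ndim + 1)], 1L)) else 1L
  if (n_extra != 1L) stop(path, ": 4D+ files not supported by this reader")

  dt_code <- rd(70, "integer", 1, 2, endian = endian)
  spec <- .nifti_datatypes[[as.character(dt_code)]]
  if (is.null(spec)) stop(path, ": unsupported NIfTI datatype code ", dt_code)
  pixdim <- rd(76, "double", 8, 4, endian = endian)
  vox_offset <- rd(108, "double", 1, 4, endian = endian)
  scl_slope <- rd(112, "double", 1, 4, endian = endian)
  scl_inter <- rd(116, "double", 1, 4, endian = endian)
  sform_code <- rd(254, "integer", 1, 2, endian = endian)

  if (sform_code > 0L) {
    srow <- rd(280, "double", 12, 4, endian = endian)
    aff <- rbind(matrix(srow, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  } else {
    aff <- diag(4)
    diag(aff)[1:3] <- pixdim[2:4]
  }

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  nvox <- prod(d)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != nvox) stop(path, ": truncated data section")
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  rcbf_volume(array(as.numeric(vals), dim = d), aff, scan_key = scan_key)
}
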