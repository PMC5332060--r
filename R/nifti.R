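#' Minimal NIfTI-1 volume I/O
#'
#' Reads a single-frame 3-D NIfTI-1 volume (.nii or .nii.gz) into an R array.
#' Supports the scalar datatypes produced by common tooling (uint8, int16,
#' int32, float32, float64, uint16) and applies the scl_slope/scl_inter
#' scaling. Byte order is auto-detected from the sizeof_hdr field.
#'
#' @param path file path, `.nii` or `.nii.gz`.
#' @return list with `data` (3-D numeric array), `affine` (4x4 voxel-to-world
#'   matrix from the sform row vectors, or a diagonal pixdim affine when no
#'   sform is present), `pixdim` (length-3 voxel size in mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  int16 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L, endian = endian)
  flt32 <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L, endian = endian)
  dim0 <- int16(40L, 8L)
  ndim <- dim0[1L]
  if (ndim < 1L || ndim > 7L) stop("bad dim[0] in NIfTI header: ", ndim)
  dims <- dim0[2L:(1L + ndim)]
  if (any(dims[-(1:3)] > 1L)) stop("only single-frame 3-D volumes supported: ", path)
  shape <- c(dims, 1L, 1L)[1:3]
  datatype <- int16(70L)
  pixdim <- flt32(76L, 8L)[2:4]
  vox_offset <- flt32(108L)
  scl_slope <- flt32(112L)
  scl_inter <- flt32(116L)
  sform_code <- int16(254L)
  srow <- matrix(flt32(280L, 12L), nrow = 3L, byrow = TRUE)
  affine <- if (sform_code > 0L) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(pixdim, 1))
  n <- prod(shape)
  spec <- switch(as.character(datatype),
    "2"   = list(what = "integer", size = 1L, signed = FALSE),
    "4"   = list(what = "integer", size = 2L, signed = TRUE),
    "8"   = list(what = "integer", size = 4L, signed = TRUE),
    "16"  = list(what = "double",  size = 4L, signed = TRUE),
    "64"  = list(what = "double",  size = 8L, signed = TRUE),
    "512" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  x <- readBin(con, spec$what, n = n, size = spec$size, signed = spec$signed,
               endian = endian)
  if (length(x) < n) stop("truncated NIfTI data section: ", path)
  x <- as.double(x)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    x <- x * scl_slope + scl_inter
  list(data = array(x, dim = shape), affine = affine, pixdim = pixdim)
}

#' Write a 3-D array as a NIfTI-1 volume
#'
#' Writes float64 data (or int16 when `datatype = "int16"`, used for label
#' volumes) with an sform affine, little-endian, single-file `n+1` layout.
#'
#' @param data 3-D numeric array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(c(pixdim, 1))`.
#' @param pixdim voxel size in mm (length 3).
#' @param datatype `"float64"` (default) or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL, pixdim = c(1, 1, 1),
                        datatype = c("float64", "int16")) {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3L)
  if (is.null(affine)) affine <- diag(c(pixdim, 1))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  code <- if (datatype == "float64") c(64L, 64L) else c(4L, 16L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                                  # sizeof_hdr
  w_raw(36L)                                   # data_type..dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))      # dim[8]
  w_f32(c(0, 0, 0))                            # intent_p1..p3
  w_i16(0L); w_i16(code[1L]); w_i16(code[2L])  # intent_code, datatype, bitpix
  w_i16(0L)                                    # slice_start
  w_f32(c(0, pixdim, 1, 1, 1, 1))              # pixdim[8] (qfac 0)
  w_f32(352)                                   # vox_offset
  w_f32(c(1, 0))                               # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                         # slice_end, slice_code, xyzt_units
  w_f32(c(max(data), min(data), 0, 0))         # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                             # glmax, glmin
  w_raw(80L + 24L)                             # descrip, aux_file
  w_i16(c(0L, 1L))                             # qform_code 0, sform_code 1
  w_f32(rep(0, 6))                             # quatern_b/c/d, qoffset_x/y/z
  w_f32(t(affine[1:3, ]))                      # srow_x, srow_y, srow_z
  w_raw(16L)                                   # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)   # magic
  w_raw(4L)                                    # extension flag
  if (datatype == "int16") {
    w_i16(as.integer(round(data)))
  } else {
    writeBin(as.double(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}
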