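# Minimal NIfTI-1 I/O.
#
# No NIfTI reader ships with base R, so the 348-byte NIfTI-1 header is
# (de)serialized here directly. Scope: single-file .nii / .nii.gz, 3-D
# volumes, little- or big-endian, datatypes uint8 / int16 / int32 /
# float32 / float64, sform (preferred) or pixdim-derived affines.
# scl_slope / scl_inter are applied on read. Extensions are ignored.

.nifti_dtypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param data numeric or logical 3-D array (a vector with a `dim` attribute
#'   works too).
#' @param path output file; `.nii` or `.nii.gz`.
#' @param affine 4x4 voxel-to-world matrix, written as the sform
#'   (`sform_code = 1`). Defaults to identity spacing.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = "float32") {
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  dims <- dim(data)
  if (is.null(dims)) dims <- length(data)
  if (length(dims) > 3L) stop("only 3-D volumes are supported")
  dims <- c(dims, rep(1L, 3L - length(dims)))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  dt <- .nifti_dtypes[[match.arg(datatype, names(.nifti_dtypes))]]

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wC <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }

  pixdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  wI(348L, 4L)                               # sizeof_hdr
  wC("", 10L); wC("", 18L)                   # data_type, db_name
  wI(0L, 4L); wI(0L, 2L)                     # extents, session_error
  wC("r", 1L); wC("", 1L)                    # regular, dim_info
  wI(c(3L, dims, rep(1L, 4L)), 2L)           # dim[8]
  wF(c(0, 0, 0)); wI(0L, 2L)                 # intent_p1..p3, intent_code
  wI(dt$code, 2L); wI(dt$bitpix, 2L)         # datatype, bitpix
  wI(0L, 2L)                                 # slice_start
  wF(c(1, pixdim, rep(1, 4L)))               # pixdim[8] (qfac = 1)
  wF(352)                                    # vox_offset
  wF(1); wF(0)                               # scl_slope, scl_inter
  wI(0L, 2L); wC("", 1L); wC("", 1L)         # slice_end, slice_code, xyzt_units
  wF(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L), 4L)                          # glmax, glmin
  wC("painsig", 80L); wC("", 24L)            # descrip, aux_file
  wI(0L, 2L); wI(1L, 2L)                     # qform_code, sform_code
  wF(rep(0, 6))                              # quatern b,c,d + qoffset x,y,z
  wF(affine[1, ]); wF(affine[2, ]); wF(affine[3, ])
  wC("", 16L)                                # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                     # extender: no extensions

  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else if (dt$size == 4L) {
    writeBin(as.double(vals), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array, slope/intercept applied), `affine`
#'   (4x4, sform if present else diagonal from pixdim), `dim`, and
#'   `datatype`.
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)

  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop(path, " is not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, ": bad NIfTI magic '", magic, "'")
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")

  rdI <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                        "integer", n = n, size = size, endian = endian)
  rdF <- function(off, n) readBin(hdr[(off + 1):(off + n * 4L)],
                                  "double", n = n, size = 4L, endian = endian)

  dim8 <- rdI(40L, 8L, 2L)
  ndim <- dim8[1]
  if (ndim < 1L || ndim > 7L) stop("bad dim[0] in ", path)
  dims <- dim8[2:(1 + ndim)]
  if (prod(dims[-(1:3)]) > 1) stop("only 3-D volumes are supported (got dim ",
                                   paste(dims, collapse = "x"), ")")
  dims3 <- c(dims, rep(1L, max(0L, 3L - length(dims))))[1:3]

  dtcode <- rdI(70L, 1L, 2L)
  dt_i <- which(vapply(.nifti_dtypes, function(d) d$code == dtcode, logical(1)))
  if (length(dt_i) != 1L) stop("unsupported NIfTI datatype code ", dtcode)
  dt <- .nifti_dtypes[[dt_i]]

  pixdim <- rdF(76L, 8L)
  vox_offset <- rdF(108L, 1L)
  scl_slope <- rdF(112L, 1L)
  scl_inter <- rdF(116L, 1L)
  sform_code <- rdI(254L, 1L, 2L)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- rdF(280L, 4L)
    affine[2, ] <- rdF(296L, 4L)
    affine[3, ] <- rdF(312L, 4L)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }

  skip <- vox_offset - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims3)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  list(data = array(vals, dim = dims3), affine = affine,
       dim = dims3, datatype = names(.nifti_dtypes)[dt_i])
}
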