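# Minimal NIfTI-1 (.nii, single-file, uncompressed) reader/writer.
#
# The pipeline only needs a lossless container for 3-D/4-D float grids with
# voxel size and repetition time, so this implements exactly the NIfTI-1
# fields required for that: dim, datatype, bitpix, pixdim, vox_offset,
# scl_slope/scl_inter, xyzt_units and magic.  Reads accept int16/int32/
# float32/float64 in either byte order; writes emit little-endian float32
# (float64 on request).

.NIFTI_HDR_SIZE <- 348L
.NIFTI_VOX_OFFSET <- 352

.nifti_datatypes <- c("int16" = 4L, "int32" = 8L, "float32" = 16L, "float64" = 64L)
.nifti_bitpix    <- c("int16" = 16L, "int32" = 32L, "float32" = 32L, "float64" = 64L)

#' Write an array to a NIfTI-1 file
#'
#' @param data numeric array, 3-D or 4-D.
#' @param path output file path (conventionally ending in `.nii`).
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param tr_seconds repetition time in seconds (stored in `pixdim[4]`).
#' @param datatype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @seealso [read_nifti()]
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(3, 3, 3), tr_seconds = 2,
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("`data` must be a 3-D or 4-D array", call. = FALSE)
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  nd <- length(dim(data))
  dims <- rep(1L, 8L)
  dims[1L] <- nd
  dims[seq_len(nd) + 1L] <- dim(data)
  pixdim <- rep(0, 8)
  pixdim[1] <- 1                      # qfac
  pixdim[2:4] <- as.numeric(voxel_size_mm)
  pixdim[5] <- as.numeric(tr_seconds)

  con <- file(path, "wb")
  on.exit(close(con))
  wint   <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wshort <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wfloat <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wraw   <- function(n) writeBin(raw(n), con)

  wint(.NIFTI_HDR_SIZE)               # sizeof_hdr
  wraw(34L)                           # data_type[10] db_name[18] extents(4) session_error(2)
  writeBin(as.raw(c(0x72, 0x00)), con)  # regular='r', dim_info=0  (offsets 38,39)
  wshort(dims)                        # dim[8]
  wfloat(c(0, 0, 0))                  # intent_p1..p3
  wshort(0L)                          # intent_code
  wshort(.nifti_datatypes[[datatype]])
  wshort(.nifti_bitpix[[datatype]])
  wshort(0L)                          # slice_start
  wfloat(pixdim)                      # pixdim[8]
  wfloat(.NIFTI_VOX_OFFSET)           # vox_offset
  wfloat(1)                           # scl_slope
  wfloat(0)                           # scl_inter
  wshort(0L)                          # slice_end
  writeBin(as.raw(c(0L, 10L)), con)   # slice_code, xyzt_units = mm(2) | sec(8)
  wfloat(c(0, 0, 0, 0))               # cal_max cal_min slice_duration toffset
  wint(c(0L, 0L))                     # glmax glmin
  desc <- charToRaw("icnscore synthetic/derived volume")
  writeBin(c(desc, raw(80L - length(desc))), con)  # descrip[80]
  wraw(24L)                           # aux_file
  wshort(c(0L, 1L))                   # qform_code=0, sform_code=1
  wfloat(c(0, 0, 0, 0, 0, 0))         # quatern b c d, qoffset x y z
  wfloat(c(pixdim[2], 0, 0, 0))       # srow_x
  wfloat(c(0, pixdim[3], 0, 0))       # srow_y
  wfloat(c(0, 0, pixdim[4], 0))       # srow_z
  wraw(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)   # magic
  wraw(4L)                            # extension flag: none
  sz <- if (datatype == "float32") 4L else 8L
  writeBin(as.numeric(data), con, size = sz, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Accepts uncompressed single-file NIfTI-1 with datatype int16, int32,
#' float32 or float64, in little- or big-endian byte order.  Slope/intercept
#' scaling is applied when `scl_slope != 0`.
#'
#' @param path path to a `.nii` file.
#' @return list with elements `data` (array), `dim`, `voxel_size_mm`,
#'   `tr_seconds`, `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fsz <- file.info(path)$size
  if (is.na(fsz) || fsz < .NIFTI_VOX_OFFSET)
    stop(sprintf("NIfTI format error in %s: file shorter than header (sizeof_hdr)", path),
         call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = .NIFTI_HDR_SIZE)

  rd <- function(what, off, n, size, endian) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  sizeof_hdr <- rd("integer", 0L, 1L, 4L, endian)
  if (sizeof_hdr != .NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- rd("integer", 0L, 1L, 4L, endian)
    if (sizeof_hdr != .NIFTI_HDR_SIZE)
      stop(sprintf("NIfTI format error in %s: bad sizeof_hdr (not 348 in either byte order)",
                   path), call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("NIfTI format error in %s: bad magic '%s'", path, magic), call. = FALSE)

  dims <- rd("integer", 40L, 8L, 2L, endian)
  nd <- dims[1L]
  if (nd < 1L || nd > 7L)
    stop(sprintf("NIfTI format error in %s: bad dim[0] = %d", path, nd), call. = FALSE)
  shape <- pmax(dims[seq_len(nd) + 1L], 1L)
  datatype_code <- rd("integer", 70L, 1L, 2L, endian)
  dt <- names(.nifti_datatypes)[match(datatype_code, .nifti_datatypes)]
  if (is.na(dt))
    stop(sprintf("NIfTI format error in %s: unsupported datatype code %d",
                 path, datatype_code), call. = FALSE)
  pixdim <- rd("numeric", 76L, 8L, 4L, endian)
  vox_offset <- rd("numeric", 108L, 1L, 4L, endian)
  scl_slope <- rd("numeric", 112L, 1L, 4L, endian)
  scl_inter <- rd("numeric", 116L, 1L, 4L, endian)

  n_vox <- prod(shape)
  sz <- .nifti_bitpix[[dt]] / 8L
  if (fsz < vox_offset + n_vox * sz)
    stop(sprintf("NIfTI format error in %s: file truncated (dim implies %d bytes of data)",
                 path, n_vox * sz), call. = FALSE)
  seek(con, where = vox_offset, origin = "start")
  what <- if (dt %in% c("float32", "float64")) "numeric" else "integer"
  vals <- readBin(con, what, n = n_vox, size = sz, endian = endian)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape),
       dim = shape,
       voxel_size_mm = pixdim[2:4],
       tr_seconds = pixdim[5],
       datatype = dt)
}
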