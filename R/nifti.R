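# Minimal NIfTI-1 reader/writer (.nii / .nii.gz).
#
# No NIfTI package is available in this environment, so the package carries
# its own implementation, restricted to what it emits: single-file NIfTI-1,
# little/big endian detection on read, scalar volumes (3D) and voxel-unit
# vector fields stored as 4D (x,y,z,3). 1 mm isotropic identity affine by
# default; the affine is carried through as an attribute.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

#' Write a volume or vector field as NIfTI-1
#'
#' @param x 3D numeric array (scalar volume) or 4D array with last dimension 3
#'   (vector field, voxel units).
#' @param path output path; gzip compression is applied when it ends in `.gz`.
#' @param datatype `"float32"` (default) or `"int32"` (label maps).
#' @param pixdim voxel size per spatial axis in mm.
#' @param affine 4x4 voxel-to-world matrix written to the sform; defaults to
#'   a 1 mm identity.
#' @return the path, invisibly.
#' @export
writeNifti <- function(x, path, datatype = c("float32", "int32"),
                       pixdim = c(1, 1, 1), affine = NULL) {
  datatype <- match.arg(datatype)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("x must be a 3D volume or a 4D (x,y,z,3) vector field")
  if (length(d) == 4L && d[4] != 3L)
    stop("4D arrays must have 3 components in the last dimension")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- pixdim
  }
  dt <- if (datatype == "float32") c(code = 16L, bitpix = 32L)
        else c(code = 8L, bitpix = 32L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(v, size) writeBin(v, con, size = size, endian = "little")
  dim8 <- integer(8)
  dim8[1] <- length(d)
  dim8[seq_along(d) + 1] <- d
  dim8[dim8 == 0L] <- 1L
  w(348L, 4)                                   # sizeof_hdr
  w(raw(35), 1)                                # data_type..regular
  w(as.raw(0L), 1)                             # dim_info
  w(as.integer(dim8), 2)                       # dim
  w(numeric(3), 4)                             # intent_p1..p3
  w(0L, 2)                                     # intent_code
  w(as.integer(dt["code"]), 2)                 # datatype
  w(as.integer(dt["bitpix"]), 2)               # bitpix
  w(0L, 2)                                     # slice_start
  pd <- numeric(8); pd[1] <- 1; pd[2:4] <- pixdim
  if (length(d) == 4L) pd[5] <- 1
  w(pd, 4)                                     # pixdim
  w(352, 4)                                    # vox_offset
  w(c(1, 0), 4)                                # scl_slope, scl_inter
  w(0L, 2); w(raw(1), 1)                       # slice_end, slice_code
  w(as.raw(2L), 1)                             # xyzt_units: mm
  w(numeric(4), 4)                             # cal_max..toffset
  w(c(0L, 0L), 4)                              # glmax, glmin
  desc <- charToRaw("synthbias"); w(c(desc, raw(80 - length(desc))), 1)
  w(raw(24), 1)                                # aux_file
  w(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  w(numeric(6), 4)                             # quatern + qoffset
  w(as.numeric(t(affine[1:3, ])), 4)           # srow_x/y/z
  w(raw(16), 1)                                # intent_name
  w(c(charToRaw("n+1"), raw(1)), 1)            # magic
  w(raw(4), 1)                                 # extension flag
  if (datatype == "int32") w(as.integer(round(as.vector(x))), 4)
  else w(as.numeric(as.vector(x)), 4)
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' Returns the image as a numeric array (3D, or 4D for vector fields) with
#' attributes `pixdim` and `affine`.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @return numeric array.
#' @export
readNifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  parse <- function(endian) {
    rc <- rawConnection(hdr)
    on.exit(close(rc))
    rd <- function(what, n, size) readBin(rc, what, n = n, size = size, endian = endian)
    h <- list()
    h$sizeof_hdr <- rd("integer", 1, 4)
    invisible(rd("raw", 36, 1))
    h$dim <- rd("integer", 8, 2)
    invisible(rd("double", 3, 4)); invisible(rd("integer", 1, 2))
    h$datatype <- rd("integer", 1, 2)
    h$bitpix <- rd("integer", 1, 2)
    invisible(rd("integer", 1, 2))
    h$pixdim <- rd("double", 8, 4)
    h$vox_offset <- rd("double", 1, 4)
    h$scl_slope <- rd("double", 1, 4)
    h$scl_inter <- rd("double", 1, 4)
    invisible(rd("integer", 1, 2)); invisible(rd("raw", 2, 1))
    invisible(rd("double", 4, 4)); invisible(rd("integer", 2, 4))
    invisible(rd("raw", 104, 1))
    invisible(rd("integer", 2, 2))
    invisible(rd("double", 6, 4))
    h$srow <- matrix(rd("double", 12, 4), nrow = 3, byrow = TRUE)
    h
  }
  endian <- "little"
  h <- parse(endian)
  if (h$sizeof_hdr != 348L) {
    endian <- "big"
    h <- parse(endian)
    if (h$sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  nd <- h$dim[1]
  dims <- h$dim[2:(1 + nd)]
  dt <- NIFTI_DTYPES[[as.character(h$datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", h$datatype)
  # skip from end of header to vox_offset
  skip <- h$vox_offset - 348
  if (skip > 0) invisible(readBin(con, "raw", n = skip))
  n <- prod(dims)
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = endian)
  if (length(v) < n) stop("truncated NIfTI data in ", path)
  v <- as.numeric(v)
  if (!is.na(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    v <- v * h$scl_slope + h$scl_inter
  out <- array(v, dim = dims)
  attr(out, "pixdim") <- h$pixdim[2:4]
  affine <- rbind(h$srow, c(0, 0, 0, 1))
  attr(out, "affine") <- affine
  out
}
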