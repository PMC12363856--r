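# Minimal NIfTI-1 reader/writer (no external NIfTI package is assumed).
# Scalar images are written as float64, label images as int32, displacement
# fields as 5-D float64 vector images (dim = [5, nx, ny, nz, 1, d]) with
# intent code 1007 (vector). Geometry is carried in the sform (srow_x/y/z =
# direction %*% diag(spacing) with the origin in the fourth column), which
# round-trips spacing/origin/direction bit-faithfully.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8, signed = TRUE))   # float64

open_nii <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nii_pad <- function(s, n) {
  r <- charToRaw(s)
  c(r[seq_len(min(length(r), n))], raw(max(0, n - length(r))))
}

write_nifti_header <- function(con, dim8, datatype, bitpix, pixdim8,
                               srow, intent_code = 0L) {
  writeBin(348L, con, size = 4)
  writeBin(raw(36), con)                        # unused analyze fields
  writeBin(as.integer(dim8), con, size = 2)     # dim[8]
  writeBin(raw(8), con)                         # intent_p1..p3 (floats x2)
  writeBin(numeric(1), con, size = 4)           # intent_p3
  writeBin(as.integer(intent_code), con, size = 2)
  writeBin(as.integer(datatype), con, size = 2)
  writeBin(as.integer(bitpix), con, size = 2)
  writeBin(0L, con, size = 2)                   # slice_start
  writeBin(as.numeric(pixdim8), con, size = 4)  # pixdim[8]
  writeBin(352, con, size = 4)                  # vox_offset (float)
  writeBin(c(1, 0), con, size = 4)              # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                   # slice_end
  writeBin(raw(2), con)                         # slice_code, xyzt_units
  writeBin(numeric(3), con, size = 4)           # cal_max/min, slice_dur
  writeBin(numeric(1), con, size = 4)           # toffset
  writeBin(integer(2), con, size = 4)           # glmax, glmin
  writeBin(nii_pad("", 80), con)                # descrip
  writeBin(nii_pad("", 24), con)                # aux_file
  writeBin(0L, con, size = 2)                   # qform_code
  writeBin(1L, con, size = 2)                   # sform_code = 1
  writeBin(numeric(6), con, size = 4)           # quatern b,c,d + qoffsets
  writeBin(as.numeric(t(srow)), con, size = 4)  # srow_x, srow_y, srow_z
  writeBin(nii_pad("", 16), con)                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
}

image_srow <- function(grid) {
  d <- grid_dim(grid)
  A3 <- diag(3); org <- c(grid$origin, 0, 0)[1:3]
  A3[1:d, 1:d] <- grid$direction %*% diag(grid$spacing, d)
  cbind(A3, org)
}

#' Write an image or displacement field as NIfTI-1
#'
#' @param image `scalar_image`, `label_image`, or `displacement_field`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  is_field <- inherits(image, "displacement_field")
  grid <- image$grid
  d <- grid_dim(grid)
  shape3 <- c(grid$shape, 1, 1)[1:3]
  pixdim8 <- c(1, grid$spacing, 1, 1, 1, 1, 1)[1:8]
  con <- open_nii(path, "wb")
  on.exit(close(con))
  if (is_field) {
    dim8 <- c(5, shape3, 1, d, 1, 1)
    write_nifti_header(con, dim8, 64L, 64L, pixdim8, image_srow(grid),
                       intent_code = 1007L)
    writeBin(as.numeric(image$vectors), con, size = 8)
  } else if (is_label_image(image)) {
    dim8 <- c(3, shape3, 1, 1, 1, 1)
    write_nifti_header(con, dim8, 8L, 32L, pixdim8, image_srow(grid))
    writeBin(as.integer(image$values), con, size = 4)
  } else {
    dim8 <- c(3, shape3, 1, 1, 1, 1)
    write_nifti_header(con, dim8, 64L, 64L, pixdim8, image_srow(grid))
    writeBin(as.numeric(image$values), con, size = 8)
  }
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' Understands the subset this package writes plus common scanner types
#' (uint8/int16/int32/float32/float64, optional scl scaling, gzip). 5-D
#' vector images (intent 1007, or any file with a 5th dimension) are
#' returned as `displacement_field`s.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as `"auto"` (integer data with integer dtype -> `label_image`),
#'   `"scalar"`, `"label"`, or `"field"`.
#' @return `scalar_image`, `label_image`, or `displacement_field`.
#' @export
read_image <- function(path, as = c("auto", "scalar", "label", "field")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  con <- open_nii(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 348) stop("read_image: truncated NIfTI header: ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            signed = TRUE, endian = "little")
  }
  sizeof <- rd(0, "integer", 1, 4)
  if (sizeof != 348) stop("read_image: not a NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("read_image: unsupported NIfTI magic '", magic, "'")
  dim8 <- rd(40, "integer", 8, 2)
  datatype <- rd(70, "integer", 1, 2)
  bitpix <- rd(72, "integer", 1, 2)
  pixdim8 <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  sform_code <- rd(254, "integer", 1, 2)
  srow <- matrix(rd(280, "double", 12, 4), 3, 4, byrow = TRUE)
  intent_code <- rd(68, "integer", 1, 2)

  nd <- dim8[1]
  shape <- dim8[2:(1 + min(nd, 3))]
  ncomp <- if (nd >= 5 && dim8[6] > 1) dim8[6] else 1L
  d <- length(shape)
  if (d == 1) stop("read_image: 1-D images unsupported")

  ti <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(ti))
    stop("read_image: unsupported datatype ", datatype, " in ", path)
  nvals <- prod(shape) * ncomp
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, ti$what, n = nvals, size = ti$size,
                  signed = ti$signed, endian = "little")
  if (length(vals) < nvals) stop("read_image: truncated data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  if (sform_code > 0) {
    A <- srow[1:d, 1:d, drop = FALSE]
    spacing <- sqrt(colSums(A^2))
    direction <- sweep(A, 2, spacing, "/")
    origin <- srow[1:d, 4]
  } else {
    spacing <- pixdim8[2:(1 + d)]
    direction <- diag(d)
    origin <- rep(0, d)
  }
  grid <- image_grid(shape, spacing, origin, direction)

  if (ncomp > 1 || as == "field" || intent_code == 1007L) {
    if (ncomp != d)
      stop("read_image: vector image has ", ncomp, " components for ",
           d, "-D grid")
    return(displacement_field(grid, array(vals, c(shape, ncomp))))
  }
  integral <- ti$what == "integer" ||
    (length(vals) && max(abs(vals - round(vals))) == 0)
  if (as == "label" || (as == "auto" && ti$what == "integer")) {
    if (!integral)
      stop("read_image: non-integer data cannot be read as labels")
    return(label_image(grid, array(as.integer(round(vals)), shape)))
  }
  scalar_image(grid, array(vals, shape))
}
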