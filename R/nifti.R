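# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#
# No NIfTI-capable package ships with this toolchain, so the 348-byte
# header is read and written directly per the NIfTI-1 layout
# (https://nifti.nimh.nih.gov/nifti-1).  Supported on read: datatypes
# uint8(2), int16(4), int32(8), float32(16), float64(64), uint16(512);
# both endiannesses; sform, qform or pixdim geometry; scl_slope/scl_inter
# rescaling.  Written files use float64 (volumes) or int32 (labels), sform
# code 1, little-endian.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

read_nifti_raw <- function(path) {
  con <- gzfile(path, "rb")  # transparently handles plain .nii too
  on.exit(close(con))
  hdr_bytes <- readBin(con, "raw", 348L)
  if (length(hdr_bytes) < 348L)
    stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sz <- readBin(hdr_bytes[1:4], "integer", 1L, 4L, endian = "little")
  if (sz != 348L) {
    if (readBin(hdr_bytes[1:4], "integer", 1L, 4L, endian = "big") == 348L)
      endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  rd <- function(off, what, n, size)
    readBin(hdr_bytes[(off + 1L):(off + n * size)], what, n, size,
            endian = endian)
  magic <- rawToChar(hdr_bytes[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("bad NIfTI magic string in ", path)
  h <- list(
    endian = endian,
    dim = rd(40L, "integer", 8L, 2L),
    datatype = rd(70L, "integer", 1L, 2L),
    bitpix = rd(72L, "integer", 1L, 2L),
    pixdim = rd(76L, "double", 8L, 4L),
    vox_offset = rd(108L, "double", 1L, 4L),
    scl_slope = rd(112L, "double", 1L, 4L),
    scl_inter = rd(116L, "double", 1L, 4L),
    qform_code = rd(252L, "integer", 1L, 2L),
    sform_code = rd(254L, "integer", 1L, 2L),
    quatern = rd(256L, "double", 3L, 4L),
    qoffset = rd(268L, "double", 3L, 4L),
    srow = rbind(rd(280L, "double", 4L, 4L),
                 rd(296L, "double", 4L, 4L),
                 rd(312L, "double", 4L, 4L))
  )
  nd <- h$dim[1]
  if (nd < 3L) stop("NIfTI image has ", nd, " dimensions; need a 3D volume")
  extra <- if (nd > 3L) h$dim[5:(nd + 1L)] else integer(0)
  if (any(extra > 1L))
    stop("NIfTI image is ", nd, "-dimensional (dim = ",
         paste(h$dim[2:(nd + 1L)], collapse = "x"),
         "); only 3D scalar volumes are supported")
  shape <- h$dim[2:4]
  dt <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", h$datatype)
  # gz connections seek unreliably: skip from byte 348 to the data offset
  skip <- as.integer(round(h$vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n_vox, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n_vox)
    stop("NIfTI data truncated: expected ", n_vox, " voxels, got ",
         length(vals))
  vals <- as.double(vals)
  if (is.finite(h$scl_slope) && h$scl_slope != 0 &&
      !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  list(data = array(vals, shape), header = h, affine = nifti_affine(h))
}

nifti_affine <- function(h) {
  if (h$sform_code > 0L) {
    rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0L) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- rbind(
      c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
      c(2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b)),
      c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2))
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    S <- R %*% diag(c(h$pixdim[2:3], qfac * h$pixdim[4]))
    rbind(cbind(S, h$qoffset), c(0, 0, 0, 1))
  } else {
    A <- diag(c(h$pixdim[2:4], 1))
    A
  }
}

# Reorient data + affine so voxel axis k increases along world axis k with
# positive direction (closest axis permutation, RAS-like).  Plane names
# xy/xz/yz are only reproducible across files after this step.
canonicalize_orientation <- function(data, affine) {
  M <- affine[1:3, 1:3]
  perm <- integer(3)   # perm[i] = voxel axis serving world axis i
  flip <- logical(3)
  Mw <- abs(M)
  for (step in 1:3) {
    ij <- arrayInd(which.max(Mw), dim(Mw))
    i <- ij[1]; j <- ij[2]
    perm[i] <- j
    flip[i] <- M[i, j] < 0
    Mw[i, ] <- -1; Mw[, j] <- -1
  }
  if (any(duplicated(perm))) stop("degenerate affine: no axis permutation")
  if (all(perm == 1:3) && !any(flip))
    return(list(data = data, affine = affine))
  d <- aperm(data, perm)
  n <- dim(d)
  idx <- lapply(1:3, function(i) if (flip[i]) n[i]:1 else seq_len(n[i]))
  d <- d[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  # old voxel index = P %*% new + t
  P <- matrix(0, 4, 4); P[4, 4] <- 1
  for (i in 1:3) {
    P[perm[i], i] <- if (flip[i]) -1 else 1
    if (flip[i]) P[perm[i], 4] <- n[i] - 1
  }
  list(data = d, affine = affine %*% P)
}

#' Read a 3D scalar volume from a NIfTI-1 file
#'
#' Loads a `.nii` or `.nii.gz` single-file NIfTI-1 image, applies any
#' `scl_slope`/`scl_inter` rescaling, and reorients the array to a fixed
#' canonical axis convention (voxel axes aligned with, and increasing
#' along, the world x/y/z axes) so that the texture planes xy/xz/yz mean
#' the same thing for every input.
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @param on_nonfinite `"error"` (default) rejects NaN/Inf voxels;
#'   `"zero"` replaces them with 0 and emits a warning with the count.
#' @return A [volume()].
#' @export
read_volume <- function(path, on_nonfinite = c("error", "zero")) {
  on_nonfinite <- match.arg(on_nonfinite)
  raw <- read_nifti_raw(path)
  d <- raw$data
  if (!all(is.finite(d))) {
    n_bad <- sum(!is.finite(d))
    if (on_nonfinite == "error")
      stop("volume ", path, " contains ", n_bad, " non-finite voxels")
    warning("replaced ", n_bad, " non-finite voxels with 0 in ", path)
    d[!is.finite(d)] <- 0
  }
  can <- canonicalize_orientation(d, raw$affine)
  spacing <- sqrt(colSums(can$affine[1:3, 1:3]^2))
  volume(can$data, spacing, can$affine)
}

#' Read a mask or atlas parcellation from a NIfTI-1 file
#'
#' As [read_volume()], but values must be non-negative integers (within
#' 1e-6 for float-encoded labels).  Labels are preserved, never renumbered.
#'
#' @inheritParams read_volume
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  raw <- read_nifti_raw(path)
  can <- canonicalize_orientation(raw$data, raw$affine)
  spacing <- sqrt(colSums(can$affine[1:3, 1:3]^2))
  label_volume(can$data, spacing, can$affine)
}

#' Write a volume or label volume to a NIfTI-1 file
#'
#' Volumes are stored as float64 (lossless round-trip), label volumes as
#' int32.  The affine is written as the sform (code 1); `.gz` suffixed
#' paths are gzip-compressed.
#'
#' @param v a [volume()] or [label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  is_lab <- inherits(v, "label_volume")
  a <- if (is_lab) v$labels else v$data
  datatype <- if (is_lab) 8L else 64L
  bitpix <- if (is_lab) 32L else 64L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), con)
  wb(348L, 4L)                          # sizeof_hdr
  pad(10L + 18L + 4L + 2L + 1L)         # data_type, db_name, extents, ...
  pad(1L)                               # dim_info
  wb(as.integer(c(3L, dim(a), 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  wb(numeric(3), 4L)                    # intent_p1..p3
  wb(0L, 2L)                            # intent_code
  wb(datatype, 2L); wb(bitpix, 2L); wb(0L, 2L)       # datatype,bitpix,slice_start
  wb(c(1, v$spacing, 1, 1, 1, 1), 4L)   # pixdim (qfac = 1)
  wb(352, 4L)                           # vox_offset
  wb(c(1, 0), 4L)                       # scl_slope, scl_inter
  wb(0L, 2L); pad(2L)                   # slice_end, slice_code+xyzt_units
  wb(numeric(4), 4L)                    # cal_max..toffset
  wb(c(0L, 0L), 4L)                     # glmax, glmin
  pad(80L + 24L)                        # descrip, aux_file
  wb(c(0L, 1L), 2L)                     # qform_code, sform_code
  wb(numeric(6), 4L)                    # quatern, qoffset
  wb(as.numeric(t(v$affine[1:3, ])), 4L)  # srow_x/y/z
  pad(16L)                              # intent_name
  writeBin(charToRaw("n+1"), con); pad(1L)  # magic
  pad(4L)                               # extension flag
  if (is_lab) wb(as.integer(a), 4L) else wb(as.numeric(a), 8L)
  invisible(path)
}
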