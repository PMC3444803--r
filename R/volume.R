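#' 3D scalar volume
#'
#' Container for a 3D scalar image: a numeric array plus voxel spacing (mm)
#' and a 4x4 voxel-to-world affine.  Voxel indices are 0-based in world
#' computations (`world = affine %*% c(i, j, k, 1)`), 1-based when the array
#' is subset in R.
#'
#' @param data 3D numeric array with at least 3 voxels along every axis and
#'   only finite values.
#' @param spacing numeric length-3, strictly positive voxel edge lengths (mm).
#' @param affine 4x4 voxel-to-world transform.  Default: `diag(spacing)` with
#'   zero origin.
#' @return An object of class `volume` with elements `data`, `spacing`,
#'   `affine`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  if (any(dim(data) < 3L))
    stop("volume must have >= 3 voxels along every axis")
  if (!all(is.finite(data)))
    stop("volume contains ", sum(!is.finite(data)), " non-finite voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "volume")
}

#' 3D integer label volume (mask or atlas parcellation)
#'
#' Label 0 is reserved for background; positive labels name regions and are
#' never renumbered.  Geometry fields mirror [volume()].
#'
#' @param labels 3D array of non-negative integers (integer-valued doubles
#'   are cast).
#' @inheritParams volume
#' @return An object of class `label_volume` with elements `labels`,
#'   `spacing`, `affine`, `region_labels` (sorted distinct positive labels).
#' @export
label_volume <- function(labels, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array")
  if (any(!is.finite(labels)))
    stop("label volume contains non-finite values")
  r <- round(labels)
  if (max(abs(labels - r)) > 1e-6)
    stop("label volume has non-integer values (tolerance 1e-6)")
  if (any(r < 0))
    stop("label volume has negative labels")
  storage.mode(r) <- "integer"
  v <- volume(r + 0, spacing, affine)  # reuse geometry checks
  structure(list(labels = r, spacing = v$spacing, affine = v$affine,
                 region_labels = sort(unique(r[r > 0L]))),
            class = "label_volume")
}

#' @export
print.volume <- function(x, ...) {
  cat("<volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, ", length(x$region_labels), " region(s), spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

# shape/spacing/affine agreement required before any joint volume/atlas op
check_aligned <- function(v, lv) {
  a <- if (inherits(v, "label_volume")) v$labels else v$data
  b <- if (inherits(lv, "label_volume")) lv$labels else lv$data
  if (!all(dim(a) == dim(b)))
    stop("volume and label volume shapes differ: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  if (max(abs(v$spacing - lv$spacing)) > 1e-6)
    stop("volume and label volume spacings differ")
  if (max(abs(v$affine - lv$affine)) > 1e-4)
    stop("volume and label volume affines differ")
  invisible(TRUE)
}

#' Resample a volume to a new isotropic or anisotropic voxel spacing
#'
#' The output grid covers the same world extent as the input, dropping any
#' trailing partial voxel (`n_new = floor(n * s_old / s_new)`); no intensity
#' is fabricated by padding.  `linear` interpolates trilinearly, `nearest`
#' takes the closest source voxel and is mandatory for label volumes.
#'
#' @param v a [volume()] or [label_volume()].
#' @param target_spacing_mm numeric length-3 (or scalar, recycled), > 0.
#' @param mode `"linear"` or `"nearest"`.
#' @return An object of the same class as `v` on the new grid, with the
#'   affine updated consistently.
#' @export
resample_volume <- function(v, target_spacing_mm,
                            mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  is_lab <- inherits(v, "label_volume")
  if (is_lab && mode != "nearest")
    stop("label volumes must be resampled with mode = \"nearest\"")
  s_new <- as.numeric(target_spacing_mm)
  if (length(s_new) == 1L) s_new <- rep(s_new, 3L)
  if (length(s_new) != 3L || any(!is.finite(s_new)) || any(s_new <= 0))
    stop("target spacing must be 3 strictly positive numbers")
  a <- if (is_lab) v$labels else v$data
  n_old <- dim(a)
  s_old <- v$spacing
  r <- s_new / s_old
  n_new <- pmax(1L, as.integer(floor(n_old / r + 1e-9)))

  # source voxel coordinate (0-based) of each output voxel centre, per axis;
  # voxel centres at (i + 1/2) * s from the grid edge on both grids
  coord <- lapply(1:3, function(ax) {
    (seq_len(n_new[ax]) - 0.5) * r[ax] - 0.5
  })

  if (mode == "nearest") {
    idx <- lapply(1:3, function(ax)
      pmin(pmax(as.integer(round(coord[[ax]])) + 1L, 1L), n_old[ax]))
    out <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- lapply(1:3, function(ax) {
      x0 <- floor(coord[[ax]])
      f <- coord[[ax]] - x0
      i0 <- pmin(pmax(as.integer(x0) + 1L, 1L), n_old[ax])
      i1 <- pmin(i0 + 1L, n_old[ax])
      # clamp: when x0 is clamped the fraction is forced to an edge value
      f[coord[[ax]] < 0] <- 0
      f[coord[[ax]] > n_old[ax] - 1] <- 1
      f[i1 == i0] <- 0
      list(i0 = i0, i1 = i1, f = f)
    })
    out <- array(0, n_new)
    for (c1 in 0:1) for (c2 in 0:1) for (c3 in 0:1) {
      w <- outer(outer(if (c1) lo[[1]]$f else 1 - lo[[1]]$f,
                       if (c2) lo[[2]]$f else 1 - lo[[2]]$f),
                 if (c3) lo[[3]]$f else 1 - lo[[3]]$f)
      if (all(w == 0)) next
      out <- out + as.vector(w) *
        a[if (c1) lo[[1]]$i1 else lo[[1]]$i0,
          if (c2) lo[[2]]$i1 else lo[[2]]$i0,
          if (c3) lo[[3]]$i1 else lo[[3]]$i0, drop = FALSE]
    }
  }

  # new-voxel -> old-voxel map: u = diag(r) %*% x + (r/2 - 1/2)
  tmat <- diag(c(r, 1))
  tmat[1:3, 4] <- r / 2 - 0.5
  affine_new <- v$affine %*% tmat
  if (is_lab) label_volume(out, s_new, affine_new)
  else volume(out, s_new, affine_new)
}
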