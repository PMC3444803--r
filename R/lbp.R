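# LBP-TOP core: per-voxel local binary pattern codes on the three
# orthogonal planes, uniform-pattern mapping, and parcellated histograms.
#
# Code convention (fixed so histogram bins are reproducible): neighbor p of
# P sits at angle 2*pi*p/P from the +first-axis direction of the plane,
# counter-clockwise; its comparison bit carries weight 2^p; sign(0) = 1,
# i.e. a neighbor equal to the center sets its bit.  A constant image
# therefore codes to 2^P - 1 everywhere.

PLANES <- c("xy", "xz", "yz")
plane_axes <- function(plane) switch(plane, xy = c(1L, 2L),
                                     xz = c(1L, 3L), yz = c(2L, 3L),
                                     stop("unknown plane: ", plane))

#' Neighborhood specification for one LBP plane
#'
#' @param P neighbor count (>= 4; `square` sampling requires P = 8).
#' @param R_mm sampling radius in millimetres (> 0); converted to voxels
#'   by dividing by the in-plane spacing.
#' @param sampling `"circular_interpolated"` (neighbors at angles
#'   `2*pi*p/P`, bilinear interpolation off-grid — the standard LBP_{P,R})
#'   or `"square"` (the 8 surrounding grid offsets scaled by R).
#' @param plane one of `"xy"`, `"xz"`, `"yz"`.
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(P = 8L, R_mm = 1,
                              sampling = c("circular_interpolated", "square"),
                              plane = c("xy", "xz", "yz")) {
  sampling <- match.arg(sampling)
  plane <- match.arg(plane)
  P <- as.integer(P)
  if (P < 4L) stop("P must be >= 4")
  if (sampling == "square" && P != 8L)
    stop("square sampling is only defined for P = 8")
  if (!is.finite(R_mm) || R_mm <= 0) stop("R_mm must be > 0")
  structure(list(P = P, R_mm = R_mm, sampling = sampling, plane = plane),
            class = "neighborhood_spec")
}

# in-plane offsets (in voxels) of the P neighbors, in bit order p = 0..P-1
neighbor_offsets <- function(P, R_vox, sampling) {
  if (sampling == "square") {
    u <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
    off <- u * R_vox
  } else {
    ang <- 2 * pi * (0:(P - 1)) / P
    off <- cbind(cos(ang), sin(ang)) * R_vox
  }
  # snap float fuzz (cos(pi/2)*R etc.) so on-grid samples are exact
  off[abs(off - round(off)) < 1e-9] <- round(off[abs(off - round(off)) < 1e-9])
  off
}

#' Per-voxel LBP codes on a single orthogonal plane
#'
#' For every voxel c with a full in-bounds neighborhood, computes
#' `code = sum_p [v_p >= v_c] * 2^p` over the P neighbors at radius R in
#' the given plane.  Off-grid neighbor values are bilinearly interpolated
#' (circular sampling); ties count as 1 (`sign(0) = 1`).
#'
#' @param v a [volume()].
#' @param spec a [neighborhood_spec()]; requires isotropic in-plane spacing
#'   and an in-plane radius of at least 1 voxel.
#' @return list with `codes` (3D integer array, 0 outside the valid set)
#'   and `valid` (3D logical array: full neighborhood inside the volume).
#' @export
lbp_codes_plane <- function(v, spec) {
  stopifnot(inherits(v, "volume"), inherits(spec, "neighborhood_spec"))
  ax <- plane_axes(spec$plane)
  sp <- v$spacing[ax]
  if (abs(sp[1] - sp[2]) > 1e-9 * max(sp))
    stop("anisotropic in-plane spacing for plane ", spec$plane, ": ",
         sp[1], " vs ", sp[2], " mm")
  R_vox <- spec$R_mm / sp[1]
  if (R_vox < 1 - 1e-9)
    stop("radius ", spec$R_mm, " mm is below 1 voxel at spacing ",
         sp[1], " mm")
  a <- v$data
  n <- dim(a)
  n1 <- n[ax[1]]; n2 <- n[ax[2]]
  off <- neighbor_offsets(spec$P, R_vox, spec$sampling)

  codes <- array(0, n)
  valid <- array(TRUE, n)
  i1 <- seq_len(n1); i2 <- seq_len(n2)

  # subset the 3D array with per-axis index vectors for this plane
  take <- function(j1, j2) {
    switch(spec$plane,
           xy = a[j1, j2, , drop = FALSE],
           xz = a[j1, , j2, drop = FALSE],
           yz = a[, j1, j2, drop = FALSE])
  }
  mark <- function(arr, ok1, ok2) {
    # combine per-axis validity (logical vectors along the plane axes)
    okA <- switch(spec$plane,
                  xy = array(outer(outer(ok1, ok2), rep(TRUE, n[3])), n),
                  xz = array(outer(outer(ok1, rep(TRUE, n[2])), ok2), n),
                  yz = array(outer(outer(rep(TRUE, n[1]), ok1), ok2), n))
    arr & okA
  }

  for (p in seq_len(spec$P)) {
    d1 <- off[p, 1]; d2 <- off[p, 2]
    s1 <- i1 - 1 + d1; s2 <- i2 - 1 + d2   # 0-based sample coords
    ok1 <- s1 >= 0 & s1 <= n1 - 1
    ok2 <- s2 >= 0 & s2 <= n2 - 1
    x0 <- pmin(pmax(floor(s1), 0), n1 - 1); f1 <- s1 - x0
    y0 <- pmin(pmax(floor(s2), 0), n2 - 1); f2 <- s2 - y0
    x1 <- pmin(x0 + 1, n1 - 1); y1 <- pmin(y0 + 1, n2 - 1)
    f1[x1 == x0] <- 0; f2[y1 == y0] <- 0
    if (all(f1 == 0) && all(f2 == 0)) {
      nb <- take(x0 + 1, y0 + 1)
    } else {
      # lerp (difference) form: exact when the corner values are equal,
      # so ties against the center survive interpolation
      F1 <- outer_plane(f1, rep(1, n2), spec$plane, n)
      F2 <- outer_plane(rep(1, n1), f2, spec$plane, n)
      v00 <- take(x0 + 1, y0 + 1); v10 <- take(x1 + 1, y0 + 1)
      v01 <- take(x0 + 1, y1 + 1); v11 <- take(x1 + 1, y1 + 1)
      t0 <- v00 + F1 * (v10 - v00)
      t1 <- v01 + F1 * (v11 - v01)
      nb <- t0 + F2 * (t1 - t0)
    }
    codes <- codes + 2^(p - 1) * (nb >= a)
    valid <- mark(valid, ok1, ok2)
  }
  codes[!valid] <- 0
  storage.mode(codes) <- "integer"
  list(codes = codes, valid = valid)
}

# weight array w1 (x) w2 broadcast over the off-plane axis
outer_plane <- function(w1, w2, plane, n) {
  switch(plane,
         xy = array(outer(outer(w1, w2), rep(1, n[3])), n),
         xz = array(outer(outer(w1, rep(1, n[2])), w2), n),
         yz = array(outer(outer(rep(1, n[1]), w1), w2), n))
}

#' LBP-TOP: codes on the three orthogonal planes
#'
#' Applies [lbp_codes_plane()] on the xy, xz and yz planes through every
#' voxel with the same radius, and intersects the three validity masks:
#' a voxel is valid only if its neighborhood fits inside the volume on all
#' three planes.
#'
#' @param v a [volume()]; spacing must be isotropic.
#' @param P neighbor count (default 8).
#' @param R_mm radius in mm, shared by all three planes.
#' @param sampling see [neighborhood_spec()].
#' @return An object of class `lbp_code_planes`: list with `codes_xy`,
#'   `codes_xz`, `codes_yz` (integer arrays), `valid` (logical array),
#'   `P`, `R_mm`.
#' @export
lbp_top <- function(v, P = 8L, R_mm = 1,
                    sampling = c("circular_interpolated", "square")) {
  sampling <- match.arg(sampling)
  if (max(v$spacing) - min(v$spacing) > 1e-9 * max(v$spacing))
    stop("lbp_top requires isotropic spacing; got ",
         paste(signif(v$spacing, 6), collapse = " x "), " mm")
  per <- lapply(PLANES, function(pl)
    lbp_codes_plane(v, neighborhood_spec(P, R_mm, sampling, pl)))
  valid <- per[[1]]$valid & per[[2]]$valid & per[[3]]$valid
  out <- list(codes_xy = per[[1]]$codes, codes_xz = per[[2]]$codes,
              codes_yz = per[[3]]$codes, valid = valid,
              P = as.integer(P), R_mm = R_mm)
  class(out) <- "lbp_code_planes"
  out
}

#' Circular uniformity measure of an LBP code
#'
#' Counts bitwise 0/1 transitions around the circular neighbor sequence,
#' including the wrap-around pair (bit P-1, bit 0).
#'
#' @param code integer vector of raw LBP codes in `[0, 2^P - 1]`.
#' @param P neighbor count.
#' @return integer vector of transition counts (always even).
#' @export
uniformity <- function(code, P = 8L) {
  P <- as.integer(P)
  code <- as.integer(code)
  if (any(code < 0L | code >= 2L^P))
    stop("code out of range [0, 2^P - 1]")
  u <- integer(length(code))
  for (b in 0:(P - 1L)) {
    bit <- bitwAnd(bitwShiftR(code, b), 1L)
    nxt <- bitwAnd(bitwShiftR(code, (b + 1L) %% P), 1L)
    u <- u + as.integer(bit != nxt)
  }
  u
}

#' Uniform-pattern mapping table
#'
#' Codes with uniformity U <= 2 each receive their own histogram bin,
#' assigned in ascending code order starting at 0; every non-uniform code
#' shares the single final bin.  For P = 8 this yields 58 + 1 = 59 bins.
#'
#' @param P neighbor count, 4..16.
#' @return An object of class `uniform_map`: list with `P`, `table`
#'   (integer vector of length `2^P`, bin of each raw code) and `n_bins`
#'   (`P*(P-1) + 3`).
#' @export
build_uniform_map <- function(P = 8L) {
  P <- as.integer(P)
  if (P < 4L || P > 16L) stop("P must be in 4..16")
  u <- uniformity(0:(2L^P - 1L), P)
  n_bins <- P * (P - 1L) + 3L
  tab <- integer(2L^P)
  tab[u > 2L] <- n_bins - 1L
  tab[u <= 2L] <- seq_len(sum(u <= 2L)) - 1L
  structure(list(P = P, table = tab, n_bins = n_bins), class = "uniform_map")
}

#' Parcellated LBP-TOP histogram feature vector
#'
#' For each atlas region (ascending label order) and each plane (xy, xz,
#' yz), histograms the uniform-mapped codes of the region's valid voxels
#' (region membership by the center voxel's label).  Blocks are
#' concatenated regions-major, then planes, then bins.  A region with no
#' valid voxels yields an all-zero block and a warning.
#'
#' @param codes an `lbp_code_planes` object from [lbp_top()].
#' @param atlas a [label_volume()] with the same shape.
#' @param umap a [build_uniform_map()] with matching `P`.
#' @param normalize if TRUE (default) each (region, plane) block is L1
#'   normalized to sum 1; if FALSE blocks hold raw counts and sum to the
#'   region's valid-voxel count.
#' @return list with `values` (numeric vector of length
#'   `n_regions * 3 * n_bins`) and `meta` (data.frame `region`, `plane`,
#'   `bin`).
#' @export
region_histograms <- function(codes, atlas, umap, normalize = TRUE) {
  stopifnot(inherits(codes, "lbp_code_planes"),
            inherits(atlas, "label_volume"),
            inherits(umap, "uniform_map"))
  if (!all(dim(atlas$labels) == dim(codes$valid)))
    stop("atlas shape does not match code arrays")
  if (umap$P != codes$P)
    stop("uniform map P = ", umap$P, " does not match codes P = ", codes$P)
  regions <- atlas$region_labels
  if (length(regions) == 0L) stop("atlas has no positive labels")
  nb <- umap$n_bins
  planes <- list(xy = codes$codes_xy, xz = codes$codes_xz,
                 yz = codes$codes_yz)
  values <- numeric(length(regions) * 3L * nb)
  meta <- data.frame(
    region = rep(regions, each = 3L * nb),
    plane = rep(rep(PLANES, each = nb), times = length(regions)),
    bin = rep.int(0:(nb - 1L), 3L * length(regions)),
    stringsAsFactors = FALSE)
  pos <- 0L
  for (r in regions) {
    in_r <- codes$valid & (atlas$labels == r)
    if (!any(in_r))
      warning("region ", r, " has no valid voxels; zero feature block")
    for (pl in PLANES) {
      h <- numeric(nb)
      if (any(in_r)) {
        mapped <- umap$table[planes[[pl]][in_r] + 1L]
        h <- tabulate(mapped + 1L, nbins = nb)
        if (normalize) {
          s <- sum(h)
          if (s > 0) h <- h / s
        }
      }
      values[pos + seq_len(nb)] <- h
      pos <- pos + nb
    }
  }
  list(values = values, meta = meta)
}

#' Extract LBP-TOP feature matrices for a cohort
#'
#' Runs [lbp_top()] + [region_histograms()] for every subject volume and
#' every radius.  Features from different radii are kept as distinct,
#' named groups (they enter iterative feature selection separately).
#'
#' @param volumes list of [volume()]s sharing shape/spacing with `atlas`.
#' @param atlas a [label_volume()].
#' @param P neighbor count (default 8).
#' @param radii_mm numeric vector of radii in mm (default `c(1, 2, 3)`).
#' @param sampling see [neighborhood_spec()].
#' @param normalize see [region_histograms()].
#' @param subject_ids optional character vector of row names.
#' @return An object of class `lbp_feature_set`: list with `X` (subjects x
#'   features matrix), `meta` (per-column data.frame with `radius_mm`,
#'   `region`, `plane`, `bin`), `groups` (named list of column index
#'   vectors, one per radius), `valid_voxels` (per subject).
#' @export
extract_features <- function(volumes, atlas, P = 8L, radii_mm = c(1, 2, 3),
                             sampling = c("circular_interpolated", "square"),
                             normalize = TRUE, subject_ids = NULL) {
  sampling <- match.arg(sampling)
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_along(volumes))
  umap <- build_uniform_map(P)
  rows <- vector("list", length(volumes))
  valid_counts <- integer(length(volumes))
  meta <- NULL
  groups <- NULL
  for (s in seq_along(volumes)) {
    v <- volumes[[s]]
    al <- try(check_aligned(v, atlas), silent = TRUE)
    if (inherits(al, "try-error"))
      stop("subject ", subject_ids[s], " is not aligned with the atlas: ",
           attr(al, "condition")$message)
    per_radius <- lapply(radii_mm, function(R) {
      ct <- lbp_top(v, P = P, R_mm = R, sampling = sampling)
      h <- region_histograms(ct, atlas, umap, normalize = normalize)
      h$n_valid <- sum(ct$valid)
      h
    })
    valid_counts[s] <- per_radius[[length(per_radius)]]$n_valid
    if (is.null(meta)) {
      meta <- do.call(rbind, lapply(seq_along(radii_mm), function(k) {
        m <- per_radius[[k]]$meta
        cbind(radius_mm = radii_mm[k], m)
      }))
      sizes <- vapply(per_radius, function(h) length(h$values), integer(1))
      ends <- cumsum(sizes)
      groups <- lapply(seq_along(radii_mm), function(k)
        (c(0L, ends)[k] + 1L):ends[k])
      names(groups) <- paste0("R", radii_mm, "mm")
    }
    rows[[s]] <- unlist(lapply(per_radius, `[[`, "values"))
  }
  X <- do.call(rbind, rows)
  rownames(X) <- subject_ids
  colnames(X) <- feature_column_names(meta)
  structure(list(X = X, meta = meta, groups = groups,
                 valid_voxels = valid_counts, P = as.integer(P),
                 radii_mm = radii_mm, normalize = normalize),
            class = "lbp_feature_set")
}

#' @export
print.lbp_feature_set <- function(x, ...) {
  cat("<lbp_feature_set> ", nrow(x$X), " subjects x ", ncol(x$X),
      " features (", length(x$groups), " radius group(s): ",
      paste(names(x$groups), collapse = ", "), "), P = ", x$P, "\n", sep = "")
  invisible(x)
}
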