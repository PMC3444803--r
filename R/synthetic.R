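# Seeded synthetic texture phantoms, masks, toy atlases, cohorts and
# region timecourses.  The class signal is deliberately *textural*
# (smoothing scale or fold frequency), never a mean-intensity shift:
# LBP codes are invariant to monotone intensity maps, so only changes in
# the local intensity *ordering* — i.e. morphology — are visible to the
# pipeline, mirroring the premise that group differences live in cortical
# folding patterns rather than raw intensity.

#' Specification of a synthetic texture phantom cohort
#'
#' @param shape voxel counts per axis (default 18^3: radius-3
#'   neighborhoods keep a 12^3 = 1728-voxel valid core, comfortably above
#'   the 100-voxel floor).
#' @param spacing_mm voxel size (default 1 mm isotropic, the resolution
#'   the texture radii 1/2/3 mm are defined on).
#' @param n_regions atlas regions inside the mask (default 1 =
#'   whole-brain mask).
#' @param class_effect >= 0; between-class texture difference.  For
#'   `smoothed_noise` it is the extra smoothing width (voxels) of class 1
#'   (class 0 uses `base_sigma`); the calibrated strong setting is
#'   `class_effect = 2`, i.e. widths 1 vs 3 voxels.  For `fold_pattern` it
#'   is the relative spatial-frequency difference of the fold lattice.
#'   `class_effect = 0` makes the two class distributions identical.
#' @param texture_kind `"smoothed_noise"` (Gaussian white noise smoothed
#'   with a class-dependent kernel) or `"fold_pattern"` (3D sinusoidal
#'   "gyrification" lattice with class-dependent frequency plus noise).
#' @param noise_sd additive white-noise SD on top of the structured
#'   texture (default 0.1 for `fold_pattern`, 0 for `smoothed_noise`
#'   where the noise *is* the texture).
#' @param base_sigma smoothing width (voxels) of class 0 for
#'   `smoothed_noise` (default 1).
#' @param base_freq fold frequency of class 0 in cycles/voxel for
#'   `fold_pattern` (default 0.15).
#' @param probability_map if TRUE, squash intensities into (0, 1) with a
#'   logistic to emulate a tissue probability map.
#' @param seed integer master seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(18L, 18L, 18L), spacing_mm = c(1, 1, 1),
                         n_regions = 1L, class_effect = 2,
                         texture_kind = c("smoothed_noise", "fold_pattern"),
                         noise_sd = NULL, base_sigma = 1, base_freq = 0.15,
                         probability_map = FALSE, seed = 1L) {
  texture_kind <- match.arg(texture_kind)
  if (is.null(noise_sd))
    noise_sd <- if (texture_kind == "fold_pattern") 0.1 else 0
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be 3 axis lengths >= 8")
  if (class_effect < 0) stop("class_effect must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_regions < 1L) stop("n_regions must be >= 1")
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 n_regions = as.integer(n_regions),
                 class_effect = class_effect, texture_kind = texture_kind,
                 noise_sd = noise_sd, base_sigma = base_sigma,
                 base_freq = base_freq, probability_map = probability_map,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing, nearest-edge padding
gaussian_smooth_3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  n <- dim(a)
  for (ax in 1:3) {
    out <- array(0, n)
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n[ax]) + o, 1L), n[ax])
      shifted <- switch(ax,
                        a[idx, , , drop = FALSE],
                        a[, idx, , drop = FALSE],
                        a[, , idx, drop = FALSE])
      out <- out + k[o + r + 1L] * shifted
    }
    a <- out
  }
  a
}

# central ellipsoid mask + atlas of n_regions equal-count chunks of the
# masked voxels in array (column-major) order
phantom_geometry <- function(spec) {
  n <- spec$shape
  g <- expand.grid(x = seq_len(n[1]), y = seq_len(n[2]), z = seq_len(n[3]))
  ctr <- (n + 1) / 2
  semi <- 0.45 * n
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  if (sum(inside) < spec$n_regions)
    stop("mask has ", sum(inside), " voxels, fewer than n_regions = ",
         spec$n_regions)
  lab <- integer(prod(n))
  w <- which(inside)
  chunk <- if (spec$n_regions == 1L) rep(1L, length(w))
           else cut(seq_along(w), spec$n_regions, labels = FALSE)
  lab[w] <- chunk
  label_volume(array(lab, n), spec$spacing_mm)
}

#' Generate one synthetic texture phantom
#'
#' Deterministic given `(spec$seed, class_id, subject)`.  The returned
#' atlas depends only on the geometry fields of `spec`, so all subjects
#' of a cohort share it.
#'
#' @param spec a [phantom_spec()].
#' @param class_id 0 or 1.
#' @param subject subject index used to derive the per-subject sub-seed.
#' @return list with `volume` (a [volume()]) and `atlas`
#'   (a [label_volume()]; a mask when `n_regions = 1`).
#' @export
generate_phantom <- function(spec, class_id, subject = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!class_id %in% c(0L, 1L)) stop("class_id must be 0 or 1")
  n <- spec$shape
  sseed <- derive_seed(spec$seed, subject, class_id)
  v <- with_seed(sseed, {
    if (spec$texture_kind == "smoothed_noise") {
      sigma <- spec$base_sigma + class_id * spec$class_effect
      x <- gaussian_smooth_3d(array(stats::rnorm(prod(n)), n), sigma)
      x <- x / stats::sd(x)
      if (spec$noise_sd > 0)
        x <- x + spec$noise_sd * stats::rnorm(prod(n))
      x
    } else {
      freq <- spec$base_freq * (1 + class_id * spec$class_effect)
      ph <- stats::runif(3, 0, 2 * pi)
      ax <- lapply(1:3, function(i)
        sin(2 * pi * freq * seq_len(n[i]) + ph[i]))
      x <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
      x + spec$noise_sd * array(stats::rnorm(prod(n)), n)
    }
  })
  if (spec$probability_map) v <- 1 / (1 + exp(-v))
  list(volume = volume(v, spec$spacing_mm),
       atlas = phantom_geometry(spec))
}

#' Generate a balanced two-class phantom cohort
#'
#' Subjects get independent sub-seeds derived deterministically from
#' `spec$seed`; all share one atlas.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_class subjects per class (>= 1).
#' @return list with `volumes` (list), `labels` (data.frame `subject_id`,
#'   `class`), `y` (integer vector), `atlas`.
#' @export
generate_cohort <- function(spec, n_per_class) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  y <- rep(c(0L, 1L), each = n_per_class)
  ids <- sprintf("sub%03d", seq_along(y))
  vols <- lapply(seq_along(y), function(i)
    generate_phantom(spec, y[i], subject = i)$volume)
  list(volumes = vols,
       labels = data.frame(subject_id = ids, class = y,
                           stringsAsFactors = FALSE),
       y = y, atlas = phantom_geometry(spec))
}

#' Generate block-correlated region timecourses
#'
#' Multivariate Gaussian draws with a block-structured target correlation:
#' regions are split into `n_blocks` contiguous blocks; pairs within a
#' block have correlation `block_correlation`, pairs across blocks 0.
#' The default single block gives every pair the same target.
#'
#' @param n_regions number of regions (>= 2).
#' @param n_timepoints number of samples (>= 3).
#' @param block_correlation target within-block correlation, |rho| < 1
#'   and above the positive-definiteness floor `-1/(block size - 1)`.
#' @param seed integer seed.
#' @param n_blocks number of blocks (default 1).
#' @return numeric matrix, regions x timepoints.
#' @export
generate_timecourses <- function(n_regions, n_timepoints,
                                 block_correlation = 0, seed = 1L,
                                 n_blocks = 1L) {
  if (n_regions < 2L) stop("need >= 2 regions")
  if (n_timepoints < 3L) stop("need >= 3 timepoints")
  if (abs(block_correlation) >= 1) stop("|block_correlation| must be < 1")
  block <- if (n_blocks == 1L) rep(1L, n_regions)
           else cut(seq_len(n_regions), n_blocks, labels = FALSE)
  S <- outer(block, block, `==`) * block_correlation
  diag(S) <- 1
  L <- tryCatch(chol(S), error = function(e)
    stop("block correlation ", block_correlation,
         " is not positive definite for these block sizes"))
  Z <- with_seed(seed,
                 matrix(stats::rnorm(n_timepoints * n_regions),
                        n_timepoints, n_regions))
  t(Z %*% L)
}
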