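# Independent scalar oracle: re-evaluates the LBP code of one voxel by a
# direct per-neighbor loop (its own offset, interpolation and comparison
# code), used to cross-check the vectorized plane implementation.
oracle_lbp_code <- function(a, i, j, k, P, R_vox, plane,
                            sampling = "circular_interpolated") {
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  ctr <- c(i, j, k)
  code <- 0
  for (p in 0:(P - 1)) {
    if (sampling == "square") {
      u <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
                 c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
      off <- u[p + 1, ] * R_vox
    } else {
      ang <- 2 * pi * p / P
      off <- c(cos(ang), sin(ang)) * R_vox
      snap <- abs(off - round(off)) < 1e-9
      off[snap] <- round(off[snap])
    }
    x <- ctr[ax[1]] + off[1]
    y <- ctr[ax[2]] + off[2]
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    x1 <- if (fx == 0) x0 else x0 + 1
    y1 <- if (fy == 0) y0 else y0 + 1
    at <- function(xx, yy) {
      q <- ctr; q[ax] <- c(xx, yy)
      a[q[1], q[2], q[3]]
    }
    t0 <- at(x0, y0) + fx * (at(x1, y0) - at(x0, y0))
    t1 <- at(x0, y1) + fx * (at(x1, y1) - at(x0, y1))
    vp <- t0 + fy * (t1 - t0)
    if (vp >= a[i, j, k]) code <- code + 2^p
  }
  code
}

# compare every valid voxel of an lbp_top result against the oracle
expect_codes_match_oracle <- function(a, ct, R_vox,
                                      sampling = "circular_interpolated") {
  n <- dim(a)
  planes <- list(xy = ct$codes_xy, xz = ct$codes_xz, yz = ct$codes_yz)
  mismatches <- 0L
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3]))
    if (ct$valid[i, j, k])
      for (pl in names(planes)) {
        want <- oracle_lbp_code(a, i, j, k, ct$P, R_vox, pl, sampling)
        if (planes[[pl]][i, j, k] != want) mismatches <- mismatches + 1L
      }
  expect_identical(mismatches, 0L)
  invisible(mismatches)
}

# circular-uniformity oracle via an explicit bit string
oracle_uniformity <- function(code, P) {
  bits <- as.integer(intToBits(code))[1:P]
  sum(bits != bits[c(2:P, 1)])
}

rand_volume <- function(n, seed) {
  set.seed(seed)
  volume(array(rnorm(n^3), c(n, n, n)))
}

seeded_shuffle <- function(x, seed) {
  set.seed(seed)
  sample(x)
}
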