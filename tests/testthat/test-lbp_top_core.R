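test_that("plane codes: constant volume, local maximum, square-mode example", {
  # constant input: every difference is 0 and sign(0) = 1, so all bits set
  v <- volume(array(5, c(10, 10, 10)))
  for (pl in c("xy", "xz", "yz")) {
    cp <- lbp_codes_plane(v, neighborhood_spec(8, 1, plane = pl))
    expect_true(all(cp$codes[cp$valid] == 255L))
  }

  # a strict in-plane maximum codes to 0 (all differences negative)
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 10
  cp <- lbp_codes_plane(volume(a), neighborhood_spec(8, 1, plane = "xy"))
  expect_identical(cp$codes[5, 5, 5], 0L)

  # fixed scalar example, square sampling: center 5, neighbors in bit
  # order (6,4,5,7,2,5,8,1) -> bits 0,2,3,5,6 -> 109
  b <- array(0, c(5, 5, 5)); b[3, 3, 3] <- 5
  off <- rbind(c(1, 0), c(1, 1), c(0, 1), c(-1, 1),
               c(-1, 0), c(-1, -1), c(0, -1), c(1, -1))
  nb <- c(6, 4, 5, 7, 2, 5, 8, 1)
  for (p in 1:8) b[3 + off[p, 1], 3 + off[p, 2], 3] <- nb[p]
  cp2 <- lbp_codes_plane(volume(b), neighborhood_spec(8, 1, "square", "xy"))
  expect_identical(cp2$codes[3, 3, 3], 109L)

  # contract errors
  aniso <- volume(array(0, c(8, 8, 8)), c(1, 2, 1))
  expect_error(lbp_codes_plane(aniso, neighborhood_spec(8, 1, plane = "xy")),
               "anisotropic")
  expect_error(lbp_codes_plane(v, neighborhood_spec(8, 0.5, plane = "xy")),
               "below 1 voxel")
})

test_that("lbp_top: joint validity, plane separability, oracle equivalence", {
  v <- volume(array(1, c(16, 16, 16)))
  ct <- lbp_top(v, 8, 1)
  expect_identical(sum(ct$valid), 2744L)  # 14^3 interior voxels
  expect_true(all(ct$codes_xy[ct$valid] == 255L))

  # intensity varying only along z: xy-plane differences are all zero
  a <- array(rep(sin(1:16), each = 16 * 16), c(16, 16, 16))
  ctz <- lbp_top(volume(a), 8, 1)
  expect_true(all(ctz$codes_xy[ctz$valid] == 255L))

  # brute-force per-voxel oracle on random volumes, both radii
  for (seed in 1:2) {
    v <- rand_volume(12, seed)
    for (R in c(1, 2))
      expect_codes_match_oracle(v$data, lbp_top(v, 8, R), R)
  }
})

test_that("uniformity measure matches circular transition counting", {
  expect_identical(uniformity(0L, 8), 0L)                 # 00000000
  expect_identical(uniformity(strtoi("01110000", base = 2), 8), 2L)
  expect_identical(uniformity(strtoi("01010101", base = 2), 8), 8L)
  expect_error(uniformity(256L, 8), "out of range")
  # full-census cross-check against an independent bit-string oracle
  want <- vapply(0:255, oracle_uniformity, integer(1), P = 8)
  expect_identical(uniformity(0:255, 8), want)
})

test_that("uniform map: census, bin count law, catch-all placement", {
  for (P in c(4L, 8L)) {
    um <- build_uniform_map(P)
    n_uniform <- sum(uniformity(0:(2^P - 1), P) <= 2)
    expect_identical(n_uniform, P * (P - 1L) + 2L)
    expect_identical(um$n_bins, P * (P - 1L) + 3L)
    expect_identical(sort(unique(um$table)), 0:(um$n_bins - 1L))
    # uniform codes get distinct bins in ascending code order
    uc <- which(uniformity(0:(2^P - 1), P) <= 2L) - 1L
    expect_identical(um$table[uc + 1L], seq_along(uc) - 1L)
    # all-zeros and all-ones are uniform, distinct, not the catch-all
    ends <- um$table[c(1L, 2^P)]
    expect_true(all(ends != um$n_bins - 1L))
    expect_false(ends[1] == ends[2])
  }
  expect_identical(build_uniform_map(8)$n_bins, 59L)
  expect_identical(build_uniform_map(4)$n_bins, 15L)
})

test_that("region histograms: conservation, normalization, zero regions", {
  set.seed(20)
  v <- rand_volume(14, 21)
  ct <- lbp_top(v, 8, 1)
  um <- build_uniform_map(8)
  lab <- array(0L, c(14, 14, 14))
  lab[2:13, 2:13, 2:7] <- 1L
  lab[2:13, 2:13, 8:13] <- 5L
  atlas <- label_volume(lab)

  h <- region_histograms(ct, atlas, um, normalize = FALSE)
  for (r in c(1L, 5L)) {
    n_r <- sum(ct$valid & atlas$labels == r)
    for (pl in c("xy", "xz", "yz")) {
      blk <- h$values[h$meta$region == r & h$meta$plane == pl]
      expect_identical(sum(blk), as.numeric(n_r))
    }
  }
  hn <- region_histograms(ct, atlas, um, normalize = TRUE)
  for (r in c(1L, 5L)) for (pl in c("xy", "xz", "yz"))
    expect_equal(sum(hn$values[hn$meta$region == r & hn$meta$plane == pl]),
                 1, tolerance = 1e-9)

  # region entirely outside the valid set -> zero block + warning
  lab2 <- lab; lab2[1, 1, 1] <- 99L
  expect_warning(h2 <- region_histograms(ct, label_volume(lab2), um),
                 "region 99")
  expect_true(all(h2$values[h2$meta$region == 99] == 0))

  # constant volume, one region: all mass in the bin of code 255
  vc <- volume(array(2, c(14, 14, 14)))
  ctc <- lbp_top(vc, 8, 1)
  hc <- region_histograms(ctc, label_volume(array(1L, c(14, 14, 14))), um,
                          normalize = FALSE)
  bin255 <- um$table[256]
  for (pl in c("xy", "xz", "yz")) {
    blk <- hc$values[hc$meta$plane == pl]
    expect_identical(blk[bin255 + 1], as.numeric(sum(ctc$valid)))
    expect_identical(sum(blk[-(bin255 + 1)]), 0)
  }
})

test_that("feature dimension law: 177 / 20532 / 33630 at P = 8", {
  expect_identical(1L * 3L * build_uniform_map(8)$n_bins, 177L)
  expect_identical(116L * 3L * 59L, 20532L)
  sp <- phantom_spec(shape = c(12L, 12L, 12L), n_regions = 116L, seed = 6)
  ph <- generate_phantom(sp, 0)
  fs <- extract_features(list(ph$volume), ph$atlas, radii_mm = 1)
  expect_identical(ncol(fs$X), 20532L)
})

test_that("monotone intensity maps and integer shifts leave codes unchanged", {
  set.seed(22)
  v <- rand_volume(12, 23)
  # grid-aligned (square) sampling: exact invariance under any strictly
  # increasing map, since only value ordering enters the comparisons
  ct1 <- lbp_top(v, 8, 1, sampling = "square")
  ct2 <- lbp_top(volume(exp(v$data), v$spacing), 8, 1, sampling = "square")
  expect_identical(ct1$codes_xy, ct2$codes_xy)
  expect_identical(ct1$codes_xz, ct2$codes_xz)
  expect_identical(ct1$codes_yz, ct2$codes_yz)
  # affine maps preserve interpolated comparisons too
  ct3 <- lbp_top(volume(3 * v$data + 7, v$spacing), 8, 1)
  ct0 <- lbp_top(v, 8, 1)
  expect_identical(ct0$codes_xy, ct3$codes_xy)

  # shift invariance: translate volume and atlas by one voxel
  a <- v$data
  b <- array(rnorm(12^3), c(12, 12, 12)); b[2:12, , ] <- a[1:11, , ]
  cta <- lbp_top(v, 8, 1)
  ctb <- lbp_top(volume(b), 8, 1)
  core <- 3:10
  expect_identical(cta$codes_xy[core, core, core],
                   ctb$codes_xy[core + 1, core, core])
})

test_that("extract_features: group layout, determinism, row permutation", {
  sp <- phantom_spec(shape = c(14L, 14L, 14L), seed = 9)
  co <- generate_cohort(sp, 2)
  fs <- extract_features(co$volumes, co$atlas, radii_mm = c(1, 2, 3))
  expect_identical(ncol(fs$X), 3L * 177L)
  expect_identical(lengths(fs$groups), c(R1mm = 177L, R2mm = 177L,
                                         R3mm = 177L))
  expect_identical(unique(fs$meta$radius_mm[fs$groups$R2mm]), 2)

  # duplicate subject volumes give identical rows
  fs2 <- extract_features(co$volumes[c(1, 1)], co$atlas, radii_mm = 1)
  expect_identical(fs2$X[1, ], fs2$X[2, ])

  # permuting subjects permutes rows only
  perm <- c(3, 1, 4, 2)
  fsp <- extract_features(co$volumes[perm], co$atlas, radii_mm = 1)
  fs1 <- extract_features(co$volumes, co$atlas, radii_mm = 1)
  expect_identical(unname(fsp$X), unname(fs1$X[perm, ]))

  # misaligned subject aborts with its id
  bad <- volume(array(0, c(12, 12, 12)))
  expect_error(extract_features(list(co$volumes[[1]], bad), co$atlas,
                                radii_mm = 1, subject_ids = c("a", "bad1")),
               "bad1")
})
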