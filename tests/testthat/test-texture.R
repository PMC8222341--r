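# quantization, first-order, co-occurrence and run-length markers, with
# brute-force oracles

test_that("gray-level normalization maps the mask range onto 0..255", {
  mask <- array(TRUE, c(3, 1, 1))
  vol <- array(c(10, 20, 30), c(3, 1, 1))
  q <- normalize_gray_levels(vol, mask)
  expect_identical(sort(q$levels), c(0L, 128L, 255L))

  qc <- normalize_gray_levels(array(7, c(3, 1, 1)), mask)
  expect_true(all(qc$levels == 0L))

  set.seed(1)
  v <- array(rnorm(4^3), c(4, 4, 4))
  q2 <- normalize_gray_levels(v, array(TRUE, c(4, 4, 4)))
  expect_identical(range(q2$levels), c(0L, 255L))
  expect_error(normalize_gray_levels(v, array(FALSE, c(4, 4, 4))), "empty mask")
})

test_that("first-order markers match the histogram oracle", {
  mask <- array(TRUE, c(4, 4, 4))
  vol <- array(c(rep(0, 32), rep(255, 32)), c(4, 4, 4))
  f <- first_order_markers(normalize_gray_levels(vol, mask))
  expect_length(f, 26L)
  expect_equal(unname(f["mean"]), 127.5)
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["entropy"]), 1)  # one bit

  fc <- first_order_markers(normalize_gray_levels(array(3, c(2, 2, 2)),
                                                  array(TRUE, c(2, 2, 2))))
  expect_equal(unname(fc["variance"]), 0)
  expect_equal(unname(fc["entropy"]), 0)
  expect_true(all(fc[sprintf("cdf_%03d", seq(10, 100, 10))] == 1))
  expect_equal(unname(fc["skewness"]), 0)
  expect_equal(unname(fc["kurtosis"]), 0)

  set.seed(7)
  v <- array(sample(0:255, 5^3, replace = TRUE), c(5, 5, 5))
  q <- normalize_gray_levels(v, array(TRUE, c(5, 5, 5)))
  expect_equal(first_order_markers(q), oracle_first_order(q$levels))
})

test_that("GLCM matches exhaustive pair enumeration and its closed forms", {
  mask <- array(TRUE, c(1, 1, 2))
  vol <- array(c(5, 9), c(1, 1, 2))
  q <- normalize_gray_levels(vol, mask)
  P <- glcm(q)
  expect_equal(dim(unclass(P)), c(256L, 256L))
  expect_equal(P[1, 256], 0.5)
  expect_equal(P[256, 1], 0.5)
  expect_equal(sum(P), 1)
  m <- glcm_markers(P)
  expect_equal(unname(m["contrast"]), 255^2)

  qc <- normalize_gray_levels(array(4, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  mc <- glcm_markers(glcm(qc))
  expect_equal(unname(mc[c("contrast", "dissimilarity", "homogeneity",
                           "asm", "energy", "correlation")]),
               c(0, 0, 1, 1, 1, 1))

  U <- matrix(1 / 65536, 256, 256)
  expect_equal(unname(glcm_markers(U)["asm"]), 1 / 65536)
  expect_error(glcm_markers(U * 2), "matrix not normalized")

  # irregular masked region against the brute-force oracle
  set.seed(11)
  mask <- array(runif(4^3) < 0.7, c(4, 4, 4))
  mask[2, 2, 2] <- TRUE
  vol <- array(rnorm(4^3), c(4, 4, 4))
  # oracle works on the full-grid level array
  lev <- array(NA_integer_, dim(mask))
  v <- vol[mask]
  lev[mask] <- as.integer(round(255 * (v - min(v)) / diff(range(v))))
  q <- normalize_gray_levels(vol, mask)
  expect_equal(unclass(glcm(q)), oracle_glcm(lev), ignore_attr = TRUE)

  one <- array(FALSE, c(3, 3, 3)); one[1, 1, 1] <- TRUE
  expect_error(glcm(normalize_gray_levels(vol[1:3, 1:3, 1:3], one)),
               "no co-occurrences")
})

test_that("GLCM is symmetric, normalized and invariant under grid symmetries", {
  set.seed(3)
  mask <- digital_ball(4, 12)
  vol <- array(rnorm(12^3), c(12, 12, 12))
  P <- unclass(glcm(normalize_gray_levels(vol, mask)))
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_identical(P, t(P))
  for (perm in list(c(2, 1, 3), c(3, 1, 2), c(2, 3, 1))) {
    P2 <- unclass(glcm(normalize_gray_levels(aperm(vol, perm), aperm(mask, perm))))
    expect_equal(P2, P, tolerance = 1e-12)
  }
  # 90-degree rotation: transpose + reverse one axis
  rot <- function(a) aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  P3 <- unclass(glcm(normalize_gray_levels(rot(vol), rot(mask))))
  expect_equal(P3, P, tolerance = 1e-12)
})

test_that("GLRLM matches run enumeration and conserves voxels", {
  # single row: runs along x, unit runs along y and z
  mask <- array(TRUE, c(5, 1, 1))
  vol <- array(c(0, 0, 255, 255, 255), c(5, 1, 1))
  q <- normalize_gray_levels(vol, mask)
  M <- glrlm(q)
  expect_equal(nrow(M), 256L)
  expect_equal(ncol(M), 5L)  # largest bounding-box dimension
  expect_equal(M[1, 2], 1)    # x: run of two 0s
  expect_equal(M[256, 3], 1)  # x: run of three 255s
  expect_equal(M[1, 1], 4)    # y+z unit runs of level 0
  expect_equal(M[256, 1], 6)
  expect_equal(sum(M * col(M)), 3 * q$n)

  # checkerboard: every run has length 1
  g <- 4
  idx <- as.matrix(expand.grid(1:g, 1:g, 1:g))
  vol <- array(ifelse(rowSums(idx) %% 2 == 0, 0, 100), c(g, g, g))
  q <- normalize_gray_levels(vol, array(TRUE, c(g, g, g)))
  M <- glrlm(q)
  expect_true(all(M[, -1] == 0))
  mk <- glrlm_markers(M)
  expect_equal(unname(mk[c("sre", "lre", "rp")]), c(1, 1, 1))

  # one run of length L at the top level
  mask <- array(TRUE, c(6, 1, 1))
  q <- normalize_gray_levels(array(c(0, rep(9, 5)), c(6, 1, 1)), mask)
  Mx <- matrix(0, 256, 6)
  Mx[256, 5] <- 1  # isolate the x-run of the five equal voxels
  attr(Mx, "directions") <- 1L
  attr(Mx, "n_voxels") <- 5L
  mk <- glrlm_markers(Mx)
  expect_equal(unname(mk["lre"]), 25)
  expect_equal(unname(mk["sre"]), 1 / 25)
  expect_error(glrlm_markers(matrix(0, 256, 3)), "empty run matrix")

  # irregular region against the exhaustive oracle
  set.seed(5)
  mask <- array(runif(5^3) < 0.6, c(5, 5, 5))
  mask[3, 3, 3] <- TRUE
  vol <- array(sample(0:3, 5^3, replace = TRUE) * 50, c(5, 5, 5))
  q <- normalize_gray_levels(vol, mask)
  lev <- array(NA_integer_, dim(mask))
  v <- vol[mask]
  lev[mask] <- as.integer(round(255 * (v - min(v)) / diff(range(v))))
  expect_equal(unclass(glrlm(q)), oracle_glrlm(lev, ncol(glrlm(q))),
               ignore_attr = TRUE)
  expect_equal(sum(glrlm(q) * col(glrlm(q))), 3 * q$n)
})

test_that("per-study texture block behaves under invariances", {
  s <- toy_study(seed = 13)
  tm <- textural_markers(s)
  expect_length(tm, 176L)

  # identical phases give identical per-phase blocks
  s2 <- s
  for (ph in names(s2$phases)) s2$phases[[ph]] <- s$phases$pre
  tm2 <- textural_markers(s2)
  pre <- tm2[grep("^pre_", names(tm2))]
  for (pf in c("art", "pv", "del")) {
    blk <- tm2[grep(paste0("^", pf, "_"), names(tm2))]
    expect_equal(unname(blk), unname(pre))
  }

  # affine intensity rescaling is absorbed by the min-max quantization
  s3 <- s
  s3$phases$arterial <- 3.7 * s$phases$arterial + 120
  tm3 <- textural_markers(s3)
  expect_equal(tm3, tm)

  # first-order markers are histogram-only: voxel shuffling preserves them,
  # but destroys spatial correlation, so contrast rises on a smooth phantom
  s4 <- small_phantom("LR1", seed = 2)
  q <- normalize_gray_levels(s4$phases$arterial, s4$mask)
  set.seed(1)
  vol_sh <- s4$phases$arterial
  vol_sh[s4$mask] <- sample(vol_sh[s4$mask])
  qs <- normalize_gray_levels(vol_sh, s4$mask)
  expect_equal(first_order_markers(qs), first_order_markers(q))
  expect_gt(glcm_markers(glcm(qs))["contrast"], glcm_markers(glcm(q))["contrast"])

  # heterogeneous phantom shows higher contrast than a homogeneous one on
  # every phase (equal kinetics, different spatial texture)
  het <- small_phantom("LR1", seed = 6, corr_sigma = 0.8, white_frac = 0.8)
  hom <- small_phantom("LR1", seed = 6)
  tmh <- textural_markers(het)
  tml <- textural_markers(hom)
  for (pf in c("pre", "art", "pv", "del"))
    expect_gt(tmh[paste0(pf, "_glcm_contrast")], tml[paste0(pf, "_glcm_contrast")])
})
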