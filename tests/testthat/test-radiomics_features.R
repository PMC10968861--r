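test_that("discretization follows the fixed-bin-width closed form", {
  cfg <- discretization_config()
  # min-anchored constant ROI collapses to level 1
  expect_true(all(discretize(rep(5.1, 10), cfg, "pet") == 1L))
  # zero anchor: floor(5.1 / 0.3125) + 1 = 17
  cfg0 <- discretization_config(anchor = "zero")
  expect_true(all(discretize(rep(5.1, 10), cfg0, "pet") == 17L))
  # clipping at the configured level count
  expect_equal(as.integer(discretize(25.0, cfg0, "pet")), 64L)
  # CT bin width 10 HU
  expect_equal(as.integer(discretize(c(0, 9.99, 10), cfg0, "ct")),
               c(1L, 1L, 2L))
})

test_that("first-order statistics: arithmetic, MTV/TLG scaling, entropy", {
  vol <- array(0, c(3, 1, 1)); vol[] <- c(2, 4, 6)
  mask <- array(1L, c(3, 1, 1))
  fo <- first_order(vol, mask, c(10, 10, 10), modality = "pet")
  expect_equal(fo$max, 6)
  expect_equal(fo$mean, 4)
  expect_equal(fo$MTV_ml, 3)
  expect_equal(fo$TLG, 12)
  # constant ROI: single occupied level, entropy 0
  cvol <- array(5, c(4, 4, 4))
  expect_equal(first_order(cvol, array(1L, c(4, 4, 4)), c(1, 1, 1),
                           modality = "pet")$entropy, 0)
  # two levels with equal counts: exactly 1 bit
  tvol <- array(rep(c(1, 3), each = 32), c(4, 4, 4))
  expect_equal(first_order(tvol, array(1L, c(4, 4, 4)), c(1, 1, 1),
                           modality = "pet")$entropy, 1)
  expect_error(first_order(cvol, array(0L, c(4, 4, 4)), c(1, 1, 1)),
               "empty-ROI")
})

test_that("AUC-CSH matches piecewise-constant and uniform oracles", {
  n <- 100L
  tol <- 1 / (2 * (n - 1))
  uni <- array(7, c(4, 4, 4))
  m <- array(1L, c(4, 4, 4))
  expect_equal(auc_csh(uni, m, n), 1.0, tolerance = tol)
  half <- array(rep(c(10, 5), each = 32), c(4, 4, 4))
  expect_equal(auc_csh(half, m, n), 0.75, tolerance = tol)
  # SUV uniform on (0, max]: integral of (1 - t) dt = 0.5
  set.seed(11)
  big <- array(runif(20^3, 0, 12), c(20, 20, 20))
  expect_equal(auc_csh(big, array(1L, c(20, 20, 20)), n), 0.5,
               tolerance = 0.02)
})

test_that("Dmax is the max pairwise centroid distance, 0 for one lesion", {
  m <- array(0L, c(10, 10, 10)); m[2:4, 2:4, 2:4] <- 1L
  expect_equal(dmax(m, c(1, 1, 1)), 0)
  m2 <- array(0L, c(10, 10, 10))
  m2[1, 1, 1] <- 1L; m2[4, 5, 1] <- 1L      # voxel offset (3,4,0)
  expect_equal(dmax(m2, c(1, 1, 1)), 5)
  m3 <- array(0L, c(30, 3, 3))
  m3[1, 1, 1] <- 1L; m3[11, 1, 1] <- 1L; m3[26, 1, 1] <- 1L
  expect_equal(dmax(m3, c(1, 1, 1)), 25)
  # diagonal-touching voxels merge under 26-connectivity
  m4 <- array(0L, c(5, 5, 5)); m4[1, 1, 1] <- 1L; m4[2, 2, 2] <- 1L
  expect_equal(dmax(m4, c(1, 1, 1)), 0)
})

test_that("GLRLM hand-enumerated examples and degenerate runs", {
  lev <- array(c(1L, 1L, 2L, 2L), c(1, 1, 4))
  m <- array(1L, c(1, 1, 4))
  f <- glrlm_features(lev, m, directions = matrix(c(0, 0, 1), 1))
  expect_equal(f$GLN, 1.0)   # two runs, one per level: (1^2+1^2)/2
  expect_equal(f$RLN, 2.0)   # both runs length 2: 2^2/2
  # constant ROI along its axis: a single run
  lev2 <- array(1L, c(1, 1, 6))
  f2 <- glrlm_features(lev2, array(1L, c(1, 1, 6)),
                       directions = matrix(c(0, 0, 1), 1))
  expect_equal(f2$GLN, 1)
  expect_equal(f2$RLN, 1)
  # masked-out voxel breaks a run
  m3 <- array(1L, c(1, 1, 4)); m3[1, 1, 2] <- 0L
  lev3 <- array(1L, c(1, 1, 4))
  mat <- glrlm_matrix(lev3, m3, directions = matrix(c(0, 0, 1), 1))
  expect_equal(unname(mat[1, ]), c(1, 1))   # runs of length 1 and 2
})

test_that("GLRLM equals the brute-force oracle on random ROIs (all 13 dirs)", {
  set.seed(101)
  for (i in 1:25) {
    roi <- random_roi()
    got <- glrlm_features(roi$levels, roi$mask)
    want <- oracle_glrlm(roi$levels, roi$mask)
    expect_equal(got$GLN, want$GLN, tolerance = 1e-12)
    expect_equal(got$RLN, want$RLN, tolerance = 1e-12)
  }
})

test_that("GLRLM run-length conservation per direction", {
  set.seed(202)
  dirs <- rbind(c(1, 0, 0), c(1, 1, 1), c(1, -1, 0))
  for (i in 1:10) {
    roi <- random_roi(c(5, 4, 3), n_levels = 3)
    for (j in seq_len(nrow(dirs))) {
      m <- glrlm_matrix(roi$levels, roi$mask, dirs[j, , drop = FALSE])
      lensum <- sum(sweep(m, 2, seq_len(ncol(m)), "*"))
      expect_equal(lensum, sum(roi$mask))
    }
  }
})

test_that("NGTDM: homogeneous guards, checkerboard and random oracle match", {
  const <- array(1L, c(4, 4, 4)); m <- array(1L, c(4, 4, 4))
  f <- ngtdm_features(const, m)
  expect_equal(f$coarseness, 1e6)
  expect_equal(f$contrast, 0)
  expect_equal(f$strength, 0)
  # 2-level 3D checkerboard
  idx <- array(0L, c(4, 4, 4))
  for (x in 1:4) for (y in 1:4) for (z in 1:4)
    idx[x, y, z] <- ((x + y + z) %% 2L) + 1L
  got <- ngtdm_features(idx, m)
  want <- oracle_ngtdm(idx, m)
  for (nm in names(want)) expect_equal(got[[nm]], want[[nm]],
                                       tolerance = 1e-12)
  set.seed(303)
  for (i in 1:10) {
    roi <- random_roi(c(5, 5, 5), n_levels = 5)
    got <- ngtdm_features(roi$levels, roi$mask)
    want <- oracle_ngtdm(roi$levels, roi$mask)
    for (nm in names(want)) expect_equal(got[[nm]], want[[nm]],
                                         tolerance = 1e-12)
  }
})

test_that("NGTDM accounting invariants hold on random ROIs", {
  set.seed(404)
  for (i in 1:10) {
    roi <- random_roi(c(4, 4, 4), n_levels = 4, p_mask = 0.5)
    nb <- deltaradiomics:::ngtdm_neighbour_means(roi$levels, roi$mask)
    lv <- roi$levels[nb$valid]
    n_i <- tabulate(lv)
    expect_equal(sum(n_i), sum(nb$valid))
    if (sum(n_i) > 0) expect_equal(sum(n_i / sum(n_i)), 1)
  }
})

test_that("full extraction: sphere phantom analytics and determinism", {
  ph <- sphere_phantom(n = 21, R_vox = 7, peak = 10, g = 2, background = 1)
  sp <- scan_pair("P1", "baseline", ph$pet,
                  array(40, dim(ph$mask)) + 25 * ph$mask, ph$mask,
                  c(2, 2, 2), "D690")
  fv <- extract_features(sp)
  vox_ml <- prod(c(2, 2, 2)) / 1000
  analytic_mtv <- 4 / 3 * pi * 7^3 * vox_ml
  expect_lt(abs(fv[["PET_MTV_ml"]] - analytic_mtv) / analytic_mtv, 0.10)
  expect_equal(unname(fv[["PET_SUVmax"]]), 11, tolerance = 0.05)
  expect_identical(fv, extract_features(sp))
})

test_that("features are translation invariant within the grid", {
  set.seed(55)
  base <- array(0, c(20, 20, 20))
  vals <- runif(5^3, 1, 9)
  m1 <- array(0L, c(20, 20, 20)); v1 <- base
  m1[3:7, 3:7, 3:7] <- 1L; v1[3:7, 3:7, 3:7] <- vals
  m2 <- array(0L, c(20, 20, 20)); v2 <- base
  m2[12:16, 11:15, 9:13] <- 1L; v2[12:16, 11:15, 9:13] <- vals
  s1 <- scan_pair("a", "baseline", v1, v1, m1, c(1, 1, 1))
  s2 <- scan_pair("a", "baseline", v2, v2, m2, c(1, 1, 1))
  expect_equal(extract_features(s1), extract_features(s2), tolerance = 1e-12)
})

test_that("single-voxel ROI: first order defined, NGTDM guarded", {
  v <- array(3, c(5, 5, 5))
  m <- array(0L, c(5, 5, 5)); m[3, 3, 3] <- 1L
  sp <- scan_pair("a", "baseline", v, v, m, c(1, 1, 1))
  fv <- extract_features(sp, include_rim = FALSE)
  expect_equal(unname(fv[["PET_SUVmax"]]), 3)
  expect_equal(unname(fv[["PET_NGTDM_coarseness"]]), 1e6)
  expect_equal(unname(fv[["PET_NGTDM_contrast"]]), 0)
})
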