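test_that("inventory closed form holds for both configurations", {
  inv22 <- feature_inventory(feature_config(22))
  expect_equal(inv22$total, 1132L)
  expect_equal(inv22[c("shape", "firstorder", "glcm", "gldm", "glrlm",
                       "glszm")],
               list(shape = 14L, firstorder = 234L, glcm = 286L,
                    gldm = 182L, glrlm = 208L, glszm = 208L))
  inv24 <- feature_inventory(feature_config(24))
  expect_equal(inv24$glcm, 312L)
  expect_equal(inv24$total, 1158L)
  for (g in c(22L, 24L)) {
    inv <- feature_inventory(feature_config(g))
    expect_equal(inv$total, 14L + 13L * (18L + g + 14L + 16L + 16L))
  }
  expect_error(feature_config(23), "22 or 24")
})

test_that("the image bank has 13 named deterministic members", {
  set.seed(5)
  v <- array(rnorm(16^3), c(16, 16, 16))
  b1 <- build_image_bank(v, c(1, 1, 1))
  expect_length(b1, 13L)
  expect_equal(names(b1)[1], "original")
  expect_equal(sum(startsWith(names(b1), "log_sigma_")), 4L)
  expect_equal(sum(startsWith(names(b1), "wavelet_")), 8L)
  b2 <- build_image_bank(v, c(1, 1, 1))
  expect_identical(b1, b2)
  expect_error(build_image_bank(v, c(1, 1, 2)), "isotropic")
})

test_that("constant volumes zero out detail bands and entropy features", {
  v <- array(42, c(14, 14, 14))
  wb <- wavelet_bank(v)
  for (nm in setdiff(names(wb), "LLL"))
    expect_lt(max(abs(wb[[nm]])), 1e-10)
  expect_equal(wb$LLL, array(42 * 2^(3 / 2), dim(v)), tolerance = 1e-12)

  m <- ball_mask(14, radius = 5)
  fv <- extract_features(v, m, c(1, 1, 1), feature_config(22))
  expect_equal(unname(fv["original_firstorder_Mean"]), 42)
  expect_equal(unname(fv["original_firstorder_Median"]), 42)
  expect_equal(unname(fv["original_firstorder_Entropy"]), 0)
  expect_equal(unname(fv["original_firstorder_Uniformity"]), 1)
  expect_equal(unname(fv["original_glcm_JointEntropy"]), 0)
  expect_equal(unname(fv["original_glcm_SumEntropy"]), 0)
  expect_equal(unname(fv["original_glcm_DifferenceEntropy"]), 0)
  expect_equal(unname(fv["original_glszm_ZoneEntropy"]), 0)
})

test_that("extraction yields the pinned counts with no non-finite values", {
  ph <- small_phantom(noise_sd = 5, seed = 41)
  vol <- phase_first(ph$series)
  fv22 <- extract_features(vol, ph$mask, c(1, 1, 1), feature_config(22))
  expect_length(fv22, 1132L)
  expect_true(all(is.finite(fv22)))
  expect_false(anyDuplicated(names(fv22)) > 0)
  fv24 <- extract_features(vol, ph$mask, c(1, 1, 1), feature_config(24))
  expect_length(fv24, 1158L)
  # the 24-set adds exactly SumAverage and MCC per image type
  extra <- setdiff(names(fv24), names(fv22))
  expect_length(extra, 26L)
  expect_true(all(grepl("_glcm_(SumAverage|MCC)$", extra)))
  # shared features agree between the two runs
  expect_equal(fv22, fv24[names(fv22)])
})

test_that("degenerate ROIs are refused", {
  v <- array(rnorm(8^3), c(8, 8, 8))
  m <- array(0L, c(8, 8, 8)); m[1:5] <- 1L
  expect_error(extract_features(v, m, c(1, 1, 1)), "degenerate ROI")
})

test_that("GLCM matrix agrees with the brute-force oracle", {
  set.seed(7)
  G <- array(sample.int(4L, 5 * 5 * 4, replace = TRUE), c(5, 5, 4))
  G[sample(length(G), 30)] <- NA_integer_   # irregular ROI
  expect_equal(glcm_matrix(G, 4L), glcm_oracle(G, 4L))
})

test_that("run and zone matrices behave on constructed patterns", {
  # a 1x1xN line of alternating levels: all runs have length 1
  G <- array(NA_integer_, c(1, 1, 8))
  G[1, 1, ] <- rep(c(1L, 2L), 4)
  R <- glrlm_matrix(G, 2L)
  # along z every run has length 1 (levels alternate); every other
  # direction sees single-voxel lines, also length 1: 13 x 8 unit runs
  expect_equal(sum(R), sum(R[, 1]))
  expect_equal(sum(R), 8 * attr(R, "n_directions"))
  expect_equal(R[1L, 1L], R[2L, 1L])

  # one homogeneous 2x2x2 block: a single zone of size 8
  G2 <- array(NA_integer_, c(4, 4, 4))
  G2[1:2, 1:2, 1:2] <- 3L
  Z <- glszm_matrix(G2, 3L)
  expect_equal(sum(Z), 1)
  expect_equal(Z[3, 8], 1)

  # dependence on a fully uniform cube interior: center voxel has 27
  G3 <- array(5L, c(3, 3, 3))
  D <- gldm_matrix(G3, 5L)
  expect_equal(ncol(D), 27L)
  expect_equal(D[5, 27], 1)          # the center voxel
  expect_equal(sum(D), 27)           # every voxel counted once
})

test_that("texture features are shift-invariant under data-anchored bins", {
  ph <- small_phantom(noise_sd = 6, seed = 43)
  vol <- phase_first(ph$series)
  cfg <- feature_config(22)
  f1 <- extract_features(vol, ph$mask, c(1, 1, 1), cfg)
  f2 <- extract_features(vol + 500, ph$mask, c(1, 1, 1), cfg)
  tex <- grepl("^original_(glcm|gldm|glrlm|glszm)_", names(f1))
  expect_equal(f1[tex], f2[tex], tolerance = 1e-10)
  # shape features are invariant to any intensity change
  shp <- grepl("^original_shape_", names(f1))
  f3 <- extract_features(vol * 3 + 11, ph$mask, c(1, 1, 1), cfg)
  expect_equal(f1[shp], f3[shp])
})

test_that("shape features hit analytic values on cubes and balls", {
  # an exactly voxelized cube: V = a^3, A = 6a^2
  m <- array(0L, c(20, 20, 20)); m[5:14, 5:14, 5:14] <- 1L
  fv <- shape_features(m, c(1, 1, 1))
  expect_equal(unname(fv["VoxelVolume"]), 1000)
  expect_equal(unname(fv["SurfaceArea"]), 600)
  expect_equal(unname(fv["Sphericity"]), (36 * pi * 1000^2)^(1 / 3) / 600)
  expect_equal(unname(fv["Maximum3DDiameter"]), sqrt(3) * 9)
  expect_equal(unname(fv["Maximum2DDiameterSlice"]), sqrt(2) * 9)
  expect_equal(unname(fv["Elongation"]), 1)
  expect_equal(unname(fv["Flatness"]), 1)

  # digital ball: voxel-face area tends to 1.5x the true sphere area, so
  # sphericity of this estimator tends to 2/3 (documented behaviour)
  mb <- ball_mask(40, radius = 15)
  fb <- shape_features(mb, c(1, 1, 1))
  expect_equal(unname(fb["Sphericity"]), 2 / 3, tolerance = 0.02)
  expect_equal(unname(fb["VoxelVolume"]), 4 / 3 * pi * 15^3,
               tolerance = 0.02)
  expect_equal(unname(fb["Maximum3DDiameter"]), 30, tolerance = 0.07)
  expect_equal(unname(fb["Elongation"]), 1, tolerance = 0.02)
})
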