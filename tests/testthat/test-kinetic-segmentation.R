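make_two_voxel_volumes <- function(s0, s1, slast) {
  # tiny 3x3x3 volumes with the voxel of interest at the center
  v0 <- array(100, c(3, 3, 3)); v1 <- v0; vl <- v0
  v0[2, 2, 2] <- s0; v1[2, 2, 2] <- s1; vl[2, 2, 2] <- slast
  list(S0 = v0, S1 = v1, Slast = vl,
       mask = array(1L, c(3, 3, 3)))
}

test_that("the 50% enhancement gate is strict and guards S0 <= 0", {
  f <- make_two_voxel_volumes(100, 151, 151)
  m <- enhancement_mask(f$S0, f$S1, f$mask)
  expect_true(m[2, 2, 2])          # 51% > 50%
  f <- make_two_voxel_volumes(100, 150, 150)
  m <- enhancement_mask(f$S0, f$S1, f$mask)
  expect_false(m[2, 2, 2])         # exactly 50% excluded
  f <- make_two_voxel_volumes(0, 80, 80)
  m <- enhancement_mask(f$S0, f$S1, f$mask)
  expect_false(m[2, 2, 2])
  expect_equal(attr(m, "quality")$n_bad_baseline, 1L)
  expect_error(enhancement_mask(f$S0, f$S1, array(0L, c(3, 3, 3))),
               "empty")
})

test_that("late-change boundaries follow strict/closed conventions", {
  thr <- kinetic_thresholds()
  enh <- array(TRUE, c(1, 1, 1))
  classify1 <- function(s1, slast) {
    S1 <- array(s1, c(1, 1, 1)); SL <- array(slast, c(1, 1, 1))
    classify_enhancement_voxels(S1, SL, enh, thr)[1, 1, 1]
  }
  expect_equal(classify1(160, 140), 1L)   # r = -0.125 -> washout
  expect_equal(classify1(100, 110), 2L)   # r = +0.10 exactly -> plateau
  expect_equal(classify1(100, 112), 3L)   # r = +0.12 -> persistent
  expect_equal(classify1(100, 90), 2L)    # r = -0.10 exactly -> plateau
  expect_equal(classify1(100, 89.999), 1L)
})

test_that("noiseless phantoms are recovered voxel-for-voxel", {
  for (props in list(c(1, 0, 0), c(0.3, 0.3, 0.4), c(0.05, 0.05, 0.9))) {
    ph <- small_phantom(noise_sd = 0, seed = 17, proportions = props)
    sub <- segment_kinetics(ph$series, ph$mask)
    expect_identical(as.vector(sub), as.vector(ph$truth))
  }
})

test_that("the subregion map partitions the enhancement mask", {
  ph <- small_phantom(noise_sd = 4, seed = 23)
  m <- enhancement_mask(phase_pre(ph$series), phase_first(ph$series), ph$mask)
  sub <- segment_kinetics(ph$series, ph$mask)
  expect_identical(sub > 0L, as.vector(m) |> array(dim(m)))
  expect_true(all(sub[!m] == 0L))
  expect_true(all(sub[m] %in% 1:3))
})

test_that("classification is invariant to global intensity scaling", {
  ph <- small_phantom(noise_sd = 2, seed = 29)
  sub1 <- segment_kinetics(ph$series, ph$mask)
  scaled <- dce_series(lapply(ph$series$phases, function(v) 7.3 * v),
                       ph$series$spacing)
  sub2 <- segment_kinetics(scaled, ph$mask)
  expect_identical(sub1, sub2)
})

test_that("lowering the enhancement gate never shrinks the mask", {
  ph <- small_phantom(noise_sd = 30, seed = 31)
  gates <- c(0.8, 0.6, 0.5, 0.4, 0.3)
  prev <- NULL
  for (g in gates) {
    m <- enhancement_mask(phase_pre(ph$series), phase_first(ph$series),
                          ph$mask, kinetic_thresholds(g, 0.1))
    if (!is.null(prev)) expect_true(all(m[prev]))
    prev <- m
  }
})

test_that("largest_component keeps the biggest cluster, ties by centroid", {
  d <- c(30L, 30L, 12L)
  m <- array(0L, d)
  m[2:11, 2:11, 2:6] <- 1L          # 500 voxels
  m[20:25, 20:23, 2:6] <- 1L        # 120 voxels
  keep <- largest_component(m)
  expect_equal(sum(keep), 500L)
  expect_true(all(keep[2:11, 2:11, 2:6] == 1L))

  single <- array(0L, d); single[5:8, 5:8, 5:8] <- 1L
  expect_identical(largest_component(single), single)

  tie <- array(0L, d)
  tie[2:6, 2:5, 2:6] <- 1L          # 100 voxels, small centroid
  tie[20:24, 20:23, 2:6] <- 1L      # 100 voxels, large centroid
  expect_warning(keep2 <- largest_component(tie), "tie")
  expect_equal(sum(keep2), 100L)
  expect_true(all(keep2[2:6, 2:5, 2:6] == 1L))

  expect_error(largest_component(array(0L, d)), "empty")
})

test_that("6- vs 26-connectivity distinguishes diagonal touching", {
  m <- array(0L, c(6, 6, 6))
  m[1:2, 1:2, 1:2] <- 1L
  m[3, 3, 3] <- 1L                  # touches only diagonally
  c26 <- largest_component(m, connectivity = 26L)
  expect_equal(sum(c26), 9L)        # merged under 26-connectivity
  c6 <- largest_component(m, connectivity = 6L)
  expect_equal(sum(c6), 8L)         # split under 6-connectivity
})
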