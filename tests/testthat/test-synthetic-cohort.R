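test_that("voxel curve model hits its pinned endpoints", {
  wa <- curve_archetype("washout", baseline = 100, uptake_fraction = 0.6,
                        late_slope_fraction = -0.125)
  cv <- simulate_voxel_curve(wa, n_post_phases = 8, noise_sd = 0)
  expect_length(cv, 9L)
  expect_equal(cv[1], 100)
  expect_equal(cv[2], 160)
  expect_equal(cv[9], 140)
  # intermediate post phases are linear in phase index and monotone
  expect_equal(diff(cv[2:9]), rep((140 - 160) / 7, 7))

  pl <- curve_archetype("plateau", 100, 0.6, 0)
  cvp <- simulate_voxel_curve(pl, 8, 0)
  expect_equal(cvp[2], 160)
  expect_equal(cvp[9], 160)

  expect_error(curve_archetype("washout", baseline = -5),
               "baseline")
  expect_error(simulate_voxel_curve(wa, n_post_phases = 1), ">= 2")
})

test_that("seeded curves and phantoms are bitwise reproducible", {
  wa <- curve_archetype("washout", 100, 0.6, -0.125)
  c1 <- simulate_voxel_curve(wa, 8, noise_sd = 5, seed = 42)
  c2 <- simulate_voxel_curve(wa, 8, noise_sd = 5, seed = 42)
  expect_identical(c1, c2)

  sp <- phantom_spec(grid_shape = c(20L, 20L, 20L), semi_axes = c(7, 6, 6),
                     noise_sd = 2, seed = 9)
  p1 <- simulate_phantom(sp); p2 <- simulate_phantom(sp)
  expect_identical(p1$series$phases, p2$series$phases)
  expect_identical(p1$truth, p2$truth)

  cs <- cohort_spec(n_patients = 30, n_features = 20, seed = 5)
  expect_identical(simulate_feature_cohort(cs), simulate_feature_cohort(cs))
})

test_that("phantom ground truth respects the mixture and the mask", {
  # degenerate mixture: all washout inside, nothing labelled outside
  p <- simulate_phantom(phantom_spec(grid_shape = c(24L, 24L, 24L),
                                     semi_axes = c(8, 8, 8),
                                     class_proportions = c(1, 0, 0),
                                     noise_sd = 0, seed = 3))
  expect_setequal(unique(p$truth[p$mask == 1L]), 1L)
  expect_true(all(p$truth[p$mask == 0L] == 0L))

  # realized proportions near 1/3 each within binomial sampling error
  p3 <- simulate_phantom(phantom_spec(grid_shape = c(40L, 40L, 40L),
                                      semi_axes = c(14, 13, 12),
                                      class_proportions = rep(1 / 3, 3),
                                      noise_sd = 0, seed = 21))
  n <- sum(p3$mask)
  expect_gt(n, 3000)
  phat <- p3$class_counts / n
  half_ci <- 4 * sqrt((1 / 3) * (2 / 3) / n)   # ~4 sigma binomial band
  expect_true(all(abs(phat - 1 / 3) < half_ci))

  # background voxels never enhance above the gate
  s0 <- phase_pre(p3$series); s1 <- phase_first(p3$series)
  bg <- p3$mask == 0L
  expect_true(all((s1[bg] - s0[bg]) / s0[bg] <= 0.5))

  expect_error(simulate_phantom(phantom_spec(grid_shape = c(10L, 10L, 10L),
                                             semi_axes = c(9, 9, 9))),
               "exceeds the grid")
})

test_that("law of large numbers: realized proportions converge to the spec", {
  p <- simulate_phantom(phantom_spec(grid_shape = c(44L, 44L, 44L),
                                     semi_axes = c(17, 16, 15),
                                     class_proportions = c(0.25, 0.34, 0.41),
                                     noise_sd = 0, seed = 13))
  n <- sum(p$mask)
  expect_gt(n, 1e4)
  phat <- p$class_counts / n
  expect_true(all(abs(phat - c(0.25, 0.34, 0.41)) < 0.02))
})

test_that("lobulated masks stay connected and inside the grid", {
  sp <- phantom_spec(grid_shape = c(36L, 36L, 36L), semi_axes = c(11, 10, 9),
                     lobulation = 0.25, seed = 2)
  p <- simulate_phantom(sp)
  comp <- largest_component(p$mask)
  expect_identical(sum(comp), sum(p$mask))  # a single component
})

test_that("feature cohorts carry the stated effect and prevalence", {
  cs <- cohort_spec(n_patients = 400, prevalence = 0.5, feature_effect = 1.0,
                    n_features = 30, n_informative = 4, seed = 8)
  co <- simulate_feature_cohort(cs)
  expect_false(anyDuplicated(colnames(co$features)) > 0)
  expect_equal(mean(co$labels), 0.5, tolerance = 0.15)
  d <- colMeans(co$features[co$labels == 1, co$informative]) -
    colMeans(co$features[co$labels == 0, co$informative])
  expect_true(all(abs(d - 1.0) < 0.35))
  noise_d <- colMeans(co$features[co$labels == 1, 5:30]) -
    colMeans(co$features[co$labels == 0, 5:30])
  expect_true(all(abs(noise_d) < 0.5))
  expect_error(cohort_spec(n_features = 5, n_informative = 6),
               "n_informative")
})
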