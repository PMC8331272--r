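test_that("phantoms are seeded-deterministic with full label sets and 0-255 range", {
  cfg <- phantom_config(shape = c(16, 16, 16), n_regions = 5, seed = 4)
  p1 <- make_phantom(cfg)
  p2 <- make_phantom(cfg)
  expect_identical(unclass(p1$volume), unclass(p2$volume))
  expect_identical(unclass(p1$labels), unclass(p2$labels))

  expect_setequal(sort(unique(as.vector(p1$labels))), 0:5)
  expect_equal(range(p1$volume), c(0, 255))

  # different seed, different phantom
  p3 <- make_phantom(phantom_config(shape = c(16, 16, 16), seed = 5))
  expect_false(identical(unclass(p1$volume), unclass(p3$volume)))
})

test_that("smooth deformations respect amplitude and the fold-free guarantee", {
  sh <- c(12, 12, 12)
  u0 <- make_smooth_deformation(sh, deformation_config(amplitude = 0, seed = 1))
  expect_equal(max(abs(u0)), 0)
  expect_identical(folding_count(jacobian_determinant(u0)), 0L)

  u <- make_smooth_deformation(sh, deformation_config(amplitude = 2,
                                                      smoothness = 3, seed = 2))
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  expect_equal(max(mag), 2, tolerance = 1e-10)
  expect_identical(folding_count(jacobian_determinant(u)), 0L)

  # wild fields are allowed (and expected) to fold when permitted
  uw <- make_smooth_deformation(sh, deformation_config(amplitude = 8,
                                                       smoothness = 0.6,
                                                       allow_folding = TRUE,
                                                       seed = 3))
  expect_gt(folding_count(jacobian_determinant(uw)), 0L)

  # infeasible fold-free request errors after the retry cap
  expect_error(make_smooth_deformation(sh,
                 deformation_config(amplitude = 8, smoothness = 0.6,
                                    allow_folding = FALSE, seed = 4,
                                    max_retries = 3)),
               class = "mcdreg_infeasible_error")
})

test_that("pairs are self-consistent: S is T warped by the ground truth", {
  pcfg <- phantom_config(shape = c(16, 16, 16), seed = 6)
  dcfg <- deformation_config(amplitude = 2.5, smoothness = 3, seed = 7)
  pr <- make_pair(pcfg, dcfg)
  expect_identical(unclass(pr$S), unclass(warp(pr$T, pr$u_true)))
  expect_identical(unclass(pr$S_labels),
                   unclass(warp_labels(pr$T_labels, pr$u_true)))
  # misalignment was actually induced
  expect_lt(mean(dice_labels(pr$S_labels, pr$T_labels)$dice), 1)

  # zero deformation keeps the pair identical
  pr0 <- make_pair(pcfg, deformation_config(amplitude = 0, seed = 8))
  expect_identical(unclass(pr0$S), unclass(pr0$T))

  # reproducibility of the full tuple
  pr2 <- make_pair(pcfg, dcfg)
  expect_identical(unclass(pr$u_true), unclass(pr2$u_true))
  expect_identical(unclass(pr$S), unclass(pr2$S))
})

test_that("lesions are spherical, seeded, and leave the rest untouched", {
  v <- make_phantom(phantom_config(shape = c(16, 16, 16), seed = 9))$volume
  expect_identical(unclass(insert_lesion(v, radius = 0)), unclass(v))

  les <- insert_lesion(v, radius = 3, intensity = 255, seed = 10)
  les2 <- insert_lesion(v, radius = 3, intensity = 255, seed = 10)
  expect_identical(unclass(les), unclass(les2))

  changed <- which(unclass(les) != unclass(v))
  expect_gt(length(changed), 0)
  # changed voxels all lie within radius of their centroid (a sphere)
  coords <- arrayInd(changed, dim(v))
  centre <- colMeans(coords)
  d <- sqrt(rowSums(sweep(coords, 2, centre)^2))
  expect_lte(max(d), 3 + 1e-6)
  expect_true(all(unclass(les)[changed] == 255))

  expect_error(insert_lesion(v, radius = 10),
               class = "mcdreg_argument_error")
})

test_that("field inversion recovers the inverse of a smooth deformation", {
  sh <- c(12, 12, 12)
  u <- make_smooth_deformation(sh, deformation_config(amplitude = 2,
                                                      smoothness = 4, seed = 11))
  v <- invert_field(u)
  # composing u after v should be near the identity away from the boundary
  comp <- unclass(v)
  for (c0 in 1:3) {
    comp[, , , c0] <- comp[, , , c0] +
      unclass(warp(as_volume(array(u[, , , c0], sh)), v))
  }
  inner <- comp[4:9, 4:9, 4:9, ]
  expect_lt(mean(abs(inner)), 0.05)
  expect_lt(endpoint_error(u, u), 1e-12)
})
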