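test_that("cross-correlation is a squared NCC: bounds, symmetry, affine invariance", {
  v <- random_volume(c(4, 4, 4), seed = 11)
  s <- random_volume(c(4, 4, 4), seed = 12)
  expect_equal(cross_correlation(v, v), 1)
  expect_equal(cross_correlation(v, 2 * unclass(v) + 3), 1)
  expect_equal(cross_correlation(v, -0.5 * unclass(v) + 1), 1)
  cc <- cross_correlation(v, s)
  expect_gte(cc, 0); expect_lte(cc, 1)
  expect_equal(cc, cross_correlation(s, v))
  # affine rescaling of either argument leaves CC unchanged
  expect_equal(cross_correlation(3 * unclass(v) - 7, s), cc)
  expect_error(cross_correlation(v, array(1, dim = c(4, 4, 4))),
               class = "mcdreg_degenerate_error")
})

test_that("cross-correlation matches a scalar-accumulator oracle", {
  t4 <- as_volume(array(c(1, 2, 3, 4, 2, 1, 0, 3), dim = c(2, 2, 2)))
  s4 <- as_volume(array(c(1, 2, 3, 5, 2, 2, 0, 3), dim = c(2, 2, 2)))
  expect_equal(cross_correlation(t4, s4), oracle_cc(t4, s4), tolerance = 1e-12)
  for (seed in 1:3) {
    a <- random_volume(c(3, 3, 3), seed = seed)
    b <- random_volume(c(3, 3, 3), seed = seed + 50)
    expect_equal(cross_correlation(a, b), oracle_cc(a, b), tolerance = 1e-12)
  }
})

test_that("smoothness penalty vanishes for constant fields and matches a loop", {
  sh <- c(4, 4, 4)
  expect_equal(smoothness_R1(zero_field(sh)), 0)
  uc <- array(2.5, dim = c(sh, 3))
  expect_equal(smoothness_R1(as_displacement_field(uc)), 0)

  # unit ramp along d in component 1: forward diffs are 1 except the far slice
  u <- array(0, dim = c(sh, 3))
  u[, , , 1] <- coord_array(sh, 1)
  n_nonzero <- 3 * 4 * 4  # interior forward differences
  expect_equal(smoothness_R1(as_displacement_field(u)),
               n_nonzero / (3 * 64))
  expect_equal(smoothness_R1(as_displacement_field(u), reduction = "sum"),
               n_nonzero)
})

test_that("anti-folding penalty is the hinge sum of negative determinants", {
  sh <- c(5, 5, 5)
  expect_equal(antifold_R2(zero_field(sh)), 0)

  # uniform expansion: all determinants positive, no penalty
  u <- array(0, dim = c(sh, 3))
  for (i in 1:3) u[, , , i] <- 0.5 * coord_array(sh, i)
  expect_equal(antifold_R2(as_displacement_field(u)), 0)

  # reflection along d: interior det = -1 contributes 1 per voxel
  ur <- array(0, dim = c(sh, 3))
  ur[, , , 1] <- -2 * coord_array(sh, 1)
  jac <- unclass(jacobian_determinant(as_displacement_field(ur)))
  expect_equal(antifold_R2(as_displacement_field(ur)),
               sum(pmax(0, -jac)))
  expect_gte(antifold_R2(as_displacement_field(ur)),
             folding_count(jac) * min(abs(jac[jac < 0])))

  # random fields: equals sum(max(0, -det)) and is 0 iff no folding
  for (seed in 1:3) {
    uu <- random_field(sh, sd = 0.6, seed = seed)
    jj <- unclass(jacobian_determinant(uu))
    expect_equal(antifold_R2(uu), sum(pmax(0, -jj)), tolerance = 1e-12)
    expect_identical(antifold_R2(uu) == 0, folding_count(jj) == 0L)
  }
})

test_that("total loss vanishes for a perfectly aligned identity pair", {
  v <- random_volume(c(4, 4, 4), seed = 21)
  expect_equal(total_loss(v, v, zero_field(c(4, 4, 4)),
                          loss_weights(alpha = 1, beta = 1e-3)), 0)
})

test_that("total loss recomposes from its terms and is linear in beta", {
  S <- random_volume(c(5, 5, 5), seed = 31)
  T <- random_volume(c(5, 5, 5), seed = 32)
  u <- random_field(c(5, 5, 5), sd = 0.8, seed = 33)
  terms <- total_loss_terms(S, T, u, loss_weights(0.7, 2e-3))
  expect_equal(terms$total,
               terms$l_image + 0.7 * terms$r1 + 2e-3 * terms$r2)
  expect_equal(terms$l_image, 1 - cross_correlation(T, warp(S, u)))
  expect_equal(terms$r1, smoothness_R1(u))
  expect_equal(terms$r2, antifold_R2(u))
  # changing beta rescales only the R2 contribution
  t2 <- total_loss(S, T, u, loss_weights(0.7, 4e-3))
  expect_equal(t2 - terms$total, 2e-3 * terms$r2)
})

test_that("analytic loss gradient w.r.t. u passes a finite-difference check", {
  sh <- c(8, 8, 8)
  S <- random_volume(sh, seed = 41)
  T <- random_volume(sh, seed = 42)
  set.seed(43)
  u <- random_field(sh, sd = 0.45)
  w <- loss_weights(alpha = 1, beta = 1e-2)
  lg <- mcdreg:::loss_with_grad_u(S, T, u, w)
  expect_equal(lg$total, total_loss(S, T, u, w), tolerance = 1e-12)
  eps <- 1e-5
  idx <- sample(length(unclass(u)), 25)
  for (i in idx) {
    up <- unclass(u); up[i] <- up[i] + eps
    um <- unclass(u); um[i] <- um[i] - eps
    num <- (total_loss(S, T, as_displacement_field(up), w) -
              total_loss(S, T, as_displacement_field(um), w)) / (2 * eps)
    expect_equal(lg$grad_u[i], num, tolerance = 1e-3)
  }
})

test_that("optimizer weight decay changes kernel updates but not biases", {
  params <- list(layer = list(W = matrix(0.5, 2, 2), b = c(0.5, 0.5)))
  # loss gradient pulls W up; decay (wd * W) pushes it back down and flips
  # the sign of the effective first-step direction
  grads <- list(layer = list(W = matrix(-0.1, 2, 2), b = c(-0.1, -0.1)))
  st <- mcdreg:::adam_init(params)
  plain <- mcdreg:::adam_step(params, grads, st, lr = 1e-2, wd = 0)
  decayed <- mcdreg:::adam_step(params, grads, st, lr = 1e-2, wd = 1)
  expect_true(all(plain$params$layer$W > 0.5))
  expect_true(all(decayed$params$layer$W < 0.5))
  # biases never receive decay
  expect_equal(plain$params$layer$b, decayed$params$layer$b)
})
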