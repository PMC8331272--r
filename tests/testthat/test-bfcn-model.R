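test_that("group normalization standardizes groups and applies the affine", {
  # constant input: zero-variance group maps to ~0 (damped by eps)
  x <- array(3, dim = c(2, 2, 2, 4))
  y <- group_normalize(x, G = 2)
  expect_equal(max(abs(y)), 0)

  # a group holding values {1, 3} equally: mu = 2, sigma -> 1, outputs {-1, 1}
  x2 <- array(rep(c(1, 3), each = 4), dim = c(2, 2, 2, 1))
  y2 <- group_normalize(x2, G = 1, eps = 1e-12)
  expect_equal(sort(unique(round(as.vector(y2), 6))), c(-1, 1))

  # gamma = 0 collapses everything onto beta
  x3 <- array(rnorm(32), dim = c(2, 2, 2, 4))
  y3 <- group_normalize(x3, G = 2, gamma = rep(0, 4), beta = rep(7, 4))
  expect_equal(as.vector(y3), rep(7, 32))

  expect_error(group_normalize(x3, G = 3), class = "mcdreg_config_error")
})

test_that("group normalization matches the explicit per-group oracle", {
  set.seed(71)
  for (rep in 1:3) {
    x <- array(rnorm(3 * 3 * 3 * 6, sd = 4), dim = c(3, 3, 3, 6))
    gamma <- rnorm(6); beta <- rnorm(6)
    got <- group_normalize(x, G = 3, gamma = gamma, beta = beta, eps = 1e-5)
    expect_equal(got, oracle_group_norm(x, 3, gamma, beta, 1e-5),
                 tolerance = 1e-6)
  }
})

test_that("normalized groups have mean 0 and standard deviation 1", {
  set.seed(72)
  x <- array(rnorm(4 * 4 * 4 * 8, sd = 10), dim = c(4, 4, 4, 8))
  y <- group_normalize(x, G = 4)
  cg <- 2
  for (g in 1:4) {
    vals <- y[, , , ((g - 1) * cg + 1):(g * cg)]
    expect_lt(abs(mean(vals)), 1e-4)
    expect_lt(abs(sqrt(mean((vals - mean(vals))^2)) - 1), 1e-3)
  }
})

test_that("network output preserves resolution and forward modes behave", {
  cfg <- network_config(input_shape = c(16, 16, 16), base_channels = 4,
                        n_levels = 3, n_groups = 2)
  net <- build_bfcnm(cfg, seed = 5)
  S <- random_volume(c(16, 16, 16), seed = 61)
  T <- random_volume(c(16, 16, 16), seed = 62)

  u <- predict_field(net, S, T)
  expect_identical(dim(u), c(16L, 16L, 16L, 3L))
  expect_true(all(is.finite(u)))

  # deterministic forward is a pure function
  expect_identical(unclass(predict_field(net, S, T)), unclass(u))

  # seeded stochastic passes reproduce; different seeds differ
  s1 <- predict_field(net, S, T, stochastic = TRUE, seed = 11)
  s2 <- predict_field(net, S, T, stochastic = TRUE, seed = 11)
  s3 <- predict_field(net, S, T, stochastic = TRUE, seed = 12)
  expect_identical(unclass(s1), unclass(s2))
  expect_false(identical(unclass(s1), unclass(s3)))

  expect_error(predict_field(net, random_volume(c(8, 8, 8), seed = 1), T),
               class = "mcdreg_shape_error")
})

test_that("network size is configuration-driven and builds reproducibly", {
  cfg <- network_config(input_shape = c(8, 8, 8), base_channels = 4,
                        n_levels = 2, n_groups = 2)
  n1 <- build_bfcnm(cfg, seed = 3)
  n2 <- build_bfcnm(cfg, seed = 3)
  expect_identical(n1$params, n2$params)
  expect_gt(n_parameters(n1), 0)

  big <- build_bfcnm(network_config(input_shape = c(8, 8, 8),
                                    base_channels = 8, n_levels = 2,
                                    n_groups = 2), seed = 3)
  expect_gt(n_parameters(big), n_parameters(n1))

  expect_error(network_config(input_shape = c(8, 8, 8), n_levels = 3),
               class = "mcdreg_config_error")
  expect_error(network_config(input_shape = c(16, 16, 16), base_channels = 5,
                              n_levels = 3, n_groups = 4),
               class = "mcdreg_config_error")
})

test_that("network parameter gradients agree with finite differences", {
  cfg <- network_config(input_shape = c(8, 8, 8), base_channels = 2,
                        n_levels = 2, n_groups = 1,
                        inception_kernels = c(3, 5))
  net <- build_bfcnm(cfg, seed = 13)
  S <- random_volume(c(8, 8, 8), seed = 63)
  T <- random_volume(c(8, 8, 8), seed = 64)
  w <- loss_weights(1, 1e-3)
  fwd <- mcdreg:::bfcnm_forward_cache(net, S, T, stochastic = FALSE)
  lg <- mcdreg:::loss_with_grad_u(S, T, as_displacement_field(fwd$u), w)
  grads <- mcdreg:::bfcnm_backward(net, fwd$cache, lg$grad_u)
  lossfun <- function(nn) {
    r <- mcdreg:::bfcnm_forward_cache(nn, S, T, stochastic = FALSE)
    total_loss(S, T, as_displacement_field(r$u), w)
  }
  eps <- 1e-4
  set.seed(65)
  for (nm in c("inc3", "enc1", "dec2_tc", "dec1_conv", "dec2_gn", "out")) {
    for (fld in names(net$params[[nm]])) {
      arr <- net$params[[nm]][[fld]]
      for (i in sample(length(arr), min(2, length(arr)))) {
        np <- net; np$params[[nm]][[fld]][i] <- arr[i] + eps
        nm2 <- net; nm2$params[[nm]][[fld]][i] <- arr[i] - eps
        num <- (lossfun(np) - lossfun(nm2)) / (2 * eps)
        ana <- grads[[nm]][[fld]][i]
        expect_equal(ana, num, tolerance = 5e-2,
                     label = sprintf("grad %s$%s[%d]", nm, fld, i))
      }
    }
  }
})
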