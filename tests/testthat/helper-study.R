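# Desk-scale study fixture shared by the acceptance tests: 16^3 phantom
# pairs with strong coarse ground-truth deformations, a 500-iteration
# training run (lr 1e-4, alpha 1, beta 1e-4), and a lighter beta contrast.
# Training happens once per session; all consumers reuse the cache.

.study_cache <- new.env(parent = emptyenv())

study_shape <- c(16L, 16L, 16L)

study_pair <- function(phantom_seed, deform_seed) {
  make_pair(phantom_config(shape = study_shape, n_regions = 3,
                           seed = phantom_seed),
            deformation_config(amplitude = 5, smoothness = 5,
                               seed = deform_seed))
}

study_fixture <- function(master_seed = 1L) {
  key <- as.character(master_seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  seeds <- mcdreg:::derive_seeds(master_seed, 80L)
  train_pairs <- lapply(1:10, function(i) study_pair(seeds[i], seeds[10 + i]))
  test_pairs <- lapply(1:6, function(i) study_pair(seeds[20 + i],
                                                   seeds[30 + i]))
  net <- build_bfcnm(network_config(input_shape = study_shape,
                                    base_channels = 16, n_levels = 3,
                                    n_groups = 4), seed = seeds[41])
  fit <- train_bfcnm(net, train_pairs,
                     train_config(learning_rate = 1e-4, epochs = 50,
                                  loss_weights = loss_weights(1, 1e-4),
                                  seed = seeds[42]))
  fx <- list(seeds = seeds, train_pairs = train_pairs,
             test_pairs = test_pairs, fit = fit)
  .study_cache[[key]] <- fx
  fx
}

# Held-out registration metrics through the MC mean field.
study_eval <- function(fx, M = 16L) {
  key <- paste0("eval_", fx$seeds[1])
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  rows <- lapply(seq_along(fx$test_pairs), function(i) {
    p <- fx$test_pairs[[i]]
    sm <- mc_summary(fx$fit, p$S, p$T, M = M, seed = fx$seeds[50 + i])
    tgt <- invert_field(p$u_true)
    tibble::tibble(
      pair = i,
      dice = mean(dice_labels(warp_labels(p$S_labels, sm$mu), p$T_labels)$dice),
      dice0 = mean(dice_labels(p$S_labels, p$T_labels)$dice),
      epe = endpoint_error(sm$mu, tgt),
      epe0 = endpoint_error(zero_field(study_shape), tgt),
      folds = folding_count(jacobian_determinant(sm$mu), mask = p$T_labels))
  })
  out <- dplyr::bind_rows(rows)
  .study_cache[[key]] <- out
  out
}

# Lighter beta-contrast training for the anti-folding trend.
study_beta_model <- function(fx, beta) {
  key <- paste0("beta_", fx$seeds[1], "_", beta)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  net <- build_bfcnm(network_config(input_shape = study_shape,
                                    base_channels = 8, n_levels = 3,
                                    n_groups = 4), seed = fx$seeds[43])
  fit <- train_bfcnm(net, fx$train_pairs[1:6],
                     train_config(learning_rate = 1e-4, epochs = 34,
                                  loss_weights = loss_weights(1, beta),
                                  seed = fx$seeds[44]))
  .study_cache[[key]] <- fit
  fit
}

study_beta_folds <- function(fx, beta) {
  fit <- study_beta_model(fx, beta)
  sum(vapply(fx$test_pairs, function(p) {
    u <- register_pair(fit, p$S, p$T)$field
    folding_count(jacobian_determinant(u), mask = p$T_labels)
  }, numeric(1)))
}

# Mean normalized uncertainty over clean vs lesioned held-out sources,
# averaged over the nonbackground evaluation domain. The lesion is dark
# (fluid-like) and centred in tissue — the strongest departure from the
# bright-core training distribution.
study_lesion_centre <- function(shape, seed) {
  with_seed(seed, round((shape + 1) / 2) + sample(-1:1, 3, replace = TRUE))
}

study_ood <- function(fx, M = 16L, radius = 4, intensity = 0) {
  key <- paste0("ood_", fx$seeds[1])
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  sums_clean <- lapply(seq_along(fx$test_pairs), function(i) {
    p <- fx$test_pairs[[i]]
    mc_summary(fx$fit, p$S, p$T, M = M, seed = fx$seeds[50 + i])
  })
  sums_les <- lapply(seq_along(fx$test_pairs), function(i) {
    p <- fx$test_pairs[[i]]
    les <- insert_lesion(p$S, radius = radius, intensity = intensity,
                         centre = study_lesion_centre(study_shape,
                                                      fx$seeds[60 + i]))
    mc_summary(fx$fit, les, p$T, M = M, seed = fx$seeds[70 + i])
  })
  stats <- uncertainty_stats(c(sums_clean, sums_les))
  fg_mean <- function(s, p) {
    mean(uncertainty_map(s, stats)[unclass(p$T_labels) > 0])
  }
  out <- list(
    clean = mean(mapply(fg_mean, sums_clean, fx$test_pairs)),
    lesioned = mean(mapply(fg_mean, sums_les, fx$test_pairs)),
    stats = stats, sums_clean = sums_clean)
  .study_cache[[key]] <- out
  out
}
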