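#' Monte Carlo Dropout samples of the displacement field
#'
#' Runs `M` stochastic forward passes with dropout kept active, each with
#' its own Bernoulli masks; sample `i` is reproducible from `(seed, i)`.
#' The spread of these samples estimates the epistemic (model) uncertainty
#' of the registration.
#'
#' @param net A `bfcnm` network (or `bfcnm_fit`).
#' @param S,T Source and target `volume`s.
#' @param M Number of samples (default 48).
#' @param seed Integer master seed.
#' @return List of `M` `displacement_field`s.
#' @export
mc_sample <- function(net, S, T, M = 48, seed = 1L) {
  if (inherits(net, "bfcnm_fit")) net <- net$network
  if (M < 1) stop_mcdreg("M must be at least 1", "mcdreg_argument_error")
  seeds <- derive_seeds(seed, M)
  lapply(seq_len(M), function(i) {
    predict_field(net, S, T, stochastic = TRUE, seed = seeds[i])
  })
}

#' Mean of Monte Carlo displacement samples
#'
#' Voxelwise, componentwise arithmetic mean of the sampled fields; this
#' mean field is the one used for the final registration (warping the
#' source and its labels).
#'
#' @param samples Non-empty list of equally shaped `displacement_field`s.
#' @return A `displacement_field`.
#' @export
mc_mean <- function(samples) {
  if (length(samples) < 1) {
    stop_mcdreg("mc_mean needs at least one sample", "mcdreg_argument_error")
  }
  acc <- unclass(samples[[1]])
  if (length(samples) > 1) {
    for (i in 2:length(samples)) acc <- acc + unclass(samples[[i]])
  }
  as_displacement_field(acc / length(samples))
}

#' Per-voxel standard deviation of Monte Carlo samples
#'
#' Componentwise sample standard deviation (denominator `M - 1`) of the
#' sampled displacement fields around their mean; the per-voxel uncertainty
#' of the registration.
#'
#' @param samples List of at least two `displacement_field`s.
#' @param mu Optional precomputed [mc_mean()] of the samples.
#' @return A (D, H, W, 3) array of standard deviations.
#' @export
mc_std <- function(samples, mu = NULL) {
  M <- length(samples)
  if (M < 2) {
    stop_mcdreg("mc_std needs at least two samples (M - 1 denominator)",
                "mcdreg_argument_error")
  }
  if (is.null(mu)) mu <- mc_mean(samples)
  mu <- unclass(mu)
  acc <- array(0, dim = dim(mu))
  for (s in samples) {
    d <- unclass(s) - mu
    acc <- acc + d * d
  }
  sqrt(acc / (M - 1))
}

#' Summarize Monte Carlo Dropout inference for one pair
#'
#' Draws `M` stochastic displacement fields and reduces them to the mean
#' field, the componentwise standard deviation, and a per-voxel scalar
#' uncertainty (Euclidean norm of the three component s.d.s).
#'
#' @inheritParams mc_sample
#' @return An `mc_summary`: list with `mu` (`displacement_field`),
#'   `sigma_vec` ((D,H,W,3) array), `sigma` (3D scalar array), `M`, `seed`.
#' @export
mc_summary <- function(net, S, T, M = 48, seed = 1L) {
  samples <- mc_sample(net, S, T, M = M, seed = seed)
  mu <- mc_mean(samples)
  sv <- mc_std(samples, mu)
  structure(list(mu = mu, sigma_vec = sv, sigma = sigma_scalar(sv),
                 M = M, seed = seed),
            class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("<mc_summary> M = %d samples, mean |mu| %.3g, sigma range [%.3g, %.3g]\n",
              x$M, mean(sqrt(x$mu[, , , 1]^2 + x$mu[, , , 2]^2 +
                               x$mu[, , , 3]^2)),
              min(x$sigma), max(x$sigma)))
  invisible(x)
}

# Collapse the 3-component sigma to a rotation-invariant per-voxel scalar.
sigma_scalar <- function(sigma_vec, method = c("norm", "mean")) {
  method <- match.arg(method)
  if (method == "norm") {
    sqrt(sigma_vec[, , , 1]^2 + sigma_vec[, , , 2]^2 + sigma_vec[, , , 3]^2)
  } else {
    (sigma_vec[, , , 1] + sigma_vec[, , , 2] + sigma_vec[, , , 3]) / 3
  }
}

#' Normalization statistics for uncertainty maps
#'
#' Thresholds on the uncertainty map live on a common \[0, 1\] scale, so
#' scalar uncertainties are min-max normalized by the minimum and maximum
#' over the *entire* evaluation set, not per volume. Compute the statistics
#' once over all summaries, persist them, and pass them to
#' [uncertainty_map()].
#'
#' @param sigmas List of 3D scalar uncertainty arrays (or `mc_summary`
#'   objects).
#' @return List with `min` and `max`.
#' @export
uncertainty_stats <- function(sigmas) {
  vals <- lapply(sigmas, function(s) {
    if (inherits(s, "mc_summary")) s$sigma else s
  })
  list(min = min(vapply(vals, min, numeric(1))),
       max = max(vapply(vals, max, numeric(1))))
}

#' Normalized per-voxel uncertainty map
#'
#' Collapses the componentwise standard deviations to a scalar per voxel
#' (Euclidean norm by default) and min-max normalizes it with set-wide
#' statistics so values are comparable to thresholds in \[0, 1\].
#'
#' @param sigma_vec A (D,H,W,3) array from [mc_std()], an `mc_summary`, or
#'   an already scalar 3D array.
#' @param stats Normalization statistics from [uncertainty_stats()].
#' @param method Scalar collapse: `"norm"` (Euclidean, default) or
#'   `"mean"` of components.
#' @return 3D array of uncertainties in \[0, 1\].
#' @export
uncertainty_map <- function(sigma_vec, stats, method = c("norm", "mean")) {
  method <- match.arg(method)
  s <- if (inherits(sigma_vec, "mc_summary")) {
    sigma_vec$sigma
  } else if (length(dim(sigma_vec)) == 4L) {
    sigma_scalar(sigma_vec, method)
  } else {
    sigma_vec
  }
  check_finite(s, "uncertainty")
  if (!is.finite(stats$max - stats$min) || stats$max <= stats$min) {
    stop_mcdreg("degenerate normalization: max <= min over the evaluation set",
                "mcdreg_degenerate_error")
  }
  pmin(pmax((s - stats$min) / (stats$max - stats$min), 0), 1)
}
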