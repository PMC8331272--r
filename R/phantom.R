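# Separable Gaussian smoothing of a 3D array; the 1-D kernel is truncated
# at 3 sigma and renormalized row-wise, so boundary voxels average over the
# in-bounds support only.
gaussian_smooth_3d <- function(x, sigma) {
  stopifnot(sigma > 0)
  smooth_axis <- function(x, axis) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    xp <- aperm(x, perm)
    n <- dim(xp)[1]
    r <- min(n - 1L, ceiling(3 * sigma))
    K <- outer(seq_len(n), seq_len(n), function(i, j) {
      w <- exp(-((i - j)^2) / (2 * sigma^2))
      w * (abs(i - j) <= r)
    })
    K <- K / rowSums(K)
    d <- dim(xp)
    dim(xp) <- c(n, prod(d[-1]))
    yp <- K %*% xp
    dim(yp) <- d
    aperm(yp, order(perm))
  }
  for (ax in 1:3) x <- smooth_axis(x, ax)
  x
}

#' Phantom generator configuration
#'
#' Describes a labeled synthetic head-like phantom: nested smooth "blobby"
#' shells with distinct mean intensities on a dark background, the stand-in
#' for an intensity-normalized anatomical volume with several labeled
#' regions.
#'
#' @param shape Grid shape (default 32^3).
#' @param n_regions Number of labeled regions (default 5, the number of
#'   cortical regions typically scored).
#' @param intensity_noise_sd Additive Gaussian intensity noise s.d. on the
#'   0-255 scale (default 6).
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(shape = c(32, 32, 32), n_regions = 5,
                           intensity_noise_sd = 6, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 8L), n_regions >= 1,
            intensity_noise_sd >= 0)
  structure(list(shape = shape, n_regions = as.integer(n_regions),
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Ground-truth deformation configuration
#'
#' A smooth random displacement field: componentwise white noise smoothed
#' by a Gaussian of scale `smoothness` and rescaled so the largest voxel
#' displacement equals `amplitude`. With `allow_folding = FALSE` the draw
#' is rejected (and redrawn, up to `max_retries` times) until the field has
#' no negative Jacobian determinant, so generated ground truths are
#' guaranteed orientation-preserving.
#'
#' @param amplitude Maximum displacement magnitude in voxels (default 2.5).
#' @param smoothness Gaussian smoothing scale in voxels (default 4).
#' @param allow_folding Accept fields with folded voxels? Default `FALSE`.
#' @param seed Integer seed.
#' @param max_retries Rejection-loop cap (default 20).
#' @return A `deformation_config`.
#' @export
deformation_config <- function(amplitude = 2.5, smoothness = 4,
                               allow_folding = FALSE, seed = 1L,
                               max_retries = 20L) {
  stopifnot(amplitude >= 0, smoothness > 0, max_retries >= 1)
  structure(list(amplitude = amplitude, smoothness = smoothness,
                 allow_folding = allow_folding, seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "deformation_config")
}

#' Generate a labeled synthetic phantom
#'
#' Builds `n_regions` nested shells around the grid centre whose boundaries
#' are perturbed by a smooth random field (so regions are blobby, not
#' spherical), assigns each region a distinct mean intensity plus Gaussian
#' noise, and min-max normalizes intensities to 0-255. Label 0 is
#' background; labels 1 (innermost) to `n_regions` index the shells.
#'
#' @param cfg A [phantom_config()].
#' @return List with `volume` (a `volume`) and `labels` (a `label_volume`).
#' @export
make_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    sh <- cfg$shape
    n <- cfg$n_regions
    ax <- function(k) (seq_len(sh[k]) - 1 - (sh[k] - 1) / 2) / (0.42 * sh[k])
    cd <- array(rep(ax(1), times = sh[2] * sh[3]), dim = sh)
    ch <- array(rep(rep(ax(2), each = sh[1]), times = sh[3]), dim = sh)
    cw <- array(rep(ax(3), each = sh[1] * sh[2]), dim = sh)
    rr <- sqrt(cd^2 + ch^2 + cw^2)
    pert <- gaussian_smooth_3d(array(rnorm(prod(sh)), dim = sh),
                               sigma = min(sh) / 8)
    pert <- pert / max(sd(pert), 1e-12) * 0.12
    s <- rr + pert
    cuts <- 0.95 * (seq_len(n) / n)^(2 / 3)
    lab <- array(0L, dim = sh)
    for (k in n:1) lab[s < cuts[k]] <- k
    # distinct mean intensities per shell on a dark background; the
    # innermost region is brightest, as in T1-weighted anatomy
    levels <- c(0, seq(230, 60, length.out = n))
    img <- levels[lab + 1L] + rnorm(prod(sh), sd = cfg$intensity_noise_sd)
    dim(img) <- sh
    list(volume = normalize_intensity(as_volume(img)),
         labels = as_label_volume(lab))
  })
}

#' Generate a smooth random displacement field
#'
#' @param shape Grid shape (D, H, W).
#' @param cfg A [deformation_config()].
#' @return A `displacement_field`; with `allow_folding = FALSE` it is
#'   guaranteed fold-free (`folding_count` of its Jacobian is 0).
#' @export
make_smooth_deformation <- function(shape, cfg = deformation_config()) {
  stopifnot(inherits(cfg, "deformation_config"))
  shape <- as.integer(shape)
  if (cfg$amplitude == 0) return(zero_field(shape))
  seeds <- derive_seeds(cfg$seed, cfg$max_retries)
  for (attempt in seq_len(cfg$max_retries)) {
    u <- with_seed(seeds[attempt], {
      u <- array(0, dim = c(shape, 3L))
      for (comp in 1:3) {
        u[, , , comp] <- gaussian_smooth_3d(
          array(rnorm(prod(shape)), dim = shape), sigma = cfg$smoothness)
      }
      mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
      u * (cfg$amplitude / max(mag))
    })
    u <- as_displacement_field(u)
    if (cfg$allow_folding ||
        folding_count(jacobian_determinant(u)) == 0) {
      return(u)
    }
  }
  stop_mcdreg(sprintf(
    "could not draw a fold-free field in %d attempts; lower amplitude or raise smoothness",
    cfg$max_retries), "mcdreg_infeasible_error")
}

#' Generate a registration pair with known ground truth
#'
#' Draws a phantom as the target `T`, a smooth ground-truth field
#' `u_true`, and defines the source as `S = warp(T, u_true)` (labels warped
#' nearest-neighbour). The network's task — predict a field aligning `S`
#' to `T` — then has a well-defined target: the inverse of `u_true`
#' (see [invert_field()]), which the unsupervised method never sees.
#'
#' @param phantom_cfg A [phantom_config()].
#' @param deform_cfg A [deformation_config()].
#' @return List with `S`, `T` (`volume`s), `S_labels`, `T_labels`
#'   (`label_volume`s), and `u_true` (`displacement_field`).
#' @export
make_pair <- function(phantom_cfg = phantom_config(),
                      deform_cfg = deformation_config()) {
  ph <- make_phantom(phantom_cfg)
  u_true <- make_smooth_deformation(phantom_cfg$shape, deform_cfg)
  list(S = warp(ph$volume, u_true),
       T = ph$volume,
       S_labels = warp_labels(ph$labels, u_true),
       T_labels = ph$labels,
       u_true = u_true)
}

#' Insert a spherical lesion into a volume
#'
#' Emulates an out-of-distribution abnormality (tumour-like bright or dark
#' blob) by overwriting all voxels within `radius` of a seeded random
#' interior centre with a fixed intensity. Used to test whether Monte
#' Carlo Dropout uncertainty rises on abnormal inputs.
#'
#' @param v A `volume`.
#' @param radius Sphere radius in voxels (0 returns the volume unchanged).
#' @param intensity Intensity written inside the sphere (default 255).
#' @param seed Integer seed for the centre location.
#' @param centre Optional 1-based centre coordinates; default draws a
#'   seeded random interior location. Place lesions inside tissue (e.g.
#'   near the volume centre) when emulating pathology — a dark lesion in
#'   dark background is not an anomaly.
#' @return The lesioned `volume`.
#' @export
insert_lesion <- function(v, radius = 3, intensity = 255, seed = 1L,
                          centre = NULL) {
  v <- as_volume(v)
  if (radius == 0) return(v)
  sh <- dim(v)
  if (any(2 * radius + 1 > sh)) {
    stop_mcdreg("lesion radius does not fit inside the volume",
                "mcdreg_argument_error")
  }
  if (is.null(centre)) {
    centre <- with_seed(seed, vapply(1:3, function(k) {
      lo <- ceiling(radius) + 1
      hi <- sh[k] - ceiling(radius)
      if (hi < lo) stop_mcdreg("lesion radius does not fit inside the volume",
                               "mcdreg_argument_error")
      sample(lo:hi, 1)
    }, numeric(1)))
  } else {
    stopifnot(length(centre) == 3)
  }
  cd <- array(rep(seq_len(sh[1]), times = sh[2] * sh[3]), dim = sh)
  ch <- array(rep(rep(seq_len(sh[2]), each = sh[1]), times = sh[3]), dim = sh)
  cw <- array(rep(seq_len(sh[3]), each = sh[1] * sh[2]), dim = sh)
  mask <- (cd - centre[1])^2 + (ch - centre[2])^2 + (cw - centre[3])^2 <=
    radius^2
  out <- unclass(v)
  out[mask] <- intensity
  as_volume(out, spacing = attr(v, "spacing"))
}
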