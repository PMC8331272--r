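# Minimal 3D convolutional layer engine.
#
# Feature grids are stored as matrices (N_voxels x C) with the voxel axis in
# (D, H, W) column-major order. Convolutions are evaluated by im2col: gather
# all k^3 input patches into an (N_out x k^3*Cin) matrix and multiply by the
# flattened kernel, so the heavy lifting is one BLAS matmul per layer.
# Zero padding of (k-1)/2 keeps stride-1 convolutions shape-preserving;
# stride-2 convolutions emit ceil(n/2) voxels per axis.

conv_out_dim <- function(n, stride) as.integer(floor((n - 1) / stride) + 1L)

# Gather-index table for one (input shape, kernel, stride) combination:
# an (N_out x k^3) integer matrix of 1-based indices into the input grid
# augmented with a leading zero row (index 1 = zero padding).
.conv_cache <- new.env(parent = emptyenv())

conv_index_map <- function(in_shape, k, stride) {
  key <- paste(c(in_shape, k, stride), collapse = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  D <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  p <- (k - 1L) %/% 2L
  Do <- conv_out_dim(D, stride); Ho <- conv_out_dim(H, stride)
  Wo <- conv_out_dim(W, stride)
  base_d <- (0:(Do - 1L)) * stride - p
  base_h <- (0:(Ho - 1L)) * stride - p
  base_w <- (0:(Wo - 1L)) * stride - p
  n_out <- Do * Ho * Wo
  idx <- matrix(1L, nrow = n_out, ncol = k^3)
  col <- 0L
  for (c_off in 0:(k - 1L)) {
    iw <- base_w + c_off
    vw <- iw >= 0L & iw < W
    for (b_off in 0:(k - 1L)) {
      ih <- base_h + b_off
      vh <- ih >= 0L & ih < H
      for (a_off in 0:(k - 1L)) {
        col <- col + 1L
        id <- base_d + a_off
        vd <- id >= 0L & id < D
        gd <- rep(id, times = Ho * Wo)
        gh <- rep(rep(ih, each = Do), times = Wo)
        gw <- rep(iw, each = Do * Ho)
        ok <- rep(vd, times = Ho * Wo) &
          rep(rep(vh, each = Do), times = Wo) &
          rep(vw, each = Do * Ho)
        lin <- 2L + gd + D * (gh + H * gw)  # +1 zero row, +1 one-based
        lin[!ok] <- 1L
        idx[, col] <- lin
      }
    }
  }
  res <- list(idx = idx, out_shape = c(Do, Ho, Wo), n_out = n_out,
              in_shape = in_shape, k = k)
  .conv_cache[[key]] <- res
  res
}

# x: (N_in x Cin) feature matrix -> (N_out x k^3*Cin) patch matrix.
im2col <- function(x, map) {
  cin <- ncol(x)
  aug <- rbind(0, x)
  pat <- aug[as.vector(map$idx), , drop = FALSE]
  dim(pat) <- c(map$n_out, map$k^3 * cin)
  pat
}

# Adjoint of im2col: scatter-add patch gradients back onto the input grid.
col2im <- function(dpat, map, cin) {
  dim(dpat) <- c(map$n_out * map$k^3, cin)
  agg <- rowsum(dpat, group = as.vector(map$idx))
  dx <- matrix(0, nrow = prod(map$in_shape), ncol = cin)
  rows <- as.integer(rownames(agg))
  keep <- rows > 1L
  dx[rows[keep] - 1L, ] <- agg[keep, , drop = FALSE]
  dx
}

init_conv <- function(k, cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (k^3 * cin))
  list(W = matrix(rnorm(k^3 * cin * cout, sd = sd), nrow = k^3 * cin),
       b = numeric(cout))
}

conv_forward <- function(x, par, map) {
  pat <- im2col(x, map)
  y <- pat %*% par$W
  y <- sweep(y, 2, par$b, `+`)
  list(y = y, cache = list(pat = pat))
}

conv_backward <- function(dy, x_cache, par, map, need_dx = TRUE) {
  dW <- crossprod(x_cache$pat, dy)
  db <- colSums(dy)
  dx <- NULL
  if (need_dx) {
    dpat <- tcrossprod(dy, par$W)
    cin <- nrow(par$W) / map$k^3
    dx <- col2im(dpat, map, cin)
  }
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution = adjoint of a strided convolution. `map` is the
# index table of the matching forward convolution whose *input* is this
# layer's output grid. Weights: (k^3*Cout x Cin); bias per output channel.
convt_forward <- function(x, par, map) {
  dpat <- tcrossprod(x, par$W)            # (N_small x k^3*Cout)
  cout <- nrow(par$W) / map$k^3
  y <- col2im(dpat, map, cout)            # (N_big x Cout)
  y <- sweep(y, 2, par$b, `+`)
  list(y = y, cache = list(x = x))
}

convt_backward <- function(dy, cache, par, map) {
  pat <- im2col(dy, map)                  # (N_small x k^3*Cout)
  dx <- pat %*% par$W
  dW <- crossprod(pat, cache$x)
  db <- colSums(dy)
  list(dx = dx, dW = dW, db = db)
}

init_prelu <- function(c) list(a = rep(0.25, c))

prelu_forward <- function(x, par) {
  neg <- pmin(x, 0)
  y <- pmax(x, 0) + sweep(neg, 2, par$a, `*`)
  list(y = y, cache = list(x = x, neg = neg))
}

prelu_backward <- function(dy, cache, par) {
  pos <- cache$x > 0
  slope <- matrix(par$a, nrow = nrow(dy), ncol = ncol(dy), byrow = TRUE)
  dx <- dy * ifelse(pos, 1, slope)
  da <- colSums(dy * cache$neg)
  list(dx = dx, da = da)
}

init_gn <- function(c) list(gamma = rep(1, c), beta = rep(0, c))

#' Group normalization of a feature grid
#'
#' Splits the channel axis into `G` contiguous groups; within each group all
#' channels and all spatial voxels are pooled to compute a mean and standard
#' deviation (`sigma = sqrt(var + eps)`), features are standardized by them,
#' and a learned per-channel affine `y = gamma * xhat + beta` is applied.
#' Unlike batch normalization the statistics do not depend on the batch, so
#' the layer behaves identically at batch size 1.
#'
#' @param x Feature array `(D, H, W, C)` or matrix `(N x C)`.
#' @param G Number of channel groups; must divide `C`.
#' @param gamma,beta Per-channel scale and shift (defaults 1 and 0).
#' @param eps Variance-stabilizing constant under the square root
#'   (default 1e-5).
#' @return Normalized features, same shape as `x`.
#' @export
group_normalize <- function(x, G, gamma = NULL, beta = NULL, eps = 1e-5) {
  shape <- dim(x)
  if (length(shape) == 4L) {
    xm <- x; dim(xm) <- c(prod(shape[1:3]), shape[4])
  } else {
    xm <- as.matrix(x)
  }
  C <- ncol(xm)
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- rep(0, C)
  res <- gn_forward(xm, list(gamma = gamma, beta = beta), G, eps)
  y <- res$y
  if (length(shape) == 4L) dim(y) <- shape
  y
}

gn_forward <- function(x, par, G, eps) {
  C <- ncol(x)
  if (C %% G != 0) {
    stop_mcdreg(sprintf("channels (%d) not divisible by groups (%d)", C, G),
                "mcdreg_config_error")
  }
  cg <- C %/% G
  y <- x
  xhat <- x
  stats <- vector("list", G)
  for (g in seq_len(G)) {
    cols <- ((g - 1L) * cg + 1L):(g * cg)
    sub <- x[, cols, drop = FALSE]
    mu <- mean(sub)
    sigma <- sqrt(mean((sub - mu)^2) + eps)
    xh <- (sub - mu) / sigma
    xhat[, cols] <- xh
    y[, cols] <- sweep(sweep(xh, 2, par$gamma[cols], `*`), 2,
                       par$beta[cols], `+`)
    stats[[g]] <- list(cols = cols, sigma = sigma)
  }
  list(y = y, cache = list(xhat = xhat, stats = stats, G = G))
}

gn_backward <- function(dy, cache, par) {
  dx <- dy
  dgamma <- numeric(ncol(dy))
  dbeta <- numeric(ncol(dy))
  for (st in cache$stats) {
    cols <- st$cols
    dsub <- dy[, cols, drop = FALSE]
    xh <- cache$xhat[, cols, drop = FALSE]
    dgamma[cols] <- colSums(dsub * xh)
    dbeta[cols] <- colSums(dsub)
    dxh <- sweep(dsub, 2, par$gamma[cols], `*`)
    dx[, cols] <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / st$sigma
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout: each activation is zeroed independently with
# probability `rate` and survivors are scaled by 1/(1-rate), so the
# expected activation is unchanged and deterministic forward passes need
# no rescaling.
dropout_forward <- function(x, rate, active) {
  if (!active || rate <= 0) {
    return(list(y = x, cache = list(mask = NULL, scale = 1)))
  }
  keep <- 1 - rate
  mask <- matrix(runif(length(x)) < keep, nrow = nrow(x))
  list(y = x * mask / keep, cache = list(mask = mask, scale = 1 / keep))
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache$mask)) return(dy)
  dy * cache$mask * cache$scale
}
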