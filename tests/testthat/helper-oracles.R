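# Independent brute-force oracles: explicit per-voxel loops, written
# without reference to the package internals they check.

# Trilinear interpolation of volume v at p + u(p), coordinate clamping at
# the boundary, looped voxel by voxel.
oracle_warp <- function(v, u) {
  v <- unclass(v); u <- unclass(u)
  sh <- dim(v)
  out <- array(0, dim = sh)
  for (d in 1:sh[1]) for (h in 1:sh[2]) for (w in 1:sh[3]) {
    p <- c(d - 1 + u[d, h, w, 1], h - 1 + u[d, h, w, 2], w - 1 + u[d, h, w, 3])
    p <- pmin(pmax(p, 0), sh - 1)
    lo <- floor(p)
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      corner <- lo + c(a, b, cc)
      wt <- prod(1 - abs(p - corner))   # weights from the nominal corner
      q <- pmin(corner, sh - 1)         # sampling clamped to the grid
      acc <- acc + wt * v[q[1] + 1, q[2] + 1, q[3] + 1]
    }
    out[d, h, w] <- acc
  }
  out
}

# Nearest-neighbour label resampling, round half up.
oracle_warp_labels <- function(l, u) {
  l <- unclass(l); u <- unclass(u)
  sh <- dim(l)
  out <- array(0L, dim = sh)
  for (d in 1:sh[1]) for (h in 1:sh[2]) for (w in 1:sh[3]) {
    p <- c(d - 1 + u[d, h, w, 1], h - 1 + u[d, h, w, 2], w - 1 + u[d, h, w, 3])
    p <- pmin(pmax(p, 0), sh - 1)
    q <- pmin(pmax(floor(p + 0.5), 0), sh - 1)
    out[d, h, w] <- l[q[1] + 1, q[2] + 1, q[3] + 1]
  }
  out
}

# Per-voxel 3x3 determinant of I + grad(u), finite differences evaluated
# scalar-by-scalar (central interior, one-sided at boundaries).
oracle_jacobian <- function(u) {
  u <- unclass(u)
  sh <- dim(u)[1:3]
  d1 <- function(comp, axis, idx) {
    n <- sh[axis]
    i <- idx[axis]
    at <- function(k) { j <- idx; j[axis] <- k; u[j[1], j[2], j[3], comp] }
    if (i == 1) at(2) - at(1)
    else if (i == n) at(n) - at(n - 1)
    else (at(i + 1) - at(i - 1)) / 2
  }
  out <- array(0, dim = sh)
  for (d in 1:sh[1]) for (h in 1:sh[2]) for (w in 1:sh[3]) {
    idx <- c(d, h, w)
    J <- diag(3)
    for (i in 1:3) for (j in 1:3) J[i, j] <- J[i, j] + d1(i, j, idx)
    out[d, h, w] <- det(J)
  }
  out
}

# Group normalization by explicit loops over groups.
oracle_group_norm <- function(x, G, gamma, beta, eps) {
  sh <- dim(x)
  C <- sh[4]
  cg <- C / G
  y <- x
  for (g in 1:G) {
    ch <- ((g - 1) * cg + 1):(g * cg)
    vals <- x[, , , ch]
    mu <- mean(vals)
    sigma <- sqrt(mean((vals - mu)^2) + eps)
    for (c0 in ch) {
      y[, , , c0] <- gamma[c0] * (x[, , , c0] - mu) / sigma + beta[c0]
    }
  }
  y
}

# Squared global NCC evaluated with scalar accumulators.
oracle_cc <- function(t, s) {
  t <- as.vector(unclass(t)); s <- as.vector(unclass(s))
  tb <- sum(t) / length(t); sb <- sum(s) / length(s)
  num <- 0; qt <- 0; qs <- 0
  for (i in seq_along(t)) {
    num <- num + (t[i] - tb) * (s[i] - sb)
    qt <- qt + (t[i] - tb)^2
    qs <- qs + (s[i] - sb)^2
  }
  num^2 / (qt * qs)
}

# Confusion counts by exhaustive enumeration over the evaluation domain.
oracle_confusion <- function(correct, unc, th) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(correct)) {
    if (is.na(correct[i])) next
    unsure <- unc[i] > th
    cor <- isTRUE(correct[i] > 0)
    if (unsure && !cor) tp <- tp + 1L
    if (!unsure && cor) tn <- tn + 1L
    if (unsure && cor) fp <- fp + 1L
    if (!unsure && !cor) fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

random_field <- function(shape, sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_displacement_field(array(rnorm(prod(shape) * 3, sd = sd),
                              dim = c(shape, 3)))
}

random_volume <- function(shape, seed = NULL, lo = 0, hi = 255) {
  if (!is.null(seed)) set.seed(seed)
  as_volume(array(runif(prod(shape), lo, hi), dim = shape))
}

# Linear coordinate ramps used by closed-form affine examples.
coord_array <- function(shape, axis) {
  n <- shape[axis]
  vals <- 0:(n - 1)
  if (axis == 1) array(rep(vals, times = shape[2] * shape[3]), dim = shape)
  else if (axis == 2) array(rep(rep(vals, each = shape[1]), times = shape[3]),
                            dim = shape)
  else array(rep(vals, each = shape[1] * shape[2]), dim = shape)
}
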