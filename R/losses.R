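#' Loss weights for registration training
#'
#' The training objective is
#' `L_total = (1 - CC(T, warp(S, u))) + alpha * R1(u) + beta * R2(u)`:
#' an image-dissimilarity term, a displacement-smoothness penalty, and an
#' anti-folding penalty on negative Jacobian determinants.
#'
#' @param alpha Non-negative smoothness weight (default 1).
#' @param beta Non-negative anti-folding weight (default 0; typical sweep
#'   values 0, 1e-5, 1e-4, 1e-3, 1e-2).
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(alpha = 1, beta = 0) {
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Squared normalized cross-correlation between two volumes
#'
#' Global squared NCC over all voxels:
#' `CC = (sum((t - tbar)(s - sbar)))^2 / (sum((t - tbar)^2) sum((s - sbar)^2))`
#' with volume-wide means. Lies in \[0, 1\], equals 1 iff the images are
#' affinely related in intensity; the image loss is `1 - CC`.
#'
#' @param t,s Volumes (or 3D arrays) of equal shape; both non-constant.
#' @return Scalar in \[0, 1\].
#' @examples
#' v <- array(rnorm(27), dim = c(3, 3, 3))
#' cross_correlation(v, 2 * v + 5)  # 1: affine intensity invariance
#' @export
cross_correlation <- function(t, s) {
  t <- unclass(as_volume(t)); s <- unclass(as_volume(s))
  check_shape_equal(t, s, "volumes")
  a <- t - mean(t); b <- s - mean(s)
  Qa <- sum(a * a); Qb <- sum(b * b)
  if (Qa <= 0 || Qb <= 0) {
    stop_mcdreg("cross_correlation is undefined for a constant volume",
                "mcdreg_degenerate_error")
  }
  P <- sum(a * b)
  (P * P) / (Qa * Qb)
}

# CC value plus gradient with respect to the second argument.
cc_with_grad <- function(t, s) {
  a <- t - mean(t); b <- s - mean(s)
  Qa <- sum(a * a); Qb <- sum(b * b)
  if (Qa <= 0 || Qb <= 0) {
    stop_mcdreg("cross_correlation is undefined for a constant volume",
                "mcdreg_degenerate_error")
  }
  P <- sum(a * b)
  cc <- (P * P) / (Qa * Qb)
  db <- (2 * P) * a / (Qa * Qb) - (2 * P * P / (Qa * Qb * Qb)) * b
  list(value = cc, grad_s = db - mean(db))
}

# Forward difference along one axis, zero at the far boundary.
fd_forward <- function(x, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  n <- dim(xp)[1]
  g <- array(0, dim = dim(xp))
  g[1:(n - 1), , ] <- xp[2:n, , ] - xp[1:(n - 1), , ]
  aperm(g, order(perm))
}

fd_forward_adjoint <- function(g, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  gp <- aperm(g, perm)
  n <- dim(gp)[1]
  y <- array(0, dim = dim(gp))
  y[1:(n - 1), , ] <- -gp[1:(n - 1), , ]
  y[2:n, , ] <- y[2:n, , ] + gp[1:(n - 1), , ]
  aperm(y, order(perm))
}

#' Displacement-smoothness penalty R1
#'
#' Mean (over voxels and vector components) of the squared forward-difference
#' spatial gradients of `u`; zero for any constant field. This is the
#' `||Du||^2` diffusion regularizer that discourages rough deformations.
#'
#' @param u A `displacement_field`.
#' @param reduction `"mean"` (default, keeps the weight `alpha` scale-free
#'   across volume sizes) or `"sum"`.
#' @return Non-negative scalar.
#' @export
smoothness_R1 <- function(u, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  u <- as_displacement_field(u)
  total <- 0
  for (comp in 1:3) for (axis in 1:3) {
    g <- fd_forward(u[, , , comp], axis)
    total <- total + sum(g * g)
  }
  if (reduction == "mean") total / (3 * prod(dim(u)[1:3])) else total
}

r1_with_grad <- function(u, reduction = "mean") {
  u <- unclass(u)
  denom <- if (reduction == "mean") 3 * prod(dim(u)[1:3]) else 1
  total <- 0
  du <- array(0, dim = dim(u))
  for (comp in 1:3) {
    acc <- 0
    for (axis in 1:3) {
      g <- fd_forward(u[, , , comp], axis)
      total <- total + sum(g * g)
      acc <- acc + fd_forward_adjoint(2 * g, axis)
    }
    du[, , , comp] <- acc / denom
  }
  list(value = total / denom, grad_u = du)
}

#' Anti-folding penalty R2
#'
#' Per-voxel hinge on the Jacobian determinant of `phi = Id + u`:
#' `0.5 * (|det| - det)`, i.e. `max(0, -det)`, summed over voxels. It is 0
#' exactly when no voxel has a negative determinant, so orientation-
#' preserving deformations are never penalized, while each folded voxel
#' contributes its determinant magnitude.
#'
#' @param u A `displacement_field` (each dimension at least 3).
#' @param reduction `"sum"` (default, count-like semantics) or `"mean"`.
#' @return Non-negative scalar.
#' @export
antifold_R2 <- function(u, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  det <- unclass(jacobian_determinant(u))
  val <- sum(0.5 * (abs(det) - det))
  if (reduction == "mean") val / length(det) else val
}

r2_with_grad <- function(u, reduction = "sum") {
  u <- unclass(u)
  g <- field_gradients(u)
  J11 <- 1 + g[[1]][[1]]; J12 <- g[[1]][[2]]; J13 <- g[[1]][[3]]
  J21 <- g[[2]][[1]]; J22 <- 1 + g[[2]][[2]]; J23 <- g[[2]][[3]]
  J31 <- g[[3]][[1]]; J32 <- g[[3]][[2]]; J33 <- 1 + g[[3]][[3]]
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  denom <- if (reduction == "mean") length(det) else 1
  val <- sum(pmax(0, -det)) / denom
  # d/ddet of max(0, -det); cofactors give d det / d J_ij
  m <- -(det < 0) / denom
  cof <- list(
    list(J22 * J33 - J23 * J32, -(J21 * J33 - J23 * J31), J21 * J32 - J22 * J31),
    list(-(J12 * J33 - J13 * J32), J11 * J33 - J13 * J31, -(J11 * J32 - J12 * J31)),
    list(J12 * J23 - J13 * J22, -(J11 * J23 - J13 * J21), J11 * J22 - J12 * J21)
  )
  du <- array(0, dim = dim(u))
  for (i in 1:3) {
    acc <- 0
    for (j in 1:3) acc <- acc + fd_axis_adjoint(m * cof[[i]][[j]], j)
    du[, , , i] <- acc
  }
  list(value = val, grad_u = du)
}

#' Total registration training loss
#'
#' `L_total = (1 - CC(T, warp(S, u))) + alpha * R1(u) + beta * R2(u)`.
#'
#' @param S,T Source and target `volume`s.
#' @param u Candidate `displacement_field`.
#' @param w A [loss_weights()] object.
#' @return Scalar loss; `total_loss_terms()` returns the individual terms.
#' @examples
#' v <- as_volume(array(rnorm(4^3), dim = c(4, 4, 4)))
#' total_loss(v, v, zero_field(c(4, 4, 4)), loss_weights())  # 0
#' @export
total_loss <- function(S, T, u, w = loss_weights()) {
  total_loss_terms(S, T, u, w)$total
}

#' @rdname total_loss
#' @export
total_loss_terms <- function(S, T, u, w = loss_weights()) {
  S <- as_volume(S); T <- as_volume(T); u <- as_displacement_field(u)
  check_shape_equal(S, T, "source and target")
  check_shape_equal(S, u, "volume and displacement field")
  warped <- warp(S, u)
  l_image <- 1 - cross_correlation(T, warped)
  r1 <- smoothness_R1(u)
  r2 <- antifold_R2(u)
  list(total = l_image + w$alpha * r1 + w$beta * r2,
       l_image = l_image, r1 = r1, r2 = r2)
}

# Loss terms plus the full gradient with respect to u (chains the CC
# gradient through the trilinear warp). The training loop backpropagates
# this gradient into the network parameters.
loss_with_grad_u <- function(S, T, u, w = loss_weights()) {
  S <- unclass(as_volume(S)); T <- unclass(as_volume(T))
  u <- unclass(as_displacement_field(u))
  wg <- warp_with_grad(S, u)
  cc <- cc_with_grad(T, wg$value)
  l_image <- 1 - cc$value
  dwarped <- -cc$grad_s
  du <- array(0, dim = dim(u))
  du[, , , 1] <- dwarped * wg$gd
  du[, , , 2] <- dwarped * wg$gh
  du[, , , 3] <- dwarped * wg$gw
  r1 <- r1_with_grad(u)
  total <- l_image + w$alpha * r1$value
  du <- du + w$alpha * r1$grad_u
  r2val <- 0
  if (w$beta > 0) {
    r2 <- r2_with_grad(u)
    r2val <- r2$value
    total <- total + w$beta * r2$value
    du <- du + w$beta * r2$grad_u
  } else {
    r2val <- antifold_R2(as_displacement_field(u))
    total <- total + w$beta * r2val
  }
  list(total = total, l_image = l_image, r1 = r1$value, r2 = r2val,
       grad_u = du)
}
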