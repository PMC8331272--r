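# Finite-difference derivative of a 3D array along one axis:
# central differences at interior voxels, one-sided at the two boundary
# slices. Operates in voxel units (grid step 1).
fd_axis <- function(x, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  xp <- aperm(x, perm)
  n <- dim(xp)[1]
  g <- xp
  g[1, , ] <- xp[2, , ] - xp[1, , ]
  g[n, , ] <- xp[n, , ] - xp[n - 1, , ]
  if (n > 2) {
    i <- 2:(n - 1)
    g[i, , ] <- (xp[i + 1, , ] - xp[i - 1, , ]) / 2
  }
  aperm(g, order(perm))
}

# Adjoint (transpose) of fd_axis as a linear operator, needed to
# backpropagate through Jacobian-determinant penalties.
fd_axis_adjoint <- function(g, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  gp <- aperm(g, perm)
  n <- dim(gp)[1]
  y <- array(0, dim = dim(gp))
  # row 1: one-sided forward difference
  y[1, , ] <- y[1, , ] - gp[1, , ]
  y[2, , ] <- y[2, , ] + gp[1, , ]
  # interior rows: central differences
  if (n > 2) {
    i <- 2:(n - 1)
    y[i - 1, , ] <- y[i - 1, , ] - gp[i, , ] / 2
    y[i + 1, , ] <- y[i + 1, , ] + gp[i, , ] / 2
  }
  # row n: one-sided backward difference
  y[n - 1, , ] <- y[n - 1, , ] - gp[n, , ]
  y[n, , ] <- y[n, , ] + gp[n, , ]
  aperm(y, order(perm))
}

# The nine spatial derivatives d u_i / d x_j as a nested list.
field_gradients <- function(u) {
  lapply(1:3, function(i) lapply(1:3, function(j) fd_axis(u[, , , i], j)))
}

#' Jacobian determinant map of a deformation
#'
#' For the deformation map `phi = Id + u`, computes `det(I + grad(u))` at
#' every voxel. The determinant is the local volume-change factor: 1 means
#' volume preserving, values below 0 mean the map folds space onto itself
#' (orientation reversal), which is physically impossible for tissue.
#' Gradients use central finite differences at interior voxels and one-sided
#' differences at boundary voxels, in voxel units.
#'
#' @param u A `displacement_field` (D, H, W, 3), each dimension at least 3.
#' @return A `jacobian_map`: 3D array of per-voxel determinants.
#' @examples
#' jac <- jacobian_determinant(zero_field(c(4, 4, 4)))
#' all(jac == 1)
#' @export
jacobian_determinant <- function(u) {
  u <- as_displacement_field(u)
  if (any(dim(u)[1:3] < 3L)) {
    stop_mcdreg("jacobian_determinant needs every spatial dimension >= 3",
                "mcdreg_degenerate_error")
  }
  g <- field_gradients(u)
  J11 <- 1 + g[[1]][[1]]; J12 <- g[[1]][[2]]; J13 <- g[[1]][[3]]
  J21 <- g[[2]][[1]]; J22 <- 1 + g[[2]][[2]]; J23 <- g[[2]][[3]]
  J31 <- g[[3]][[1]]; J32 <- g[[3]][[2]]; J33 <- 1 + g[[3]][[3]]
  det <- J11 * (J22 * J33 - J23 * J32) -
         J12 * (J21 * J33 - J23 * J31) +
         J13 * (J21 * J32 - J22 * J31)
  structure(det, class = "jacobian_map")
}

#' @export
print.jacobian_map <- function(x, ...) {
  cat(sprintf("<jacobian_map> %s, det range [%.3g, %.3g], %d folded voxel(s)\n",
              paste(dim(x), collapse = " x "), min(x), max(x),
              sum(x < 0)))
  invisible(x)
}

#' Count folded voxels (negative Jacobian determinant)
#'
#' Counts voxels where the deformation is locally orientation-reversing,
#' i.e. `det < 0` strictly (a determinant of exactly 0 is not counted).
#' When a mask is supplied the count is restricted to nonbackground voxels
#' (`mask > 0`), matching how folding is reported over brain tissue only.
#'
#' @param jac A `jacobian_map` (or 3D array of determinants).
#' @param mask Optional `label_volume` or array; voxels with `mask > 0` are
#'   counted. `NULL` (default) counts over the full grid.
#' @return Non-negative integer count.
#' @export
folding_count <- function(jac, mask = NULL) {
  jac <- unclass(jac)
  check_finite(jac, "jacobian map")
  neg <- jac < 0
  if (!is.null(mask)) {
    mask <- unclass(mask)
    check_shape_equal(jac, mask, "jacobian map and mask")
    neg <- neg & (mask > 0)
  }
  sum(neg)
}
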