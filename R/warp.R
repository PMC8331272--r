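# Shared geometry for the spatial transformer: clamped sample coordinates,
# corner indices, and interpolation fractions for each voxel. Coordinates
# are 0-based; out-of-bounds sample positions are clamped to the boundary.
warp_geometry <- function(shape, u) {
  D <- shape[1]; H <- shape[2]; W <- shape[3]
  cd <- array(rep(0:(D - 1), times = H * W), dim = shape)
  ch <- array(rep(rep(0:(H - 1), each = D), times = W), dim = shape)
  cw <- array(rep(0:(W - 1), each = D * H), dim = shape)
  pd_raw <- cd + u[, , , 1]
  ph_raw <- ch + u[, , , 2]
  pw_raw <- cw + u[, , , 3]
  pd <- pmin(pmax(pd_raw, 0), D - 1)
  ph <- pmin(pmax(ph_raw, 0), H - 1)
  pw <- pmin(pmax(pw_raw, 0), W - 1)
  i0 <- floor(pd); j0 <- floor(ph); k0 <- floor(pw)
  list(
    i0 = i0, j0 = j0, k0 = k0,
    i1 = pmin(i0 + 1, D - 1), j1 = pmin(j0 + 1, H - 1),
    k1 = pmin(k0 + 1, W - 1),
    fd = pd - i0, fh = ph - j0, fw = pw - k0,
    # clamp derivative: zero outside the open interval
    in_d = (pd_raw > 0) & (pd_raw < D - 1),
    in_h = (ph_raw > 0) & (ph_raw < H - 1),
    in_w = (pw_raw > 0) & (pw_raw < W - 1),
    pd = pd, ph = ph, pw = pw,
    D = D, H = H, W = W
  )
}

lin_index <- function(i, j, k, D, H) 1 + i + D * (j + H * k)

# Trilinear interpolation and (optionally) its derivative with respect to
# the three sample-coordinate components. Vectorized over all voxels.
trilinear_eval <- function(s_flat, geo, want_grad = FALSE) {
  val <- 0
  gd <- if (want_grad) 0 else NULL
  gh <- if (want_grad) 0 else NULL
  gw <- if (want_grad) 0 else NULL
  for (a in 0:1) {
    wd <- if (a == 0) 1 - geo$fd else geo$fd
    ia <- if (a == 0) geo$i0 else geo$i1
    sa <- if (a == 0) -1 else 1
    for (b in 0:1) {
      wh <- if (b == 0) 1 - geo$fh else geo$fh
      jb <- if (b == 0) geo$j0 else geo$j1
      sb <- if (b == 0) -1 else 1
      for (cc in 0:1) {
        ww <- if (cc == 0) 1 - geo$fw else geo$fw
        kc <- if (cc == 0) geo$k0 else geo$k1
        sc <- if (cc == 0) -1 else 1
        sv <- s_flat[lin_index(ia, jb, kc, geo$D, geo$H)]
        val <- val + wd * wh * ww * sv
        if (want_grad) {
          gd <- gd + sa * wh * ww * sv
          gh <- gh + wd * sb * ww * sv
          gw <- gw + wd * wh * sc * sv
        }
      }
    }
  }
  if (want_grad) {
    list(value = val,
         gd = gd * geo$in_d, gh = gh * geo$in_h, gw = gw * geo$in_w)
  } else {
    list(value = val)
  }
}

#' Warp a volume through a displacement field (spatial transformer)
#'
#' Resamples `v` at `p + u(p)` for every voxel `p` by trilinear
#' interpolation over the eight integer neighbours, the differentiable
#' warping operation `S o phi` used to train the registration network.
#' Sample positions falling outside the grid are clamped to the boundary.
#'
#' @param v A `volume` (the moving/source image).
#' @param u A `displacement_field` of the same spatial shape, voxel units.
#' @param mode Interpolation mode; only `"linear"` is supported.
#' @return The warped `volume`.
#' @examples
#' v <- as_volume(array(rnorm(64), dim = c(4, 4, 4)))
#' identical(unclass(warp(v, zero_field(c(4, 4, 4)))), unclass(v))
#' @export
warp <- function(v, u, mode = "linear") {
  mode <- match.arg(mode, "linear")
  v <- as_volume(v)
  u <- as_displacement_field(u)
  check_shape_equal(v, u, "volume and displacement field")
  geo <- warp_geometry(dim(v), unclass(u))
  out <- trilinear_eval(as.vector(unclass(v)), geo)$value
  as_volume(array(out, dim = dim(v)), spacing = attr(v, "spacing"))
}

# Warp plus derivative of every output voxel w.r.t. its own displacement
# vector: returns the warped values and three arrays d(out)/d(u_d,h,w).
warp_with_grad <- function(v, u) {
  geo <- warp_geometry(dim(v)[1:3], unclass(u))
  res <- trilinear_eval(as.vector(unclass(v)), geo, want_grad = TRUE)
  shape <- dim(v)[1:3]
  list(value = array(res$value, dim = shape),
       gd = array(res$gd, dim = shape),
       gh = array(res$gh, dim = shape),
       gw = array(res$gw, dim = shape))
}

#' Warp a label volume (nearest-neighbour)
#'
#' Labels are categorical and must never be blended, so resampling takes
#' the label at the nearest integer position to `p + u(p)` (ties at .5
#' round half up). Out-of-bounds positions are clamped.
#'
#' @param l A `label_volume`.
#' @param u A `displacement_field` of the same spatial shape.
#' @return The warped `label_volume`.
#' @export
warp_labels <- function(l, u) {
  l <- as_label_volume(l)
  u <- as_displacement_field(u)
  check_shape_equal(l, u, "labels and displacement field")
  geo <- warp_geometry(dim(l), unclass(u))
  ni <- pmin(pmax(floor(geo$pd + 0.5), 0), geo$D - 1)
  nj <- pmin(pmax(floor(geo$ph + 0.5), 0), geo$H - 1)
  nk <- pmin(pmax(floor(geo$pw + 0.5), 0), geo$W - 1)
  out <- as.vector(unclass(l))[lin_index(ni, nj, nk, geo$D, geo$H)]
  as_label_volume(array(out, dim = dim(l)))
}
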