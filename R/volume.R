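#' Construct a 3D scalar volume
#'
#' A `volume` is a numeric 3D array with per-axis voxel spacing, the basic
#' image container for registration: a scalar intensity on a (D, H, W) grid.
#'
#' @param data Numeric 3D array (D, H, W). All values must be finite.
#' @param spacing Numeric length-3 voxel size per axis (default isotropic 1).
#' @return A `volume` object (numeric 3D array with a `spacing` attribute).
#' @examples
#' v <- as_volume(array(rnorm(27), dim = c(3, 3, 3)))
#' dim(v)
#' @export
as_volume <- function(data, spacing = c(1, 1, 1)) {
  if (inherits(data, "volume")) return(data)
  data <- unclass(data)
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop_mcdreg("a volume must be a 3D array (D, H, W)", "mcdreg_shape_error")
  }
  check_finite(data, "volume")
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(data, spacing = as.numeric(spacing), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume> %d x %d x %d, spacing (%s), range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 3), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' Construct an integer label volume
#'
#' Labels index anatomical-like regions; 0 is background. Used for Dice
#' overlap evaluation and for the per-voxel correctness map.
#'
#' @param data Integer-valued 3D array of non-negative labels.
#' @return A `label_volume` object.
#' @export
as_label_volume <- function(data) {
  if (inherits(data, "label_volume")) return(data)
  data <- unclass(data)
  if (is.null(dim(data)) || length(dim(data)) != 3L) {
    stop_mcdreg("a label volume must be a 3D array", "mcdreg_shape_error")
  }
  if (any(data < 0) || any(data != round(data))) {
    stop_mcdreg("labels must be non-negative integers", "mcdreg_value_error")
  }
  storage.mode(data) <- "integer"
  structure(data, class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  ids <- setdiff(sort(unique(as.integer(x))), 0L)
  cat(sprintf("<label_volume> %d x %d x %d, %d region(s): {%s}\n",
              d[1], d[2], d[3], length(ids),
              paste(ids, collapse = ", ")))
  invisible(x)
}

#' Label identifiers present in a label volume
#' @param l A `label_volume`.
#' @param include_background Keep the 0 background label? Default `FALSE`.
#' @return Sorted integer vector of labels.
#' @export
label_ids <- function(l, include_background = FALSE) {
  ids <- sort(unique(as.integer(l)))
  if (!include_background) ids <- setdiff(ids, 0L)
  ids
}

#' Construct a dense displacement field
#'
#' A displacement field `u` assigns each voxel `p` of the target grid a
#' 3-vector (in voxel units) so that the deformation map is `phi = Id + u`:
#' the warped image samples the source at `p + u(p)`.
#'
#' @param u Numeric 4D array (D, H, W, 3); last axis holds the (d, h, w)
#'   displacement components.
#' @return A `displacement_field` object.
#' @export
as_displacement_field <- function(u) {
  if (inherits(u, "displacement_field")) return(u)
  u <- unclass(u)
  if (is.null(dim(u)) || length(dim(u)) != 4L || dim(u)[4] != 3L) {
    stop_mcdreg("a displacement field must be a (D, H, W, 3) array",
                "mcdreg_shape_error")
  }
  check_finite(u, "displacement field")
  structure(u, class = "displacement_field")
}

#' Zero displacement field for a given grid
#' @param shape Integer length-3 spatial shape.
#' @return A `displacement_field` of zeros (the identity deformation).
#' @export
zero_field <- function(shape) {
  as_displacement_field(array(0, dim = c(shape, 3L)))
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x)
  mag <- sqrt(x[, , , 1]^2 + x[, , , 2]^2 + x[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d, |u| max %.3g voxels\n",
              d[1], d[2], d[3], max(mag)))
  invisible(x)
}

#' Min-max normalize intensities to the 0-255 range
#'
#' Linear rescale of a volume so its minimum maps to 0 and its maximum to
#' 255, the standard preprocessing for the registration network's inputs.
#'
#' @param v A `volume` (or 3D array).
#' @return A `volume` with values in \[0, 255\].
#' @examples
#' v <- as_volume(array(c(10, 20, 30), dim = c(3, 1, 1)))
#' range(normalize_intensity(v))
#' @export
normalize_intensity <- function(v) {
  v <- as_volume(v)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    stop_mcdreg("cannot normalize a constant volume (degenerate intensity)",
                "mcdreg_degenerate_error")
  }
  out <- (unclass(v) - lo) * (255 / (hi - lo))
  as_volume(out, spacing = attr(v, "spacing"))
}
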