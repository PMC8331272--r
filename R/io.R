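# NIfTI-1 is the single on-disk volume format: 3D images for volumes,
# labels, Jacobian and uncertainty maps; 4D images (last axis = vector
# component, order d,h,w) for displacement fields.

#' Read / write volumes and displacement fields as NIfTI
#'
#' `read_volume()`/`write_volume()` handle 3D scalar volumes (`.nii` /
#' `.nii.gz`; spacing round-trips through the pixdim header).
#' `read_field()`/`write_field()` handle displacement fields as 4D NIfTI
#' with the vector component on the last axis in (d, h, w) order.
#' `read_labels()` reads an integer label volume.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param v,u Object to write.
#' @return The read object, or (invisibly) the path written.
#' @export
read_volume <- function(path) {
  img <- read_nifti_checked(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim = dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    stop_mcdreg(sprintf(
      "%s: expected a 3D volume, got %d dimensions (this toolkit is 3D-only)",
      path, length(dim(arr))), "mcdreg_dimension_error")
  }
  as_volume(arr, spacing = RNifti::pixdim(img)[1:3])
}

read_nifti_checked <- function(path) {
  if (!file.exists(path)) {
    stop_mcdreg(sprintf("file not found: %s", path), "mcdreg_format_error")
  }
  tryCatch(RNifti::readNifti(path),
           error = function(e) {
             stop_mcdreg(sprintf("malformed NIfTI file %s: %s", path,
                                 conditionMessage(e)),
                         "mcdreg_format_error")
           })
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  img <- RNifti::asNifti(unclass(v))
  RNifti::pixdim(img) <- attr(v, "spacing")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  v <- read_volume(path)
  as_label_volume(round(unclass(v)))
}

#' @rdname read_volume
#' @export
write_labels <- function(v, path) {
  img <- RNifti::asNifti(unclass(as_label_volume(v)),
                         descrip = "mcdreg labels, axes (D,H,W)")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
write_field <- function(u, path) {
  u <- as_displacement_field(u)
  img <- RNifti::asNifti(unclass(u),
                         descrip = "mcdreg displacement, last axis components (d,h,w), voxel units")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_field <- function(path) {
  img <- read_nifti_checked(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L) {
    stop_mcdreg(sprintf("%s: expected a (D,H,W,3) displacement field", path),
                "mcdreg_format_error")
  }
  as_displacement_field(arr)
}

#' Save / load a network checkpoint
#'
#' The checkpoint embeds the full `network_config`, so loading needs no
#' separate architecture description.
#'
#' @param net A `bfcnm` network or `bfcnm_fit`.
#' @param path Checkpoint path (`.rds`).
#' @return `load_checkpoint()` returns the `bfcnm`.
#' @export
save_checkpoint <- function(net, path) {
  if (inherits(net, "bfcnm_fit")) net <- net$network
  stopifnot(inherits(net, "bfcnm"))
  saveRDS(list(format = "mcdreg_checkpoint_v1",
               config = unclass(net$config), params = net$params), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mcdreg_checkpoint_v1")) {
    stop_mcdreg(sprintf("%s is not an mcdreg checkpoint", path),
                "mcdreg_format_error")
  }
  cfg <- do.call(network_config,
                 obj$config[setdiff(names(obj$config), "channels")])
  structure(list(config = cfg, params = obj$params), class = "bfcnm")
}

#' Default run configuration
#'
#' One nested, human-readable configuration covering every pipeline stage
#' (network, training, phantom simulation, Monte Carlo inference,
#' evaluation); serialize with [write_run_config()] and read back with
#' [read_run_config()] (lossless round trip).
#'
#' @return Nested list of configuration blocks.
#' @export
default_run_config <- function() {
  list(
    network = list(input_shape = c(32L, 32L, 32L), base_channels = 16L,
                   inception_kernels = c(3L, 5L, 7L), n_levels = 3L,
                   n_groups = 4L, dropout_rate = 0.5, epsilon = 1e-5),
    training = list(learning_rate = 1e-4, epochs = 10L, weight_decay = 1e-5,
                    seed = 1L, alpha = 1, beta = 0),
    phantom = list(shape = c(32L, 32L, 32L), n_regions = 5L,
                   intensity_noise_sd = 6, seed = 1L),
    deformation = list(amplitude = 2.5, smoothness = 4,
                       allow_folding = FALSE, seed = 1L),
    simulate = list(n_pairs = 4L),
    mc = list(samples = 48L, seed = 1L),
    evaluation = list(thresholds = seq(0, 1, by = 0.1))
  )
}

#' @rdname default_run_config
#' @param cfg Nested configuration list.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  base <- default_run_config()
  user <- yaml::read_yaml(path)
  for (blk in names(user)) {
    if (is.list(user[[blk]]) && blk %in% names(base)) {
      for (k in names(user[[blk]])) base[[blk]][[k]] <- user[[blk]][[k]]
    } else {
      base[[blk]] <- user[[blk]]
    }
  }
  base
}
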