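#' Training configuration
#'
#' Unsupervised training minimizes
#' `1 - CC(T, warp(S, u)) + alpha R1(u) + beta R2(u)` over all ordered
#' image pairs with Adam at batch size 1. Dropout stays active during
#' training and an L2 penalty on the convolution kernels is applied through
#' the optimizer as weight decay, which together make the procedure the
#' practical form of variational Bayesian inference with a Bernoulli
#' posterior over weights.
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param epochs Passes over the training pairs (default 10).
#' @param loss_weights A [loss_weights()] object (`alpha` default 1).
#' @param weight_decay L2 coefficient on convolution kernels (default 1e-5).
#' @param seed Master seed; all dropout masks and any other randomness in a
#'   run derive from it, so identical seeds give identical histories.
#' @param dropout_active Keep dropout on during training (default `TRUE`).
#' @param batch_size Images per step; only 1 is supported.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 10,
                         loss_weights = NULL,
                         weight_decay = 1e-5, seed = 1L,
                         dropout_active = TRUE, batch_size = 1L) {
  stopifnot(learning_rate > 0, epochs >= 0, weight_decay >= 0,
            batch_size == 1L)
  if (is.null(loss_weights)) loss_weights <- loss_weights()
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 loss_weights = loss_weights, weight_decay = weight_decay,
                 seed = as.integer(seed), dropout_active = dropout_active,
                 batch_size = 1L),
            class = "train_config")
}

adam_init <- function(params) {
  zero_like <- function(p) lapply(p, function(a) array(0, dim = dim(a) %||% length(a)))
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One Adam update (beta1 = 0.9, beta2 = 0.999, eps = 1e-8). Weight decay
# adds `wd * W` to the gradient of convolution kernels (fields named "W"),
# the optimizer-side form of an L2 penalty on the weights.
adam_step <- function(params, grads, state, lr, wd = 0) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      g <- grads[[nm]][[fld]]
      if (fld == "W" && wd > 0) g <- g + wd * params[[nm]][[fld]]
      m <- b1 * state$m[[nm]][[fld]] + (1 - b1) * g
      v <- b2 * state$v[[nm]][[fld]] + (1 - b2) * g * g
      state$m[[nm]][[fld]] <- m
      state$v[[nm]][[fld]] <- v
      mhat <- m / (1 - b1^t)
      vhat <- v / (1 - b2^t)
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train the registration network on image pairs
#'
#' Runs Adam over all supplied ordered `(S, T)` pairs for the configured
#' number of epochs, with dropout active and weight decay applied. Fully
#' reproducible given `cfg$seed`.
#'
#' @param net A `bfcnm` network.
#' @param pairs List of pairs; each element is a list with `volume`
#'   elements `S` (moving) and `T` (target), matching the network's input
#'   shape.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch mean losses to stderr?
#' @return A `bfcnm_fit`: the trained network, a per-iteration history
#'   tibble (total loss and each component), and the configuration.
#'   [tidy()] returns the history, [glance()] a one-row summary, and
#'   [autoplot()] the loss curves.
#' @export
train_bfcnm <- function(net, pairs, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "bfcnm"), length(pairs) >= 1)
  for (p in pairs) {
    if (!identical(dim(p$S)[1:3], net$config$input_shape) ||
        !identical(dim(p$T)[1:3], net$config$input_shape)) {
      stop_mcdreg("training pair does not match the network input shape",
                  "mcdreg_shape_error")
    }
  }
  history <- list()
  if (cfg$epochs == 0L) {
    return(new_bfcnm_fit(net, history_tibble(history), cfg))
  }
  state <- adam_init(net$params)
  iter <- 0L
  t0 <- Sys.time()
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      for (pi in seq_along(pairs)) {
        iter <- iter + 1L
        S <- pairs[[pi]]$S; T <- pairs[[pi]]$T
        fwd <- bfcnm_forward_cache(net, S, T,
                                   stochastic = cfg$dropout_active)
        lg <- loss_with_grad_u(S, T, as_displacement_field(fwd$u),
                               cfg$loss_weights)
        if (!is.finite(lg$total)) {
          stop_mcdreg(sprintf("training diverged: non-finite loss at iteration %d",
                              iter), "mcdreg_divergence_error")
        }
        grads <- bfcnm_backward(net, fwd$cache, lg$grad_u)
        upd <- adam_step(net$params, grads, state, cfg$learning_rate,
                         cfg$weight_decay)
        net$params <- upd$params
        state <- upd$state
        history[[iter]] <- list(iteration = iter, epoch = epoch, pair = pi,
                                total = lg$total, l_image = lg$l_image,
                                r1 = lg$r1, r2 = lg$r2,
                                elapsed = as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs")))
      }
      if (verbose) {
        ep <- vapply(history[(iter - length(pairs) + 1L):iter],
                     function(h) h$total, numeric(1))
        message(sprintf("epoch %d/%d  mean loss %.5f", epoch, cfg$epochs,
                        mean(ep)))
      }
    }
  })
  new_bfcnm_fit(net, history_tibble(history), cfg)
}

history_tibble <- function(history) {
  if (length(history) == 0) {
    return(tibble::tibble(iteration = integer(), epoch = integer(),
                          pair = integer(), total = numeric(),
                          l_image = numeric(), r1 = numeric(),
                          r2 = numeric(), elapsed = numeric()))
  }
  dplyr::bind_rows(lapply(history, tibble::as_tibble))
}

new_bfcnm_fit <- function(net, history, cfg) {
  structure(list(network = net, history = history, config = cfg),
            class = "bfcnm_fit")
}

#' @export
print.bfcnm_fit <- function(x, ...) {
  cat(sprintf("<bfcnm_fit> %d iteration(s)", nrow(x$history)))
  if (nrow(x$history) > 0) {
    cat(sprintf(", loss %.5f -> %.5f", x$history$total[1],
                x$history$total[nrow(x$history)]))
  }
  cat("\n")
  print(x$network$config)
  invisible(x)
}

#' Register a pair of volumes with a trained network
#'
#' Deterministic forward pass (dropout off) followed by the trilinear warp;
#' use [mc_summary()] instead when uncertainty is wanted.
#'
#' @param net A `bfcnm` network (or `bfcnm_fit`).
#' @param S,T Source and target `volume`s.
#' @return List with `field` (the predicted `displacement_field`) and
#'   `warped` (S resampled through it).
#' @export
register_pair <- function(net, S, T) {
  if (inherits(net, "bfcnm_fit")) net <- net$network
  u <- predict_field(net, S, T, stochastic = FALSE)
  list(field = u, warped = warp(as_volume(S), u))
}

#' Numerically invert a displacement field
#'
#' Fixed-point iteration for the field `v` with `(Id+u) o (Id+v) = Id`,
#' i.e. `v(p) = -u(p + v(p))`, resampling `u` trilinearly each sweep. Used
#' to compare a predicted source-to-target field against a ground-truth
#' deformation applied in the opposite direction.
#'
#' @param u A `displacement_field`.
#' @param n_iter Number of fixed-point sweeps (default 10).
#' @return The approximate inverse `displacement_field`.
#' @export
invert_field <- function(u, n_iter = 10) {
  u <- as_displacement_field(u)
  shape <- dim(u)[1:3]
  v <- array(0, dim = dim(u))
  for (it in seq_len(n_iter)) {
    vf <- as_displacement_field(v)
    vnew <- array(0, dim = dim(u))
    for (comp in 1:3) {
      uc <- as_volume(array(u[, , , comp], dim = shape))
      vnew[, , , comp] <- -unclass(warp(uc, vf))
    }
    v <- vnew
  }
  as_displacement_field(v)
}

#' Mean endpoint error between two displacement fields
#'
#' Mean Euclidean distance (in voxels) between corresponding displacement
#' vectors; the standard accuracy measure when a ground-truth field exists.
#'
#' @param u,v `displacement_field`s of equal shape.
#' @param mask Optional array; restrict to voxels with `mask > 0`.
#' @return Non-negative scalar.
#' @export
endpoint_error <- function(u, v, mask = NULL) {
  u <- as_displacement_field(u); v <- as_displacement_field(v)
  check_shape_equal(u, v, "displacement fields")
  d <- unclass(u) - unclass(v)
  mag <- sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2)
  if (!is.null(mask)) {
    check_shape_equal(mag, unclass(mask), "field and mask")
    mean(mag[unclass(mask) > 0])
  } else {
    mean(mag)
  }
}
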