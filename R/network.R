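#' Configuration of the registration network
#'
#' Describes the Bayesian fully convolutional registration network: an
#' inception-style first layer (parallel convolutions at several kernel
#' sizes, concatenated), an encoder of stride-2 convolutions (no pooling),
#' and a decoder of upsampling blocks joined to the encoder by "add" skip
#' connections. The deepest two decoder stages are Bayesian blocks
#' (transposed convolution, convolution, PReLU, group normalization,
#' dropout); keeping their dropout active at test time turns the network
#' into an approximate Bayesian posterior over displacement fields.
#'
#' Channel widths: each inception branch emits `base_channels` channels
#' (concatenated), and encoder level `l` carries `base_channels * 2^l`
#' channels, the smallest layout consistent with the topology; all widths
#' scale with `base_channels`.
#'
#' @param input_shape Integer length-3 spatial shape (D, H, W).
#' @param base_channels Channels per inception branch; doubled per level.
#' @param inception_kernels Odd kernel sizes of the parallel first-layer
#'   branches.
#' @param n_levels Number of stride-2 downsamplings (default 3, giving the
#'   three "add" skip connections).
#' @param n_groups Group count `G` for group normalization; must divide the
#'   channel width at every normalization site.
#' @param dropout_rate Probability of zeroing an activation in the Bayesian
#'   blocks, in (0, 1); default 0.5.
#' @param epsilon Group-normalization variance floor (default 1e-5).
#' @param final_sd Initialization s.d. of the final displacement-emitting
#'   convolution; small so the initial predicted field is near zero.
#' @return A `network_config` object.
#' @export
network_config <- function(input_shape = c(32, 32, 32),
                           base_channels = 16,
                           inception_kernels = c(3, 5, 7),
                           n_levels = 3,
                           n_groups = 4,
                           dropout_rate = 0.5,
                           epsilon = 1e-5,
                           final_sd = 1e-3) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape >= 4L),
            base_channels >= 1, n_levels >= 1,
            all(inception_kernels %% 2 == 1),
            dropout_rate > 0, dropout_rate < 1, epsilon > 0)
  if (min(input_shape) / 2^n_levels < 2) {
    stop_mcdreg("n_levels too deep: a downsampled dimension would fall below 2",
                "mcdreg_config_error")
  }
  channels <- c(length(inception_kernels) * base_channels,
                base_channels * 2^seq_len(n_levels))
  # GN sites: the Bayesian decoder stages (the two deepest) emit
  # channels[l] for stage l, 1-based.
  gn_channels <- channels[seq(n_levels, max(n_levels - 1, 1))]
  if (any(gn_channels %% n_groups != 0)) {
    stop_mcdreg(sprintf(
      "n_groups (%d) must divide the normalized channel widths (%s)",
      n_groups, paste(gn_channels, collapse = ", ")), "mcdreg_config_error")
  }
  structure(list(input_shape = input_shape, base_channels = base_channels,
                 inception_kernels = as.integer(inception_kernels),
                 n_levels = as.integer(n_levels),
                 n_groups = as.integer(n_groups),
                 dropout_rate = dropout_rate, epsilon = epsilon,
                 final_sd = final_sd, channels = channels),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> input %s | inception k={%s} | channels %s | G=%d | dropout %.2f\n",
    paste(x$input_shape, collapse = "x"),
    paste(x$inception_kernels, collapse = ","),
    paste(x$channels, collapse = "-"), x$n_groups, x$dropout_rate))
  invisible(x)
}

level_shapes <- function(cfg) {
  shapes <- vector("list", cfg$n_levels + 1L)
  shapes[[1]] <- cfg$input_shape
  for (l in seq_len(cfg$n_levels)) {
    shapes[[l + 1]] <- vapply(shapes[[l]], conv_out_dim, integer(1),
                              stride = 2L)
  }
  shapes
}

bayesian_stages <- function(cfg) {
  # The two deepest decoder stages carry GN + dropout (Bayesian blocks).
  L <- cfg$n_levels
  seq(L, max(L - 1L, 1L))
}

#' Build the Bayesian fully convolutional registration network
#'
#' Initializes all trainable parameters (He-initialized convolution
#' kernels, PReLU slopes at 0.25, unit group-norm scales) for the network
#' described by `cfg`. The final convolution is initialized near zero so an
#' untrained network predicts an almost-identity deformation.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return A `bfcnm` object (config plus parameter list).
#' @export
build_bfcnm <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- cfg$channels
  L <- cfg$n_levels
  with_seed(seed, {
    params <- list()
    for (k in cfg$inception_kernels) {
      params[[paste0("inc", k)]] <- init_conv(k, 2L, cfg$base_channels)
    }
    params$inc_act <- init_prelu(ch[1])
    for (l in seq_len(L)) {
      params[[paste0("enc", l)]] <- init_conv(3L, ch[l], ch[l + 1])
      params[[paste0("enc", l, "_act")]] <- init_prelu(ch[l + 1])
    }
    for (l in L:1) {
      # transposed conv C_l -> C_{l-1}; weights shaped (k^3*Cout x Cin)
      params[[paste0("dec", l, "_tc")]] <- list(
        W = matrix(rnorm(27 * ch[l] * ch[l + 1],
                         sd = sqrt(2 / (27 * ch[l + 1]))),
                   nrow = 27 * ch[l]),
        b = numeric(ch[l]))
      params[[paste0("dec", l, "_conv")]] <- init_conv(3L, ch[l], ch[l])
      params[[paste0("dec", l, "_act")]] <- init_prelu(ch[l])
      if (l %in% bayesian_stages(cfg)) {
        params[[paste0("dec", l, "_gn")]] <- init_gn(ch[l])
      }
    }
    params$out <- init_conv(3L, ch[1], 3L, sd = cfg$final_sd)
    structure(list(config = cfg, params = params), class = "bfcnm")
  })
}

#' @export
print.bfcnm <- function(x, ...) {
  cat(sprintf("<bfcnm> %s parameters\n",
              format(n_parameters(x), big.mark = ",")))
  print(x$config)
  invisible(x)
}

#' Number of trainable parameters
#' @param net A `bfcnm` network.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(unlist(net$params, recursive = FALSE), length, integer(1)))
}

# Forward pass keeping every intermediate needed for backpropagation.
# Returns list(u = (D,H,W,3) array, cache).
bfcnm_forward_cache <- function(net, S, T, stochastic = FALSE) {
  cfg <- net$config
  p <- net$params
  shapes <- level_shapes(cfg)
  L <- cfg$n_levels
  ch <- cfg$channels
  bayes <- bayesian_stages(cfg)
  x <- cbind(as.vector(unclass(S)) / 255, as.vector(unclass(T)) / 255)

  cache <- list(e = vector("list", L + 1L), dec = vector("list", L))
  # inception front layer: parallel convolutions, concatenated
  branches <- list(); bc <- list()
  for (k in cfg$inception_kernels) {
    map <- conv_index_map(shapes[[1]], k, 1L)
    r <- conv_forward(x, p[[paste0("inc", k)]], map)
    branches[[as.character(k)]] <- r$y
    bc[[as.character(k)]] <- r$cache
  }
  cat_y <- do.call(cbind, unname(branches))
  act <- prelu_forward(cat_y, p$inc_act)
  cache$inc <- bc; cache$inc_act <- act$cache
  e <- vector("list", L + 1L)
  e[[1]] <- act$y

  # encoder: stride-2 convolutions
  enc_cache <- vector("list", L)
  for (l in seq_len(L)) {
    map <- conv_index_map(shapes[[l]], 3L, 2L)
    cv <- conv_forward(e[[l]], p[[paste0("enc", l)]], map)
    ac <- prelu_forward(cv$y, p[[paste0("enc", l, "_act")]])
    enc_cache[[l]] <- list(conv = cv$cache, act = ac$cache)
    e[[l + 1]] <- ac$y
  }
  cache$enc <- enc_cache
  cache$e_dims <- lapply(e, dim)

  # decoder: transposed conv + conv + PReLU (+ GN + dropout in Bayesian
  # stages), then "add" skip connection to the encoder feature
  h <- e[[L + 1]]
  for (l in L:1) {
    map <- conv_index_map(shapes[[l]], 3L, 2L)   # big side = level l-1 grid
    tc <- convt_forward(h, p[[paste0("dec", l, "_tc")]], map)
    map1 <- conv_index_map(shapes[[l]], 3L, 1L)
    cv <- conv_forward(tc$y, p[[paste0("dec", l, "_conv")]], map1)
    ac <- prelu_forward(cv$y, p[[paste0("dec", l, "_act")]])
    y <- ac$y
    st <- list(tc = tc$cache, conv = cv$cache, act = ac$cache)
    if (l %in% bayes) {
      gn <- gn_forward(y, p[[paste0("dec", l, "_gn")]], cfg$n_groups,
                       cfg$epsilon)
      dr <- dropout_forward(gn$y, cfg$dropout_rate, stochastic)
      y <- dr$y
      st$gn <- gn$cache; st$drop <- dr$cache
    }
    h <- y + e[[l]]
    cache$dec[[l]] <- st
  }

  out_map <- conv_index_map(shapes[[1]], 3L, 1L)
  out <- conv_forward(h, p$out, out_map)
  u <- out$y
  dim(u) <- c(shapes[[1]], 3L)
  cache$out <- out$cache
  list(u = u, cache = cache)
}

# Backpropagate a gradient w.r.t. the displacement field into gradients
# w.r.t. every network parameter.
bfcnm_backward <- function(net, cache, du) {
  cfg <- net$config
  p <- net$params
  shapes <- level_shapes(cfg)
  L <- cfg$n_levels
  bayes <- bayesian_stages(cfg)
  grads <- list()

  dy <- du
  dim(dy) <- c(prod(shapes[[1]]), 3L)
  out_map <- conv_index_map(shapes[[1]], 3L, 1L)
  bk <- conv_backward(dy, cache$out, p$out, out_map)
  grads$out <- list(W = bk$dW, b = bk$db)
  dh <- bk$dx

  de <- vector("list", L + 1L)
  for (l in seq_len(L)) {
    st <- cache$dec[[l]]
    # skip branch of the add
    de[[l]] <- if (is.null(de[[l]])) dh else de[[l]] + dh
    d <- dh
    if (l %in% bayes) {
      d <- dropout_backward(d, st$drop)
      gb <- gn_backward(d, st$gn, p[[paste0("dec", l, "_gn")]])
      grads[[paste0("dec", l, "_gn")]] <- list(gamma = gb$dgamma,
                                               beta = gb$dbeta)
      d <- gb$dx
    }
    ab <- prelu_backward(d, st$act, p[[paste0("dec", l, "_act")]])
    grads[[paste0("dec", l, "_act")]] <- list(a = ab$da)
    map1 <- conv_index_map(shapes[[l]], 3L, 1L)
    cb <- conv_backward(ab$dx, st$conv, p[[paste0("dec", l, "_conv")]], map1)
    grads[[paste0("dec", l, "_conv")]] <- list(W = cb$dW, b = cb$db)
    map <- conv_index_map(shapes[[l]], 3L, 2L)
    tb <- convt_backward(cb$dx, st$tc, p[[paste0("dec", l, "_tc")]], map)
    grads[[paste0("dec", l, "_tc")]] <- list(W = tb$dW, b = tb$db)
    dh <- tb$dx
  }
  de[[L + 1]] <- dh

  for (l in L:1) {
    d <- de[[l + 1]]
    ab <- prelu_backward(d, cache$enc[[l]]$act, p[[paste0("enc", l, "_act")]])
    grads[[paste0("enc", l, "_act")]] <- list(a = ab$da)
    map <- conv_index_map(shapes[[l]], 3L, 2L)
    cb <- conv_backward(ab$dx, cache$enc[[l]]$conv, p[[paste0("enc", l)]], map)
    grads[[paste0("enc", l)]] <- list(W = cb$dW, b = cb$db)
    de[[l]] <- if (is.null(de[[l]])) cb$dx else de[[l]] + cb$dx
  }

  ab <- prelu_backward(de[[1]], cache$inc_act, p$inc_act)
  grads$inc_act <- list(a = ab$da)
  dcat <- ab$dx
  col0 <- 0L
  for (k in cfg$inception_kernels) {
    cols <- (col0 + 1L):(col0 + cfg$base_channels)
    col0 <- col0 + cfg$base_channels
    map <- conv_index_map(shapes[[1]], k, 1L)
    cb <- conv_backward(dcat[, cols, drop = FALSE],
                        cache$inc[[as.character(k)]],
                        p[[paste0("inc", k)]], map, need_dx = FALSE)
    grads[[paste0("inc", k)]] <- list(W = cb$dW, b = cb$db)
  }
  grads
}

#' Predict a displacement field with the registration network
#'
#' Stacks the source and target volumes as a two-channel input (intensities
#' are expected on the 0-255 scale and divided by 255 internally) and runs
#' the network. With `stochastic = FALSE` (the default) dropout is off and
#' the forward pass is a pure function of the inputs and parameters; with
#' `stochastic = TRUE` the Bayesian blocks draw fresh Bernoulli dropout
#' masks, which is the sampling mechanism behind Monte Carlo Dropout
#' uncertainty.
#'
#' @param net A `bfcnm` network.
#' @param S,T Source and target `volume`s matching the configured input
#'   shape.
#' @param stochastic Keep dropout active?
#' @param seed Optional integer making a stochastic pass reproducible.
#' @return A `displacement_field`.
#' @export
predict_field <- function(net, S, T, stochastic = FALSE, seed = NULL) {
  stopifnot(inherits(net, "bfcnm"))
  S <- as_volume(S); T <- as_volume(T)
  if (!identical(dim(S), net$config$input_shape) ||
      !identical(dim(T), net$config$input_shape)) {
    stop_mcdreg("input volumes do not match the configured network shape",
                "mcdreg_shape_error")
  }
  run <- function() bfcnm_forward_cache(net, S, T, stochastic = stochastic)
  res <- if (stochastic) with_seed(seed, run()) else run()
  as_displacement_field(res$u)
}
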