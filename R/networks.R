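# Network construction, parameter counting and forward/backward passes.
#
# Architectures are declared by plain-list specs and realised as networks
# whose parameters live in an environment (so the training loop can update
# them in place). The reference specs reproduce the published trainable
# parameter totals exactly: 3,163,142 for the shallow (depth-2) generator
# plus discriminator and 4,868,614 for the depth-3 benchmark plus the same
# discriminator.

#' Generator architecture specification
#'
#' Declares a U-Net generator. The encoder has `depth` stages (one
#' convolution + batch norm + ReLU per `convs_per_stage`, then 2x2 max
#' pooling), a bottleneck stage, and a symmetric decoder built from 4x4
#' stride-2 up-convolutions whose output is concatenated with the matching
#' encoder features. Decoder convolutions keep the concatenated feature
#' width, so the decoder operates on the concatenated maps directly.
#'
#' The default feature ladder (32, 64, 128) for `depth = 2` is the
#' reference shallow generator; `unet3_spec()` gives the depth-3 benchmark.
#'
#' @param depth number of encoder/decoder stages (2 for the shallow net,
#'   3 for the benchmark).
#' @param stage_features feature counts per encoder stage plus bottleneck;
#'   length must be `depth + 1`.
#' @param convs_per_stage convolutions per encoder/bottleneck stage.
#' @param kernel_size convolution kernel size (square).
#' @param up_kernel_size transposed-convolution kernel size.
#' @param final_kernel_size kernel of the last convolution to 1 channel.
#' @param in_channels,out_channels image channels (1 and 1: single-channel
#'   MR in, single-channel synthetic CT out).
#' @param use_batch_norm include batch normalization after every
#'   convolution and up-convolution.
#' @param dropout_rate dropout rate applied after each decoder stage;
#'   following the image-to-image cGAN convention this noise source is
#'   active at training and at prediction time.
#' @return object of class `sucgan_generator_spec`.
#' @export
generator_spec <- function(depth = 2L,
                           stage_features = c(32L, 64L, 128L),
                           convs_per_stage = 1L,
                           kernel_size = 4L,
                           up_kernel_size = 4L,
                           final_kernel_size = 3L,
                           in_channels = 1L,
                           out_channels = 1L,
                           use_batch_norm = TRUE,
                           dropout_rate = 0.5) {
  depth <- as.integer(depth)
  stage_features <- as.integer(stage_features)
  if (length(stage_features) != depth + 1L)
    stop("stage_features must have length depth + 1 (stages plus bottleneck)")
  if (any(stage_features <= 0L)) stop("feature counts must be positive")
  if (convs_per_stage < 1L) stop("convs_per_stage must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(depth = depth, stage_features = stage_features,
                 convs_per_stage = as.integer(convs_per_stage),
                 kernel_size = as.integer(kernel_size),
                 up_kernel_size = as.integer(up_kernel_size),
                 final_kernel_size = as.integer(final_kernel_size),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 use_batch_norm = isTRUE(use_batch_norm),
                 dropout_rate = dropout_rate),
            class = "sucgan_generator_spec")
}

#' Reference depth-3 benchmark generator specification
#'
#' The conventional-depth U-Net generator used as benchmark: identical
#' layer recipe to the shallow generator but with three encoder/decoder
#' stages (features 32, 64, 128) and a 128-feature bottleneck.
#'
#' @inheritParams generator_spec
#' @return object of class `sucgan_generator_spec` with `depth = 3`.
#' @export
unet3_spec <- function(stage_features = c(32L, 64L, 128L, 128L), ...) {
  generator_spec(depth = 3L, stage_features = stage_features, ...)
}

#' Discriminator architecture specification
#'
#' A conditional patch discriminator: three blocks, each a pair of 3x3
#' convolution + batch norm + ReLU layers (the first convolution of every
#' block has stride 2), followed by a single convolution to one channel
#' and a sigmoid that maps the score map into \[0, 1\]. The conditional
#' input stacks the MR slice and the candidate CT slice as two channels.
#'
#' @param block_features feature counts of the three blocks.
#' @param convs_per_block convolutions per block.
#' @param kernel_size block convolution kernel size.
#' @param final_kernel_size kernel of the last convolution.
#' @param stride stride of the first convolution in each block.
#' @param conditional logical; if `TRUE` the input has 2 channels
#'   (MR + CT candidate), otherwise 1.
#' @return object of class `sucgan_discriminator_spec`.
#' @export
discriminator_spec <- function(block_features = c(94L, 188L, 376L),
                               convs_per_block = 2L,
                               kernel_size = 3L,
                               final_kernel_size = 2L,
                               stride = 2L,
                               conditional = TRUE) {
  block_features <- as.integer(block_features)
  if (length(block_features) != 3L)
    stop("a discriminator has exactly 3 blocks before the final convolution")
  structure(list(block_features = block_features,
                 convs_per_block = as.integer(convs_per_block),
                 kernel_size = as.integer(kernel_size),
                 final_kernel_size = as.integer(final_kernel_size),
                 stride = as.integer(stride),
                 conditional = isTRUE(conditional)),
            class = "sucgan_discriminator_spec")
}

# ---- architecture realisation ---------------------------------------------

layer_conv <- function(name, k, cin, cout, stride = 1L, bias = TRUE)
  list(name = name, kind = "conv", k = k, cin = cin, cout = cout,
       stride = stride, bias = bias)
layer_tconv <- function(name, k, cin, cout, bias = TRUE)
  list(name = name, kind = "tconv", k = k, cin = cin, cout = cout, bias = bias)
layer_bn <- function(name, c) list(name = name, kind = "bn", c = c)

generator_arch <- function(spec) {
  f <- spec$stage_features; d <- spec$depth
  k <- spec$kernel_size; ncs <- spec$convs_per_stage
  arch <- list()
  add <- function(l) arch[[length(arch) + 1L]] <<- l
  cin <- spec$in_channels
  for (i in seq_len(d)) {
    for (j in seq_len(ncs)) {
      add(layer_conv(sprintf("enc%d_conv%d", i, j), k, cin, f[i]))
      if (spec$use_batch_norm) add(layer_bn(sprintf("enc%d_bn%d", i, j), f[i]))
      cin <- f[i]
    }
  }
  for (j in seq_len(ncs)) {
    add(layer_conv(sprintf("bott_conv%d", j), k, cin, f[d + 1L]))
    if (spec$use_batch_norm) add(layer_bn(sprintf("bott_bn%d", j), f[d + 1L]))
    cin <- f[d + 1L]
  }
  prev <- f[d + 1L]
  for (i in rev(seq_len(d))) {
    add(layer_tconv(sprintf("up%d", i), spec$up_kernel_size, prev, f[i]))
    if (spec$use_batch_norm) add(layer_bn(sprintf("up%d_bn", i), f[i]))
    w <- 2L * f[i]                        # decoder keeps concatenated width
    add(layer_conv(sprintf("dec%d_conv1", i), k, 2L * f[i], w))
    if (spec$use_batch_norm) add(layer_bn(sprintf("dec%d_bn1", i), w))
    prev <- w
  }
  add(layer_conv("final", spec$final_kernel_size, prev, spec$out_channels))
  arch
}

discriminator_arch <- function(spec) {
  f <- spec$block_features
  cin <- if (spec$conditional) 2L else 1L
  k <- spec$kernel_size
  arch <- list()
  add <- function(l) arch[[length(arch) + 1L]] <<- l
  for (b in 1:3) {
    for (j in seq_len(spec$convs_per_block)) {
      s <- if (j == 1L) spec$stride else 1L
      add(layer_conv(sprintf("blk%d_conv%d", b, j), k, cin, f[b], stride = s))
      add(layer_bn(sprintf("blk%d_bn%d", b, j), f[b]))
      cin <- f[b]
    }
  }
  add(layer_conv("final", spec$final_kernel_size, cin, 1L))
  arch
}

alloc_params <- function(arch) {
  env <- new.env(parent = emptyenv())
  for (l in arch) {
    p <- switch(l$kind,
      conv = list(kind = "conv", w = array(0, c(l$k, l$k, l$cin, l$cout)),
                  b = if (l$bias) numeric(l$cout) else NULL),
      tconv = list(kind = "tconv", w = array(0, c(l$k, l$k, l$cout, l$cin)),
                   b = if (l$bias) numeric(l$cout) else NULL),
      bn = list(kind = "bn", gamma = rep(1, l$c), beta = numeric(l$c),
                rm = numeric(l$c), rv = rep(1, l$c)))
    assign(l$name, p, envir = env)
  }
  env
}

new_network <- function(spec, arch, type) {
  structure(list(spec = spec, arch = arch, type = type,
                 params = alloc_params(arch)),
            class = "sucgan_network")
}

#' Build the shallow U-Net generator
#'
#' @param spec a [generator_spec()] with `depth = 2`.
#' @return a `sucgan_network` generator (parameters zero-initialised; see
#'   [he_initialize()]).
#' @export
build_sunet_generator <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "sucgan_generator_spec"))
  if (spec$depth != 2L) stop("the shallow generator has encoder/decoder depth 2")
  new_network(spec, generator_arch(spec), "generator")
}

#' Build the depth-3 benchmark U-Net generator
#'
#' @param spec a [generator_spec()] with `depth = 3` (see [unet3_spec()]).
#' @return a `sucgan_network` generator.
#' @export
build_unet3_generator <- function(spec = unet3_spec()) {
  stopifnot(inherits(spec, "sucgan_generator_spec"))
  if (spec$depth != 3L) stop("the benchmark generator has encoder/decoder depth 3")
  new_network(spec, generator_arch(spec), "generator")
}

#' Build the conditional discriminator
#'
#' @param spec a [discriminator_spec()].
#' @return a `sucgan_network` discriminator.
#' @export
build_discriminator <- function(spec = discriminator_spec()) {
  stopifnot(inherits(spec, "sucgan_discriminator_spec"))
  new_network(spec, discriminator_arch(spec), "discriminator")
}

#' Count trainable parameters
#'
#' Sums convolution and up-convolution weights and biases and batch-norm
#' scale/shift parameters; batch-norm running statistics are state, not
#' trainable parameters, and are excluded.
#'
#' @param net a `sucgan_network`, or a list of networks (counted jointly,
#'   e.g. generator plus discriminator).
#' @return integer parameter count.
#' @export
count_trainable_parameters <- function(net) {
  if (inherits(net, "sucgan_network")) net <- list(net)
  tot <- 0L
  for (n in net) {
    for (name in ls(n$params)) {
      p <- get(name, envir = n$params)
      tot <- tot + switch(p$kind,
        conv = length(p$w) + length(p$b),
        tconv = length(p$w) + length(p$b),
        bn = length(p$gamma) + length(p$beta))
    }
  }
  as.integer(tot)
}

#' He initialization
#'
#' Draws every convolution and up-convolution weight from a zero-mean
#' normal with variance `2 / fan_in`, where `fan_in` is kernel area times
#' input channels. Biases start at zero, batch-norm scale at one and shift
#' at zero. Deterministic under a fixed seed; the caller's RNG state is
#' left untouched.
#'
#' @param net a `sucgan_network`.
#' @param seed integer seed.
#' @return the initialised network (parameters are updated in place).
#' @export
he_initialize <- function(net, seed) {
  stopifnot(inherits(net, "sucgan_network"))
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (l in net$arch) {
      p <- get(l$name, envir = net$params)
      if (p$kind %in% c("conv", "tconv")) {
        fan_in <- l$k * l$k * l$cin
        p$w[] <- stats::rnorm(length(p$w), 0, sqrt(2 / fan_in))
        if (!is.null(p$b)) p$b[] <- 0
      } else {
        p$gamma[] <- 1; p$beta[] <- 0; p$rm[] <- 0; p$rv[] <- 1
      }
      assign(l$name, p, envir = net$params)
    }
  })
  invisible(net)
}

# ---- forward / backward ----------------------------------------------------

get_p <- function(net, name) get(name, envir = net$params)
set_p <- function(net, name, p) assign(name, p, envir = net$params)

# conv (+ optional bn + optional relu); records cache under `name` in `st`
fwd_conv_unit <- function(net, name, bn_name, x, stride, training, st,
                          activation = TRUE, bn_batch = training) {
  p <- get_p(net, name)
  cf <- conv2d_forward(x, p$w, p$b, stride, keep_cols = training)
  out <- cf$out
  cache <- list(conv = cf$cache)
  if (!is.null(bn_name)) {
    bp <- get_p(net, bn_name)
    bf <- batchnorm_forward(out, bp$gamma, bp$beta, bp$rm, bp$rv, bn_batch)
    out <- bf$out
    cache$bn <- bf$cache
    if (training) {
      bp$rm <- bf$run_mean; bp$rv <- bf$run_var
      set_p(net, bn_name, bp)
    }
  }
  if (activation) {
    cache$pre_relu <- out
    out <- relu(out)
  }
  if (!is.null(st)) st[[name]] <- cache
  out
}

bwd_conv_unit <- function(net, name, bn_name, dout, st, grads,
                          activation = TRUE) {
  cache <- st[[name]]
  if (activation) dout <- dout * (cache$pre_relu > 0)
  if (!is.null(bn_name)) {
    bp <- get_p(net, bn_name)
    bb <- batchnorm_backward(dout, bp$gamma, cache$bn)
    grads[[bn_name]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    dout <- bb$dx
  }
  p <- get_p(net, name)
  cb <- conv2d_backward(dout, p$w, cache$conv)
  grads[[name]] <- list(w = cb$dw, b = cb$db)
  cb$dx
}

check_gen_input <- function(spec, d) {
  div <- 2L^spec$depth
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("input %dx%d not divisible by %d (encoder/decoder depth %d)",
                 d[1], d[2], div, spec$depth))
}

# Generator forward. `x` is (H, W, in_channels). Returns list(out, cache).
# Dropout is a noise source active in training and, by default, at
# prediction (pass use_dropout = FALSE to disable).
forward_generator <- function(net, x, training = FALSE,
                              use_dropout = training || net$spec$dropout_rate > 0,
                              bn_batch = TRUE) {
  spec <- net$spec
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  check_gen_input(spec, dim(x))
  bn <- spec$use_batch_norm
  st <- if (training) new.env(parent = emptyenv()) else NULL
  skips <- vector("list", spec$depth)
  cur <- x
  for (i in seq_len(spec$depth)) {
    for (j in seq_len(spec$convs_per_stage))
      cur <- fwd_conv_unit(net, sprintf("enc%d_conv%d", i, j),
                           if (bn) sprintf("enc%d_bn%d", i, j), cur, 1L,
                           training, st, bn_batch = bn_batch)
    skips[[i]] <- cur
    mp <- maxpool2_forward(cur)
    if (training) st[[sprintf("pool%d", i)]] <- mp$cache
    cur <- mp$out
  }
  for (j in seq_len(spec$convs_per_stage))
    cur <- fwd_conv_unit(net, sprintf("bott_conv%d", j),
                         if (bn) sprintf("bott_bn%d", j), cur, 1L, training, st,
                         bn_batch = bn_batch)
  for (i in rev(seq_len(spec$depth))) {
    p <- get_p(net, sprintf("up%d", i))
    tf <- tconv2d_forward(cur, p$w, p$b)
    cur <- tf$out
    cache <- list(tconv = tf$cache)
    if (bn) {
      bname <- sprintf("up%d_bn", i)
      bp <- get_p(net, bname)
      bf <- batchnorm_forward(cur, bp$gamma, bp$beta, bp$rm, bp$rv, bn_batch)
      cur <- bf$out
      cache$bn <- bf$cache
      if (training) { bp$rm <- bf$run_mean; bp$rv <- bf$run_var; set_p(net, bname, bp) }
    }
    cache$pre_relu <- cur
    cur <- relu(cur)
    if (training) st[[sprintf("up%d", i)]] <- cache
    n_up <- dim(cur)[3]
    cur <- abind3(cur, skips[[i]])
    cur <- fwd_conv_unit(net, sprintf("dec%d_conv1", i),
                         if (bn) sprintf("dec%d_bn1", i), cur, 1L, training, st,
                         bn_batch = bn_batch)
    if (use_dropout && spec$dropout_rate > 0) {
      df <- dropout_forward(cur, spec$dropout_rate)
      cur <- df$out
      if (training) st[[sprintf("drop%d", i)]] <- df$cache
    }
    if (training) st[[sprintf("split%d", i)]] <- n_up
  }
  out <- fwd_conv_unit(net, "final", NULL, cur, 1L, training, st,
                       activation = FALSE)
  list(out = out, cache = st)
}

backward_generator <- function(net, cache, dout) {
  spec <- net$spec
  bn <- spec$use_batch_norm
  grads <- new.env(parent = emptyenv())
  cur <- bwd_conv_unit(net, "final", NULL, dout, cache, grads,
                       activation = FALSE)
  dskips <- vector("list", spec$depth)
  for (i in seq_len(spec$depth)) {
    dc <- cache[[sprintf("drop%d", i)]]
    if (!is.null(dc)) cur <- dropout_backward(cur, dc)
    cur <- bwd_conv_unit(net, sprintf("dec%d_conv1", i),
                         if (bn) sprintf("dec%d_bn1", i), cur, cache, grads)
    n_up <- cache[[sprintf("split%d", i)]]
    dskips[[i]] <- cur[, , (n_up + 1L):dim(cur)[3], drop = FALSE]
    cur <- cur[, , seq_len(n_up), drop = FALSE]
    ucache <- cache[[sprintf("up%d", i)]]
    cur <- cur * (ucache$pre_relu > 0)
    if (bn) {
      bname <- sprintf("up%d_bn", i)
      bp <- get_p(net, bname)
      bb <- batchnorm_backward(cur, bp$gamma, ucache$bn)
      grads[[bname]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      cur <- bb$dx
    }
    p <- get_p(net, sprintf("up%d", i))
    tb <- tconv2d_backward(cur, p$w, ucache$tconv)
    grads[[sprintf("up%d", i)]] <- list(w = tb$dw, b = tb$db)
    cur <- tb$dx
  }
  for (j in rev(seq_len(spec$convs_per_stage)))
    cur <- bwd_conv_unit(net, sprintf("bott_conv%d", j),
                         if (bn) sprintf("bott_bn%d", j), cur, cache, grads)
  for (i in rev(seq_len(spec$depth))) {
    cur <- maxpool2_backward(cur, cache[[sprintf("pool%d", i)]])
    cur <- cur + dskips[[i]]
    for (j in rev(seq_len(spec$convs_per_stage)))
      cur <- bwd_conv_unit(net, sprintf("enc%d_conv%d", i, j),
                           if (bn) sprintf("enc%d_bn%d", i, j), cur, cache, grads)
  }
  list(grads = grads, dx = cur)
}

# Discriminator forward: returns sigmoid score map, pre-sigmoid logits and
# cache. Input is (H, W, 2) for the conditional discriminator.
forward_discriminator <- function(net, x, training = FALSE) {
  spec <- net$spec
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  want <- if (spec$conditional) 2L else 1L
  if (dim(x)[3] != want)
    stop(sprintf("discriminator expects %d input channel(s), got %d",
                 want, dim(x)[3]))
  st <- if (training) new.env(parent = emptyenv()) else NULL
  cur <- x
  for (b in 1:3) for (j in seq_len(spec$convs_per_block)) {
    s <- if (j == 1L) spec$stride else 1L
    cur <- fwd_conv_unit(net, sprintf("blk%d_conv%d", b, j),
                         sprintf("blk%d_bn%d", b, j), cur, s, training, st)
  }
  z <- fwd_conv_unit(net, "final", NULL, cur, 1L, training, st,
                     activation = FALSE)
  list(score = sigmoid(z), z = z, cache = st)
}

backward_discriminator <- function(net, cache, dz) {
  spec <- net$spec
  grads <- new.env(parent = emptyenv())
  cur <- bwd_conv_unit(net, "final", NULL, dz, cache, grads, activation = FALSE)
  for (b in 3:1) for (j in rev(seq_len(spec$convs_per_block)))
    cur <- bwd_conv_unit(net, sprintf("blk%d_conv%d", b, j),
                         sprintf("blk%d_bn%d", b, j), cur, cache, grads)
  list(grads = grads, dx = cur)
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1] == db[1], da[2] == db[2])
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

#' @export
print.sucgan_network <- function(x, ...) {
  cat(sprintf("<sucgan %s: %d layers, %s trainable parameters>\n",
              x$type, length(x$arch),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- spec serialization & checkpoints --------------------------------------

#' Write or read a network spec as JSON
#'
#' @param spec a generator or discriminator spec.
#' @param path file path.
#' @return `read_spec` returns the spec object.
#' @export
write_spec <- function(spec, path) {
  kind <- if (inherits(spec, "sucgan_generator_spec")) "generator" else "discriminator"
  jsonlite::write_json(c(list(.kind = kind), unclass(spec)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$.kind; x$.kind <- NULL
  if (identical(kind, "generator")) do.call(generator_spec, x)
  else do.call(discriminator_spec, x)
}

#' Save or load a network checkpoint
#'
#' The checkpoint embeds the architecture spec, so a saved file is
#' self-describing and can be reloaded without external context.
#'
#' @param net a `sucgan_network`.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the network.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(spec = net$spec, type = net$type,
               params = as.list(net$params)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  net <- if (identical(x$type, "generator")) {
    if (x$spec$depth == 2L) build_sunet_generator(x$spec) else build_unet3_generator(x$spec)
  } else build_discriminator(x$spec)
  for (name in names(x$params)) assign(name, x$params[[name]], envir = net$params)
  net
}
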