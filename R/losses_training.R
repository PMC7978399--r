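# Adversarial and L1 objectives and the alternating generator /
# discriminator training loop.
#
# The discriminator is trained to minimise
#   -[log D(x|y) + log(1 - D(G(y)|y))]
# and the generator minimises the non-saturating adversarial term
#   -log D(G(y)|y)
# (identical fixed points to the min-max form, better-behaved gradients)
# plus lambda times the L1 distance between the generated and the measured
# CT slice. Scores are clamped away from {0, 1} by a small epsilon before
# taking logarithms.

SCORE_EPS <- 1e-7

#' Training configuration
#'
#' Hyperparameters of the adversarial training protocol: L1 weight
#' `lambda_l1 = 100`, minibatch size 1, 200 epochs, Adam with learning
#' rate 2e-4 and moment decays (0.5, 0.999), and left/right flip
#' augmentation. The CT intensity scale maps normalized generator output
#' back to Hounsfield Units; it is fixed (default -1024..3071 HU) so that
#' prediction never depends on the held-out subject's CT.
#'
#' @param lambda_l1 non-negative weight of the L1 term.
#' @param epochs number of passes over the slice pool.
#' @param minibatch minibatch size (the protocol uses 1).
#' @param optimizer list with `lr`, `beta1`, `beta2`, `eps`.
#' @param seed integer seed driving shuffling and dropout.
#' @param augment_flip add left/right-flipped copies to the slice pool.
#' @param ct_scale an [intensity_scale()] for CT normalization and
#'   synthetic-CT HU recovery.
#' @param device informational label (computation is CPU BLAS).
#' @return object of class `train_config`.
#' @export
train_config <- function(lambda_l1 = 100,
                         epochs = 200L,
                         minibatch = 1L,
                         optimizer = list(lr = 2e-4, beta1 = 0.5,
                                          beta2 = 0.999, eps = 1e-8),
                         seed = 1L,
                         augment_flip = TRUE,
                         ct_scale = intensity_scale(-1024, 3071),
                         device = "cpu") {
  if (lambda_l1 < 0) stop("lambda_l1 must be non-negative")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (minibatch < 1L) stop("minibatch must be >= 1")
  stopifnot(inherits(ct_scale, "intensity_scale"))
  structure(list(lambda_l1 = lambda_l1, epochs = as.integer(epochs),
                 minibatch = as.integer(minibatch), optimizer = optimizer,
                 seed = as.integer(seed), augment_flip = isTRUE(augment_flip),
                 ct_scale = ct_scale, device = device),
            class = "train_config")
}

#' L1 reconstruction term
#'
#' Mean absolute difference between a measured CT slice and a generated
#' slice.
#'
#' @param x measured slice/volume (array).
#' @param gx generated slice/volume of the same shape.
#' @return non-negative scalar.
#' @export
l1_term <- function(x, gx) {
  if (!identical(dim(x) %||% length(x), dim(gx) %||% length(gx)))
    stop("shape mismatch between measured and generated slices")
  mean(abs(x - gx))
}

#' Discriminator loss
#'
#' `-[log d_real + log(1 - d_fake)]`, averaged over the score map, i.e.
#' the minimisation form of the adversarial objective for the
#' discriminator. Scores are clamped to `(eps, 1 - eps)`.
#'
#' @param d_real,d_fake discriminator scores (scalars or score maps) in
#'   (0, 1).
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  dr <- clamp(d_real, SCORE_EPS, 1 - SCORE_EPS)
  df <- clamp(d_fake, SCORE_EPS, 1 - SCORE_EPS)
  -(mean(log(dr)) + mean(log(1 - df)))
}

#' Generator adversarial loss
#'
#' Non-saturating form `-log d_fake`, averaged over the score map.
#'
#' @param d_fake discriminator score(s) for generated output.
#' @return scalar loss.
#' @export
generator_adversarial_loss <- function(d_fake) {
  -mean(log(clamp(d_fake, SCORE_EPS, 1 - SCORE_EPS)))
}

#' Total generator loss
#'
#' `adv + lambda_l1 * l1`: the adversarial term plus the weighted L1
#' reconstruction term.
#'
#' @param adv adversarial loss scalar.
#' @param l1 L1 term scalar.
#' @param lambda_l1 weight.
#' @return scalar.
#' @export
total_generator_loss <- function(adv, l1, lambda_l1) adv + lambda_l1 * l1

# ---- Adam ------------------------------------------------------------------

ensure_opt_state <- function(net) {
  if (is.null(net$opt_env)) {
    e <- new.env(parent = emptyenv())
    assign(".t", 0L, envir = e)
    net$opt_env <- e
  }
  net
}

adam_update <- function(net, grads, opt) {
  st <- net$opt_env
  t <- get(".t", envir = st) + 1L
  assign(".t", t, envir = st)
  bc1 <- 1 - opt$beta1^t
  bc2 <- 1 - opt$beta2^t
  for (name in ls(grads)) {
    g <- get(name, envir = grads)
    p <- get_p(net, name)
    key <- paste0(".mv_", name)
    mv <- if (exists(key, envir = st)) get(key, envir = st)
          else lapply(g, function(x) list(m = 0 * x, v = 0 * x))
    for (comp in names(g)) {
      gi <- g[[comp]]
      m <- opt$beta1 * mv[[comp]]$m + (1 - opt$beta1) * gi
      v <- opt$beta2 * mv[[comp]]$v + (1 - opt$beta2) * gi^2
      mv[[comp]] <- list(m = m, v = v)
      p[[comp]] <- p[[comp]] - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    }
    assign(key, mv, envir = st)
    set_p(net, name, p)
  }
  invisible(net)
}

# ---- slice pool ------------------------------------------------------------

# Normalized training pairs: MR per-volume min-max to [0,1]; CT with the
# fixed global scale so training targets and prediction share one HU map.
build_slice_pool <- function(cases, config) {
  pool <- list()
  lo <- config$ct_scale$lo; hi <- config$ct_scale$hi
  for (case in cases) {
    mrn <- normalize_to_unit(case$mr)$volume$data
    ctn <- clamp((case$ct$data - lo) / (hi - lo), 0, 1)
    S <- dim(mrn)[3]
    for (s in seq_len(S)) {
      pool[[length(pool) + 1L]] <- list(mr = mrn[, , s], ct = ctn[, , s],
                                        subject_id = case$subject_id)
      if (config$augment_flip) {
        rev1 <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
        pool[[length(pool) + 1L]] <- list(mr = rev1(mrn[, , s]),
                                          ct = rev1(ctn[, , s]),
                                          subject_id = case$subject_id)
      }
    }
  }
  pool
}

# ---- training loop ---------------------------------------------------------

#' Train the conditional GAN
#'
#' Alternating optimisation with minibatch 1: for every slice in the
#' shuffled pool, one discriminator update (real and generated pairs) is
#' followed by one generator update (adversarial + weighted L1). The slice
#' pool contains every transverse slice of every case, plus left/right
#' flipped copies when `config$augment_flip` is on, and is reshuffled each
#' epoch under the seeded generator.
#'
#' @param gen an initialised generator (`sucgan_network`).
#' @param disc an initialised discriminator.
#' @param cases list of [paired_case()] training subjects.
#' @param config a [train_config()].
#' @return list with elements `generator`, `discriminator` and `history`
#'   (a tibble with one row per generator step: epoch, iteration,
#'   discriminator loss, generator adversarial loss, L1 term, total
#'   generator loss).
#' @export
train <- function(gen, disc, cases, config = train_config()) {
  stopifnot(inherits(gen, "sucgan_network"), gen$type == "generator",
            inherits(disc, "sucgan_network"), disc$type == "discriminator",
            inherits(config, "train_config"))
  pool <- build_slice_pool(cases, config)
  if (!length(pool)) stop("empty slice pool: no training slices")
  gen <- ensure_opt_state(gen)
  disc <- ensure_opt_state(disc)
  opt <- config$optimizer
  lambda <- config$lambda_l1
  n_pool <- length(pool)
  hist <- vector("list", config$epochs * n_pool)
  r <- 0L
  with_preserved_rng({
    set.seed(config$seed)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_pool)
      for (idx in ord) {
        mr <- pool[[idx]]$mr; ct <- pool[[idx]]$ct
        mr3 <- array(mr, c(dim(mr), 1L))
        ct3 <- array(ct, c(dim(ct), 1L))

        gf <- forward_generator(gen, mr3, training = TRUE)
        fake <- gf$out

        # --- discriminator step ---
        fr <- forward_discriminator(disc, abind3(mr3, ct3), training = TRUE)
        n_map <- length(fr$z)
        dz_real <- (fr$score - 1) / n_map
        br <- backward_discriminator(disc, fr$cache, dz_real)
        ff <- forward_discriminator(disc, abind3(mr3, fake), training = TRUE)
        dz_fake <- ff$score / n_map
        bf <- backward_discriminator(disc, ff$cache, dz_fake)
        dgrads <- br$grads
        for (nm in ls(bf$grads)) {
          ga <- get(nm, envir = dgrads); gb <- get(nm, envir = bf$grads)
          assign(nm, Map(`+`, ga, gb), envir = dgrads)
        }
        d_loss <- discriminator_loss(fr$score, ff$score)
        adam_update(disc, dgrads, opt)

        # --- generator step ---
        fg <- forward_discriminator(disc, abind3(mr3, fake), training = TRUE)
        adv <- generator_adversarial_loss(fg$score)
        l1 <- l1_term(ct3, fake)
        g_total <- total_generator_loss(adv, l1, lambda)
        if (!is.finite(g_total) || !is.finite(d_loss))
          stop(sprintf("non-finite loss at epoch %d (D=%g, G=%g): aborting",
                       epoch, d_loss, g_total))
        dz <- (fg$score - 1) / length(fg$z)
        bd <- backward_discriminator(disc, fg$cache, dz)
        dfake <- bd$dx[, , 2L, drop = FALSE] +
          lambda * sign(fake - ct3) / length(fake)
        bg <- backward_generator(gen, gf$cache, dfake)
        adam_update(gen, bg$grads, opt)

        r <- r + 1L
        hist[[r]] <- c(epoch = epoch, iter = r, d_loss = d_loss,
                       g_adv = adv, l1 = l1, g_total = g_total)
      }
    }
  })
  history <- tibble::as_tibble(do.call(rbind, hist))
  list(generator = gen, discriminator = disc, history = history)
}

#' Predict a synthetic CT volume
#'
#' Runs the trained generator slice by slice on the normalized MR volume,
#' restacks the output and maps it to Hounsfield Units with the fixed CT
#' intensity scale. Dropout, when enabled (the default, following the
#' image-to-image cGAN noise model), is driven by `seed`, making the
#' prediction reproducible.
#'
#' @param gen trained generator.
#' @param mr MR [voxel_volume()].
#' @param ct_scale an [intensity_scale()] mapping normalized output to HU.
#' @param use_dropout keep the dropout noise source active at prediction.
#' @param seed seed for the dropout noise.
#' @return a synthetic-CT [voxel_volume()] (modality `"SCT"`, HU domain).
#' @export
predict_volume <- function(gen, mr, ct_scale = intensity_scale(-1024, 3071),
                           use_dropout = TRUE, seed = 1L) {
  stopifnot(inherits(gen, "sucgan_network"), gen$type == "generator",
            inherits(mr, "voxel_volume"))
  mrn <- normalize_to_unit(mr)$volume$data
  d <- dim(mrn)
  out <- array(0, d)
  with_preserved_rng({
    set.seed(as.integer(seed))
    for (s in seq_len(d[3])) {
      x <- array(mrn[, , s], c(d[1], d[2], 1L))
      f <- forward_generator(gen, x, training = FALSE,
                             use_dropout = use_dropout)
      out[, , s] <- f$out[, , 1L]
    }
  })
  sct <- voxel_volume(out * (ct_scale$hi - ct_scale$lo) + ct_scale$lo,
                      mr$spacing_mm, "SCT", "HU")
  sct
}
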