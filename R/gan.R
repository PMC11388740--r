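# Style-transfer GAN for synthesising covered frames: the generator takes
# an uncovered frame, a covered style reference and a noise vector; the
# patch discriminator scores overlapping regions of real versus synthetic
# covered frames.  Implemented at a configurable width so it trains at
# smoke scale on one CPU.  Note that in the reference training recipe the
# statistical augmentation outperformed GAN synthesis, so this module is
# excluded from the default training path and provided for comparison
# experiments.

.gan_width <- function(width_multiplier) max(2L, as.integer(round(8 * width_multiplier)))

.inception_block <- function(cin, c) {
  # classic parallel 1x1 / 3x3 / 5x5 / pooled branches, concatenated
  nn_parcat(
    nn_seq(nn_conv(1, 1, cin, c, pad = 0), nn_bn(c), nn_act("selu")),
    nn_seq(nn_conv(3, 3, cin, c), nn_bn(c), nn_act("selu")),
    nn_seq(nn_conv(5, 5, cin, c), nn_bn(c), nn_act("selu")),
    nn_seq(nn_pool("max", 3), nn_conv(1, 1, cin, c, pad = 0), nn_bn(c),
           nn_act("selu")))
}

.res_block <- function(c) {
  nn_seq(nn_res(nn_seq(nn_conv(3, 3, c, c), nn_bn(c), nn_act("selu"),
                       nn_conv(3, 3, c, c), nn_bn(c))),
         nn_act("selu"))
}

#' Build the cover-synthesis generator
#'
#' Structure: a noise vector (uniform in `[-0.5, 0.5]`) is linearly
#' transformed and reshaped into a map of the input's shape, concatenated
#' with the uncovered frame and encoded with a 3x3 convolution; the style
#' reference is encoded with a 7x7 convolution and pooled in parallel with
#' 5x5 stride-1 average and max pooling (a summary of its intensity
#' distribution without fine detail); the merged trunk runs an inception
#' block, a 3x3 convolution, five residual blocks and two final 3x3
#' convolutions.  Batch normalisation and SELU follow every convolution
#' except the output layer; all convolutions are stride 1 with
#' shape-preserving padding.
#'
#' @param height,width Frame dimensions the generator operates on.
#' @param width_multiplier Channel-width multiplier (1 gives base width 8).
#' @param noise_dim Length of the input noise vector.
#' @param seed Weight-initialisation seed.
#' @return An object of class `gan_generator`.
#' @export
build_generator <- function(height = 160, width = 120,
                            width_multiplier = 0.25, noise_dim = 64L,
                            seed = 0L) {
  stopifnot(width_multiplier > 0)
  c <- .gan_width(width_multiplier)
  spec <- list(
    noise = nn_seq(nn_linear(as.integer(noise_dim),
                             as.integer(height * width))),
    enc = nn_seq(nn_conv(3, 3, 2, c), nn_bn(c), nn_act("selu")),
    style = nn_seq(nn_conv(7, 7, 1, c), nn_bn(c), nn_act("selu"),
                   nn_parcat(nn_seq(nn_pool("avg", 5)),
                             nn_seq(nn_pool("max", 5)))),
    trunk = nn_seq(
      .inception_block(3L * c, c),
      nn_conv(3, 3, 4L * c, 2L * c), nn_bn(2L * c), nn_act("selu"),
      .res_block(2L * c), .res_block(2L * c), .res_block(2L * c),
      .res_block(2L * c), .res_block(2L * c),
      nn_conv(3, 3, 2L * c, c), nn_bn(c), nn_act("selu"),
      nn_conv(3, 3, c, 1)))
  params <- NULL
  with_seed(seed, params <- lapply(spec, nn_init))
  state <- lapply(spec, nn_state_init)
  structure(list(height = height, width = width, c = c,
                 noise_dim = as.integer(noise_dim), spec = spec,
                 params = params, state = state),
            class = "gan_generator")
}

#' Sample a generator noise vector
#'
#' @param n Batch size.
#' @param noise_dim Vector length.
#' @param seed RNG seed.
#' @return `noise_dim x n` matrix, uniform in `[-0.5, 0.5]`.
#' @export
gan_noise <- function(n, noise_dim = 64L, seed = 0L) {
  with_seed(seed, matrix(runif(noise_dim * n, -0.5, 0.5), noise_dim, n))
}

.gen_forward <- function(gen, xu, xc, noise, training = FALSE) {
  d <- dim(xu)
  if (!identical(dim(xu), dim(xc)))
    stop("uncovered and style frames must share one shape")
  rn <- nn_forward(gen$spec$noise, gen$params$noise, gen$state$noise,
                   noise, training)
  nmap <- array(rn$y, dim = c(d[1], d[2], 1, d[4]))
  xcat <- cat_channels(xu, nmap)
  re <- nn_forward(gen$spec$enc, gen$params$enc, gen$state$enc, xcat,
                   training)
  rs <- nn_forward(gen$spec$style, gen$params$style, gen$state$style, xc,
                   training)
  tcat <- cat_channels(re$y, rs$y)
  rt <- nn_forward(gen$spec$trunk, gen$params$trunk, gen$state$trunk,
                   tcat, training)
  list(xs = rt$y,
       cache = list(noise = rn$cache, enc = re$cache, style = rs$cache,
                    trunk = rt$cache, c_enc = dim(re$y)[3], d = d),
       state = list(noise = rn$state, enc = re$state, style = rs$state,
                    trunk = rt$state))
}

.gen_backward <- function(gen, cache, gxs) {
  rt <- nn_backward(gen$spec$trunk, gen$params$trunk, cache$trunk, gxs)
  ce <- cache$c_enc
  g_e <- slice_channels(rt$gx, 1L, ce)
  g_s <- slice_channels(rt$gx, ce + 1L, dim(rt$gx)[3])
  re <- nn_backward(gen$spec$enc, gen$params$enc, cache$enc, g_e)
  rs <- nn_backward(gen$spec$style, gen$params$style, cache$style, g_s)
  g_nmap <- slice_channels(re$gx, 2L, 2L)
  d <- cache$d
  g_nvec <- matrix(g_nmap, d[1] * d[2], d[4])
  rn <- nn_backward(gen$spec$noise, gen$params$noise, cache$noise, g_nvec)
  list(noise = rn$grads, enc = re$grads, style = rs$grads,
       trunk = rt$grads)
}

#' Build the GAN patch discriminator
#'
#' An initial 3x3 convolution, an inception block, then six 3x3
#' convolutions (four strided) reducing the input to a score map
#' one-sixteenth its size (e.g. 160x128 -> 10x8); batch norm + SELU follow
#' every convolution except the last.  Trained to output all ones on real
#' covered frames and all zeros on synthetic ones.
#'
#' @param height,width Input dimensions; both must be divisible by 16
#'   (pad the frame first, e.g. with [pad_frame_width()], if not).
#' @param width_multiplier Channel-width multiplier.
#' @param seed Weight-initialisation seed.
#' @return An object of class `gan_discriminator`.
#' @export
build_gan_discriminator <- function(height = 160, width = 128,
                                    width_multiplier = 0.25, seed = 0L) {
  if (height %% 16 != 0 || width %% 16 != 0)
    stop("discriminator input must be divisible by 16; pad the frame ",
         "(see pad_frame_width) before scoring")
  c <- .gan_width(width_multiplier)
  spec <- nn_seq(
    nn_conv(3, 3, 1, c), nn_bn(c), nn_act("selu"),
    .inception_block(c, c),
    nn_conv(3, 3, 4L * c, 2L * c, stride = 2), nn_bn(2L * c), nn_act("selu"),
    nn_conv(3, 3, 2L * c, 2L * c, stride = 2), nn_bn(2L * c), nn_act("selu"),
    nn_conv(3, 3, 2L * c, 4L * c, stride = 2), nn_bn(4L * c), nn_act("selu"),
    nn_conv(3, 3, 4L * c, 4L * c, stride = 2), nn_bn(4L * c), nn_act("selu"),
    nn_conv(3, 3, 4L * c, 4L * c), nn_bn(4L * c), nn_act("selu"),
    nn_conv(3, 3, 4L * c, 1))
  params <- NULL
  with_seed(seed, params <- nn_init(spec))
  state <- nn_state_init(spec)
  structure(list(height = height, width = width, c = c, spec = spec,
                 params = params, state = state),
            class = "gan_discriminator")
}

#' Reflect-pad a frame's width to a multiple of 16
#'
#' @param px Matrix or `(H, W, C, N)` array.
#' @return The padded object (width rounded up to a multiple of 16).
#' @export
pad_frame_width <- function(px) {
  w <- if (is.matrix(px)) ncol(px) else dim(px)[2]
  target <- 16 * ceiling(w / 16)
  if (target == w) return(px)
  extra <- target - w
  idx <- c(seq_len(w), w - seq_len(extra))  # reflect right edge
  if (is.matrix(px)) px[, idx] else px[, idx, , , drop = FALSE]
}

#' Composite generator loss
#'
#' `LG = g1 + g2 + g3 + g4` with `g1` the MSE between the discriminator's
#' map on the synthetic frame and all ones, `g2` the MSE between the
#' synthetic frame and the uncovered frame scaled by the covered/uncovered
#' mean-intensity ratio, and `g3`/`g4` the squared differences between the
#' per-frame mean/standard deviation of the synthetic frame and the style
#' reference.
#'
#' @param xs,xu,xc `(H, W, 1, N)` arrays: synthetic, uncovered, style.
#' @param disc_out Discriminator map on `xs`, or NULL during the
#'   generator-only warm-up (then `g1 = 0`).
#' @return A list with `g1`, `g2`, `g3`, `g4`, `total`.
#' @export
generator_loss <- function(xs, xu, xc, disc_out = NULL) {
  stopifnot(identical(dim(xs), dim(xu)), identical(dim(xs), dim(xc)))
  N <- dim(xs)[4]
  P <- dim(xs)[1] * dim(xs)[2]
  mu_u <- apply(xu, 4, mean)
  if (any(mu_u == 0)) stop("uncovered frame has zero mean intensity")
  mu_c <- apply(xc, 4, mean)
  mu_s <- apply(xs, 4, mean)
  sd_p <- function(a) apply(a, 4, function(m) sqrt(mean((m - mean(m))^2)))
  sd_c <- sd_p(xc)
  sd_s <- sd_p(xs)
  ratio <- array(rep(mu_c / mu_u, each = P), dim = dim(xs))
  g2 <- mean((xs - xu * ratio)^2)
  g3 <- mean((mu_s - mu_c)^2)
  g4 <- mean((sd_s - sd_c)^2)
  g1 <- if (is.null(disc_out)) 0 else mean((disc_out - 1)^2)
  list(g1 = g1, g2 = g2, g3 = g3, g4 = g4, total = g1 + g2 + g3 + g4)
}

# Gradient of (g2 + g3 + g4) with respect to xs.
.generator_loss_grad <- function(xs, xu, xc) {
  d <- dim(xs)
  N <- d[4]; P <- d[1] * d[2]
  mu_u <- apply(xu, 4, mean)
  mu_c <- apply(xc, 4, mean)
  mu_s <- apply(xs, 4, mean)
  sd_p <- function(a) apply(a, 4, function(m) sqrt(mean((m - mean(m))^2)))
  sd_c <- sd_p(xc)
  sd_s <- sd_p(xs)
  ratio <- array(rep(mu_c / mu_u, each = P), dim = d)
  g <- 2 * (xs - xu * ratio) / (P * N)                       # d g2
  g <- g + array(rep(2 * (mu_s - mu_c) / (P * N), each = P), dim = d)
  mu_rep <- array(rep(mu_s, each = P), dim = d)
  sd_rep <- array(rep(pmax(sd_s, 1e-8), each = P), dim = d)
  dsd <- (xs - mu_rep) / (P * sd_rep)
  g + array(rep(2 * (sd_s - sd_c) / N, each = P), dim = d) * dsd
}

#' GAN discriminator loss
#'
#' `LD = 0.5 * (MSE(D(real), 1) + MSE(D(synthetic), 0))`.
#'
#' @param out_real Discriminator map on real covered frames.
#' @param out_synth Discriminator map on synthetic frames.
#' @return Non-negative scalar.
#' @export
gan_discriminator_loss <- function(out_real, out_synth) {
  if (!identical(dim(out_real), dim(out_synth)))
    stop("discriminator maps differ in shape")
  0.5 * (mean((out_real - 1)^2) + mean(out_synth^2))
}

#' Synthesise a covered frame
#'
#' @param gen A trained [build_generator()].
#' @param xu Uncovered [ir_frame()].
#' @param xc Covered style-reference [ir_frame()].
#' @param seed Noise seed (two different seeds give two different outputs).
#' @return An [ir_frame()] with `cover = "synthetic"`, clipped to `[0, 1]`.
#' @details Batch-norm layers use batch statistics at synthesis time (the
#'   usual choice for generative models, whose outputs are produced under
#'   the same normalisation they were trained with); the generator's
#'   stored running statistics are left untouched.
#' @export
gan_synthesize <- function(gen, xu, xc, seed = 0L) {
  xua <- array(xu$pixels, dim = c(nrow(xu$pixels), ncol(xu$pixels), 1, 1))
  xca <- array(xc$pixels, dim = dim(xua))
  z <- gan_noise(1, gen$noise_dim, seed)
  xs <- .gen_forward(gen, xua, xca, z, training = TRUE)$xs
  ir_frame(pmin(pmax(xs[, , 1, 1], 0), 1), cover = "synthetic")
}

#' Train the GAN
#'
#' Random uncovered/covered frame pairs feed the generator.  Phase A
#' trains the generator alone on `g2 + g3 + g4` (no adversarial term) for
#' `epochs_solo` epochs; phase B alternates discriminator and generator
#' updates for `epochs_tandem` more.  AdamW with initial learning rate
#' `lr`, decayed by `lr_decay` after every epoch.
#'
#' @param manifest Manifest with uncovered and covered training frames.
#' @param config Configuration (uses the `gan` block of
#'   [default_config()]).
#' @param verbose Print per-epoch losses.
#' @return A list with `generator`, `discriminator` and `history` (one row
#'   per epoch: epoch, phase, g1-g4, lg, ld, lr).
#' @export
train_gan <- function(manifest, config = default_config(), verbose = FALSE) {
  gcf <- config$gan
  seed <- derive_seed(config$seed, "gan")
  recs <- manifest$records[manifest$records$split == "train", ]
  xu_names <- recs$image[recs$cover == "none"]
  xc_names <- recs$image[recs$cover %in% c("thin", "thick")]
  if (length(xc_names) == 0) stop("manifest has no covered frames")
  if (length(xu_names) == 0) stop("manifest has no uncovered frames")
  get_px <- function(nm) read_frame(file.path(manifest$dir, nm))$pixels
  xu_all <- lapply(xu_names, function(nm) pad_frame_width(get_px(nm)))
  xc_all <- lapply(xc_names, function(nm) pad_frame_width(get_px(nm)))
  H <- nrow(xu_all[[1]]); W <- ncol(xu_all[[1]])

  gen <- build_generator(H, W, gcf$width_multiplier, gcf$noise_dim,
                         seed = derive_seed(seed, "g-init"))
  disc <- build_gan_discriminator(H, W, gcf$width_multiplier,
                                  seed = derive_seed(seed, "d-init"))
  opt_g <- lapply(gen$params, adamw_init)
  opt_d <- adamw_init(disc$params)
  tg <- 0; td <- 0
  hist <- NULL
  total_epochs <- gcf$epochs_solo + gcf$epochs_tandem
  bs <- gcf$batch_size

  make_batch <- function() {
    iu <- sample(length(xu_all), bs, replace = TRUE)
    ic <- sample(length(xc_all), bs, replace = TRUE)
    list(xu = array(unlist(xu_all[iu]), dim = c(H, W, 1, bs)),
         xc = array(unlist(xc_all[ic]), dim = c(H, W, 1, bs)))
  }

  with_seed(seed, {
    for (ep in seq_len(total_epochs)) {
      phase <- if (ep <= gcf$epochs_solo) "solo" else "tandem"
      lr <- gcf$lr * gcf$lr_decay^(ep - 1)
      n_batches <- if (!is.null(gcf$steps_per_epoch)) gcf$steps_per_epoch
                   else max(1, floor(length(xu_all) / bs))
      acc <- c(g1 = 0, g2 = 0, g3 = 0, g4 = 0, lg = 0, ld = 0)
      for (b in seq_len(n_batches)) {
        ba <- make_batch()
        z <- matrix(runif(gen$noise_dim * bs, -0.5, 0.5), gen$noise_dim, bs)
        fw <- .gen_forward(gen, ba$xu, ba$xc, z, training = TRUE)
        gen$state <- fw$state
        ld_val <- NA_real_
        if (phase == "tandem") {
          # discriminator update on real vs (detached) synthetic
          fr <- nn_forward(disc$spec, disc$params, disc$state, ba$xc, TRUE)
          disc$state <- fr$state
          fs <- nn_forward(disc$spec, disc$params, disc$state, fw$xs, TRUE)
          disc$state <- fs$state
          ld_val <- gan_discriminator_loss(fr$y, fs$y)
          m <- length(fr$y)
          gr <- nn_backward(disc$spec, disc$params, fr$cache,
                            0.5 * 2 * (fr$y - 1) / m)
          gs <- nn_backward(disc$spec, disc$params, fs$cache,
                            0.5 * 2 * fs$y / m)
          grads_d <- .tree_add(gr$grads, gs$grads)
          td <- td + 1
          r <- adamw_step(disc$params, grads_d, opt_d, lr, td)
          disc$params <- r$params
          opt_d <- r$opt
        }
        # generator update
        disc_cache <- NULL
        gxs <- .generator_loss_grad(fw$xs, ba$xu, ba$xc)
        loss <- generator_loss(fw$xs, ba$xu, ba$xc, disc_out = NULL)
        if (phase == "tandem") {
          fsd <- nn_forward(disc$spec, disc$params, disc$state, fw$xs, FALSE)
          loss <- generator_loss(fw$xs, ba$xu, ba$xc, disc_out = fsd$y)
          m <- length(fsd$y)
          rb <- nn_backward(disc$spec, disc$params, fsd$cache,
                            2 * (fsd$y - 1) / m)
          gxs <- gxs + rb$gx
        }
        grads_g <- .gen_backward(gen, fw$cache, gxs)
        tg <- tg + 1
        for (part in names(gen$params)) {
          r <- adamw_step(gen$params[[part]], grads_g[[part]],
                          opt_g[[part]], lr, tg)
          gen$params[[part]] <- r$params
          opt_g[[part]] <- r$opt
        }
        acc <- acc + c(loss$g1, loss$g2, loss$g3, loss$g4, loss$total,
                       if (is.na(ld_val)) 0 else ld_val)
      }
      acc <- acc / n_batches
      hist <- rbind(hist, data.frame(
        epoch = ep, phase = phase, g1 = acc[["g1"]], g2 = acc[["g2"]],
        g3 = acc[["g3"]], g4 = acc[["g4"]], lg = acc[["lg"]],
        ld = if (phase == "tandem") acc[["ld"]] else NA_real_, lr = lr))
      if (verbose)
        message(sprintf("gan epoch %d (%s)  LG %.4f  LD %s  lr %.5f", ep,
                        phase, acc[["lg"]],
                        if (phase == "tandem")
                          sprintf("%.4f", acc[["ld"]]) else "-", lr))
    }
  })
  rownames(hist) <- NULL
  list(generator = gen, discriminator = disc, history = hist)
}

.tree_add <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  out <- a
  for (i in seq_along(a)) out[[i]] <- .tree_add(a[[i]], b[[i]])
  out
}
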