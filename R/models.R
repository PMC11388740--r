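# Heatmap pose network (encoder + deconvolution decoder + per-channel
# spatial softmax), pose discriminator with a pose-attention block, their
# losses, the heatmap-deformation generator used for discriminator
# negatives, and the CPU training loops.

#' Pose network configuration
#'
#' The default backbone is a compact 4-stage strided convolutional encoder
#' that trains in minutes on one CPU; larger encoders can be registered as
#' plugins (the contract — encode, deconvolve, 1x1 conv, spatial softmax —
#' is what the package tests, not the capacity).  With `input_size = NULL`
#' the network runs at the native frame resolution; setting it emulates the
#' nearest-neighbour upscale used with large pretrained encoders (e.g. 440
#' with a 114 heatmap).
#'
#' @param height,width Frame dimensions the network will see.
#' @param backbone Backbone identifier; `"tiny"` is built in.
#' @param input_size Optional square size the input is nearest-neighbour
#'   upscaled to (replicated to 3 channels either way).
#' @param heatmap_size Optional square heatmap size; by default the heatmap
#'   is `input / heatmap_stride`.
#' @param heatmap_stride Ratio of network input to heatmap resolution used
#'   when `heatmap_size` is NULL.
#' @param n_keypoints Number of keypoint channels (14).
#' @param deconv_blocks Number of x2 upsampling deconvolution blocks.
#' @param deconv_channels Channels in each deconvolution block.
#' @param stage_channels Channel widths of the four backbone stages.
#' @return A config list of class `pose_net_config`.
#' @export
pose_net_config <- function(height = 160, width = 120, backbone = "tiny",
                            input_size = NULL, heatmap_size = NULL,
                            heatmap_stride = 2, n_keypoints = 14L,
                            deconv_blocks = 3L, deconv_channels = 32L,
                            stage_channels = c(8L, 16L, 32L, 48L)) {
  if (backbone != "tiny" && !backbone %in% names(.pose_backbones))
    stop("unknown backbone: ", backbone)
  net_in <- if (is.null(input_size)) c(height, width)
            else c(input_size, input_size)
  hm <- if (is.null(heatmap_size)) pmax(1, round(net_in / heatmap_stride))
        else c(heatmap_size, heatmap_size)
  structure(list(height = height, width = width, backbone = backbone,
                 input_size = input_size, net_in = net_in,
                 heatmap_shape = hm, n_keypoints = as.integer(n_keypoints),
                 deconv_blocks = as.integer(deconv_blocks),
                 deconv_channels = as.integer(deconv_channels),
                 stage_channels = as.integer(stage_channels)),
            class = "pose_net_config")
}

# Plugin registry for alternative encoders: name -> function(config) giving
# list(spec, out_channels).
.pose_backbones <- new.env(parent = emptyenv())

#' Register an alternative pose-net backbone
#'
#' @param name Identifier.
#' @param builder `function(config)` returning `list(spec, out_channels)`
#'   where `spec` is an internal layer spec consuming a 3-channel input.
#' @export
register_pose_backbone <- function(name, builder) {
  assign(name, builder, envir = .pose_backbones)
  invisible(name)
}

.tiny_backbone <- function(config) {
  ch <- config$stage_channels
  spec <- nn_seq(
    nn_conv(3, 3, 3, ch[1], stride = 2), nn_bn(ch[1]), nn_act("relu"),
    nn_conv(3, 3, ch[1], ch[2], stride = 2), nn_bn(ch[2]), nn_act("relu"),
    nn_conv(3, 3, ch[2], ch[3], stride = 2), nn_bn(ch[3]), nn_act("relu"),
    nn_conv(3, 3, ch[3], ch[4], stride = 2), nn_bn(ch[4]), nn_act("relu"))
  list(spec = spec, out_channels = ch[4])
}

#' Build a pose-estimation network
#'
#' Encoder-decoder heatmap network: a convolutional encoder, a stack of
#' deconvolution blocks (x2 nearest upsample + 3x3 convolution + batch
#' norm + ReLU), a nearest resize to the configured heatmap shape, and a
#' final 1x1 convolution with per-channel spatial softmax so that every
#' keypoint channel is a probability map summing to 1.
#'
#' @param config A [pose_net_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `pose_net`.
#' @export
build_pose_net <- function(config = pose_net_config(), seed = 0L) {
  bb <- if (config$backbone == "tiny") .tiny_backbone(config)
        else get(config$backbone, envir = .pose_backbones)(config)
  cin <- bb$out_channels
  head_layers <- list()
  for (i in seq_len(config$deconv_blocks)) {
    head_layers <- c(head_layers, list(
      nn_resize(factor = 2),
      nn_conv(3, 3, if (i == 1) cin else config$deconv_channels,
              config$deconv_channels),
      nn_bn(config$deconv_channels), nn_act("relu")))
  }
  head_layers <- c(head_layers, list(
    nn_resize(h = config$heatmap_shape[1], w = config$heatmap_shape[2]),
    nn_conv(1, 1, config$deconv_channels, config$n_keypoints, pad = 0),
    nn_softmax2d()))
  spec <- list(backbone = bb$spec, head = do.call(nn_seq, head_layers))
  params <- state <- NULL
  with_seed(seed, {
    params <- list(backbone = nn_init(spec$backbone),
                   head = nn_init(spec$head))
  })
  state <- list(backbone = nn_state_init(spec$backbone),
                head = nn_state_init(spec$head))
  structure(list(config = config, spec = spec, params = params,
                 state = state), class = "pose_net")
}

#' @export
print.pose_net <- function(x, ...) {
  cat(sprintf(
    "<pose_net backbone=%s in=%dx%d heatmap=%dx%dx%d params=%d>\n",
    x$config$backbone, x$config$net_in[1], x$config$net_in[2],
    x$config$heatmap_shape[1], x$config$heatmap_shape[2],
    x$config$n_keypoints, n_params(x$params)))
  invisible(x)
}

n_params <- function(p) {
  if (is.numeric(p)) return(length(p))
  sum(vapply(p, n_params, numeric(1)))
}

# Frames (list of ir_frame or matrices) -> (H, W, 1, N) array.
frames_to_batch <- function(frames) {
  mats <- lapply(frames, function(f) if (inherits(f, "ir_frame")) f$pixels else f)
  H <- nrow(mats[[1]]); W <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), dim = c(H, W, 1, length(mats)))
}

# Nearest upscale (optional) + replicate to 3 channels; no gradient needed
# back through this stage.
.pose_net_preprocess <- function(model, x) {
  cfg <- model$config
  if (!is.null(cfg$input_size))
    x <- .cpp_resize_fwd(x, cfg$net_in[1], cfg$net_in[2])
  x[, , c(1, 1, 1), , drop = FALSE]
}

.pose_net_forward <- function(model, x, training = FALSE) {
  x <- .pose_net_preprocess(model, x)
  r1 <- nn_forward(model$spec$backbone, model$params$backbone,
                   model$state$backbone, x, training)
  r2 <- nn_forward(model$spec$head, model$params$head, model$state$head,
                   r1$y, training)
  list(y = r2$y, cache = list(backbone = r1$cache, head = r2$cache),
       state = list(backbone = r1$state, head = r2$state))
}

.pose_net_backward <- function(model, cache, gy) {
  r2 <- nn_backward(model$spec$head, model$params$head, cache$head, gy)
  r1 <- nn_backward(model$spec$backbone, model$params$backbone,
                    cache$backbone, r2$gx)
  list(backbone = r1$grads, head = r2$grads)
}

#' Predict heatmap stacks for frames
#'
#' Runs the network in evaluation mode.  With `flip = TRUE` each frame is
#' also decoded horizontally mirrored and the two heatmap sets are
#' combined by [flip_average()] — the test-time averaging scheme.
#'
#' @param model A [build_pose_net()] model.
#' @param frames List of [ir_frame()] (or plain matrices).
#' @param flip Use flip-averaged inference.
#' @return A list of [heatmap_stack()] objects.
#' @export
predict_heatmaps <- function(model, frames, flip = FALSE) {
  if (length(frames) == 0) return(list())
  cfg <- model$config
  sx <- cfg$width / cfg$heatmap_shape[2]
  sy <- cfg$height / cfg$heatmap_shape[1]
  x <- frames_to_batch(frames)
  out <- .pose_net_forward(model, x, training = FALSE)$y
  stacks <- lapply(seq_along(frames), function(i)
    heatmap_stack(out[, , , i, drop = TRUE], scale = c(sx, sy)))
  if (flip) {
    xf <- x[, dim(x)[2]:1, , , drop = FALSE]
    outf <- .pose_net_forward(model, xf, training = FALSE)$y
    stacks <- lapply(seq_along(frames), function(i)
      flip_average(stacks[[i]],
                   heatmap_stack(outf[, , , i, drop = TRUE],
                                 scale = c(sx, sy))))
  }
  stacks
}

#' Predict poses for frames
#'
#' Convenience wrapper: [predict_heatmaps()] then [decode_pose()].
#'
#' @inheritParams predict_heatmaps
#' @param params [refinement_params()].
#' @return List of decoded pose results (see [decode_pose()]).
#' @export
predict_poses <- function(model, frames, flip = TRUE,
                          params = refinement_params()) {
  lapply(predict_heatmaps(model, frames, flip = flip), decode_pose,
         params = params)
}

#' Pose training loss
#'
#' Sum over the 14 keypoint channels of the per-channel mean squared error
#' between predicted and ground-truth heatmaps.
#'
#' @param predicted,target [heatmap_stack()] objects (or bare
#'   `H' x W' x 14` arrays) of equal shape.
#' @return Non-negative scalar; zero iff the stacks are identical.
#' @export
pose_loss <- function(predicted, target) {
  p <- if (inherits(predicted, "heatmap_stack")) predicted$maps else predicted
  g <- if (inherits(target, "heatmap_stack")) target$maps else target
  if (!identical(dim(p), dim(g))) stop("heatmap stacks differ in shape")
  d <- dim(p)
  sum((p - g)^2) / (d[1] * d[2])
}

#' Deform a pose for discriminator negatives
#'
#' Produces implausible annotations of the kinds that plague pseudo-labels:
#' `"limb-shrink"` pulls wrists and ankles toward their parent joints by a
#' factor drawn from `[0.3, 0.7]` (abnormally short limbs), `"jitter"`
#' displaces a random subset of joints by at least twice the PCKh@0.5
#' tolerance, and `"lr-swap"` exchanges the left/right mirror pairs.
#'
#' @param pose 14 x 2 pose matrix.
#' @param seed Integer RNG seed.
#' @param mode One of `"limb-shrink"`, `"jitter"`, `"lr-swap"`.
#' @param shape,scale,radius Passed to [encode_pose()] for the returned
#'   heatmap encoding.
#' @return A list with `pose` (deformed) and `stack` (its encoding).
#' @export
deform_heatmaps <- function(pose, seed, mode = "limb-shrink",
                            shape = c(80, 60), scale = 2, radius = 2) {
  check_pose(pose)
  mode <- match.arg(mode, c("limb-shrink", "jitter", "lr-swap"))
  out <- with_seed(seed, {
    p <- pose
    if (mode == "limb-shrink") {
      distal <- c(1L, 6L, 7L, 12L)   # ankles and wrists
      parent <- c(2L, 5L, 8L, 11L)   # knees and elbows
      f <- runif(4, 0.3, 0.7)
      p[distal, ] <- pose[parent, ] + f * (pose[distal, ] - pose[parent, ])
    } else if (mode == "jitter") {
      l <- sqrt(sum((pose[14, ] - pose[13, ])^2))
      k <- sample(2:6, 1)
      joints <- sample(1:14, k)
      ang <- runif(k, 0, 2 * pi)
      mag <- runif(k, 1, 1.6) * max(l, 1)  # >= 2 x the 0.5 l tolerance
      p[joints, 1] <- pose[joints, 1] + mag * cos(ang)
      p[joints, 2] <- pose[joints, 2] + mag * sin(ang)
    } else {
      mp <- mirror_pairs()
      p[mp[, 1], ] <- pose[mp[, 2], ]
      p[mp[, 2], ] <- pose[mp[, 1], ]
    }
    p
  })
  list(pose = out, stack = encode_pose(out, shape, scale, radius))
}

#' Binary cross-entropy for a discriminator score
#'
#' @param score Score(s) in `(0, 1)`; clamped to `[1e-7, 1 - 1e-7]`.
#' @param label 0/1 label(s).
#' @return Mean BCE over the inputs.
#' @export
discriminator_loss <- function(score, label) {
  s <- pmin(1 - 1e-7, pmax(1e-7, score))
  mean(-(label * log(s) + (1 - label) * log(1 - s)))
}

#' Build a pose discriminator
#'
#' Scores an (image, heatmap) pair between 0 and 1, higher meaning a more
#' plausible annotation.  The image passes through the front half of a
#' compact convolutional backbone; in the middle a pose-attention block
#' resizes the heatmaps to feature resolution, multiplies the features by
#' the summed-over-channels heatmap (spatial attention), concatenates the
#' heatmap channels for redundancy and restores the expected width with a
#' 1x1 convolution; the back half ends in global average pooling, a linear
#' layer and a sigmoid.
#'
#' @param height,width Frame dimensions.
#' @param heatmap_shape `c(H', W')` of the heatmaps being scored.
#' @param channels Widths `c(front1, front2, back1, back2)`.
#' @param seed Weight-initialisation seed.
#' @return An object of class `pose_disc`.
#' @export
build_pose_discriminator <- function(height = 160, width = 120,
                                     heatmap_shape = c(80, 60),
                                     channels = c(8L, 16L, 32L, 32L),
                                     seed = 0L) {
  ch <- as.integer(channels)
  spec <- list(
    front = nn_seq(
      nn_conv(3, 3, 1, ch[1], stride = 2), nn_bn(ch[1]), nn_act("relu"),
      nn_conv(3, 3, ch[1], ch[2], stride = 2), nn_bn(ch[2]), nn_act("relu")),
    merge = nn_seq(
      nn_conv(1, 1, ch[2] + 14L, ch[2], pad = 0), nn_bn(ch[2]),
      nn_act("relu")),
    back = nn_seq(
      nn_conv(3, 3, ch[2], ch[3], stride = 2), nn_bn(ch[3]), nn_act("relu"),
      nn_conv(3, 3, ch[3], ch[4], stride = 2), nn_bn(ch[4]), nn_act("relu"),
      nn_gap(), nn_linear(ch[4], 1L), nn_act("sigmoid")))
  params <- NULL
  with_seed(seed, {
    params <- lapply(spec, nn_init)
  })
  state <- lapply(spec, nn_state_init)
  structure(list(height = height, width = width,
                 heatmap_shape = heatmap_shape, channels = ch,
                 spec = spec, params = params, state = state),
            class = "pose_disc")
}

.disc_forward <- function(disc, x, hm, training = FALSE) {
  r1 <- nn_forward(disc$spec$front, disc$params$front, disc$state$front,
                   x, training)
  fd <- dim(r1$y)
  hm_r <- .cpp_resize_fwd(hm, fd[1], fd[2])
  att <- hm_r[, , 1, , drop = FALSE]
  for (c in 2:dim(hm_r)[3]) att <- att + hm_r[, , c, , drop = FALSE]
  att_b <- att[, , rep(1, fd[3]), , drop = FALSE]
  fa <- r1$y * att_b
  catted <- cat_channels(fa, hm_r)
  r2 <- nn_forward(disc$spec$merge, disc$params$merge, disc$state$merge,
                   catted, training)
  r3 <- nn_forward(disc$spec$back, disc$params$back, disc$state$back,
                   r2$y, training)
  list(score = as.numeric(r3$y),
       cache = list(front = r1$cache, merge = r2$cache, back = r3$cache,
                    feat = r1$y, att_b = att_b, fd = fd),
       state = list(front = r1$state, merge = r2$state, back = r3$state))
}

.disc_backward <- function(disc, cache, gscore) {
  gy <- matrix(gscore, 1, length(gscore))
  r3 <- nn_backward(disc$spec$back, disc$params$back, cache$back, gy)
  r2 <- nn_backward(disc$spec$merge, disc$params$merge, cache$merge, r3$gx)
  fd <- cache$fd
  g_fa <- slice_channels(r2$gx, 1L, fd[3])
  g_f1 <- g_fa * cache$att_b
  r1 <- nn_backward(disc$spec$front, disc$params$front, cache$front, g_f1)
  list(front = r1$grads, merge = r2$grads, back = r3$grads)
}

#' Score (frame, heatmap) pairs with a pose discriminator
#'
#' @param disc A [build_pose_discriminator()] model.
#' @param frames List of [ir_frame()].
#' @param stacks List of [heatmap_stack()] aligned with `frames`.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
discriminator_score <- function(disc, frames, stacks) {
  if (length(frames) == 0) return(numeric(0))
  x <- frames_to_batch(frames)
  hm <- array(unlist(lapply(stacks, function(s) s$maps), use.names = FALSE),
              dim = c(dim(stacks[[1]]$maps), length(stacks)))
  .disc_forward(disc, x, hm, training = FALSE)$score
}

#' Train the pose discriminator on real versus deformed heatmaps
#'
#' Each annotated frame contributes a positive example (its ground-truth
#' encoding) and a negative example (a random deformation: limb shrink,
#' jitter or left/right swap), optimised with AdamW on binary
#' cross-entropy.
#'
#' @param disc A [build_pose_discriminator()] model.
#' @param items List of `list(frame, pose)` training samples.
#' @param epochs,batch_size,lr Optimisation settings.
#' @param radius Encoding radius for both positives and negatives.
#' @param bank Optional [attenuation_bank()]; when given, frames are shown
#'   to the discriminator with synthetic covers and sensor noise half the
#'   time, so that covered frames do not look out of distribution when the
#'   discriminator later scores pseudo-labels.
#' @param seed RNG seed for shuffling and deformations.
#' @param verbose Print per-epoch loss.
#' @return The trained `pose_disc` (with a `history` element of per-epoch
#'   mean BCE).
#' @export
train_pose_discriminator <- function(disc, items, epochs = 10,
                                     batch_size = 8, lr = 1e-3, radius = 2,
                                     bank = NULL, seed = 0L,
                                     verbose = FALSE) {
  hs <- disc$heatmap_shape
  sc <- c(disc$width / hs[2], disc$height / hs[1])
  opt <- lapply(disc$params, adamw_init)
  t_step <- 0
  history <- numeric(0)
  modes <- c("limb-shrink", "jitter", "lr-swap")
  with_seed(derive_seed(seed, "disc-train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(items))
      losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[b0:min(length(ord), b0 + batch_size - 1)]
        frames <- list(); hms <- list(); labels <- numeric(0)
        for (i in idx) {
          it <- items[[i]]
          fr <- it$frame
          if (!is.null(bank)) {
            fr <- augment_sample(fr, it$pose, bank,
                                 floor(runif(1, 1, 1e8)),
                                 probs = c(cover = 0.5, noise = 0.3,
                                           occlude = 0, flip = 0))$frame
          }
          lab <- sample(0:1, 1)
          if (lab == 1) {
            st <- encode_pose(it$pose, hs, sc, radius)
          } else {
            mode <- sample(modes, 1, prob = c(0.5, 0.3, 0.2))
            st <- deform_heatmaps(it$pose,
                                  seed = floor(runif(1, 1, 1e8)),
                                  mode = mode, shape = hs, scale = sc,
                                  radius = radius)$stack
          }
          frames[[length(frames) + 1]] <- fr
          hms[[length(hms) + 1]] <- st$maps
          labels <- c(labels, lab)
        }
        x <- frames_to_batch(frames)
        hm <- array(unlist(hms, use.names = FALSE),
                    dim = c(hs[1], hs[2], 14, length(frames)))
        fw <- .disc_forward(disc, x, hm, training = TRUE)
        disc$state <- fw$state
        losses <- c(losses, discriminator_loss(fw$score, labels))
        # d BCE / d pre-sigmoid = (s - label); undo the sigmoid-layer
        # derivative so the composed gradient is exactly that.
        s <- pmin(1 - 1e-7, pmax(1e-7, fw$score))
        gscore <- (s - labels) / (s * (1 - s)) / length(labels)
        grads <- .disc_backward(disc, fw$cache, gscore)
        t_step <- t_step + 1
        for (part in names(disc$params)) {
          r <- adamw_step(disc$params[[part]], grads[[part]],
                          opt[[part]], lr, t_step)
          disc$params[[part]] <- r$params
          opt[[part]] <- r$opt
        }
      }
      history <- c(history, mean(losses))
      if (verbose)
        message(sprintf("disc epoch %d  bce %.4f", ep, mean(losses)))
    }
  })
  disc$history <- history
  disc
}

#' Train the pose network
#'
#' Supervised training with the shrinking-radius heatmap targets, AdamW,
#' optional on-the-fly augmentation, and best-checkpoint selection (and
#' optional early stopping) by validation AUC%.
#'
#' @param model A [build_pose_net()] model.
#' @param items List of `list(frame, pose)` training samples.
#' @param val_items Validation samples of the same shape (may be NULL to
#'   skip validation; the final weights are then returned).
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param lr Learning rate (constant policy) or maximum learning rate
#'   (one-cycle policy).
#' @param lr_policy `"constant"` or `"one-cycle"`.
#' @param patience Early-stopping patience in epochs on validation AUC%
#'   (`Inf` disables).
#' @param bank Optional [attenuation_bank()] enabling cover augmentation.
#' @param augment_probs Probabilities passed to [augment_sample()]; used
#'   only when `augment = TRUE`.
#' @param augment Apply on-the-fly augmentation.
#' @param radius_schedule Function `epoch -> radius` (default
#'   [radius_at_epoch()]).
#' @param seed RNG seed for shuffling and augmentation.
#' @param verbose Print per-epoch progress.
#' @return The trained model with `history` (data frame of epoch, loss,
#'   val_auc) and `best_val_auc` attached.
#' @export
train_pose_net <- function(model, items, val_items = NULL, epochs = 40,
                           batch_size = 8, lr = 1e-3,
                           lr_policy = c("constant", "one-cycle"),
                           patience = 10, bank = NULL,
                           augment_probs = c(cover = 0.8, noise = 0.5,
                                             occlude = 0.3, flip = 0.5),
                           augment = TRUE,
                           radius_schedule = radius_at_epoch,
                           seed = 0L, verbose = FALSE) {
  lr_policy <- match.arg(lr_policy)
  cfg <- model$config
  hs <- cfg$heatmap_shape
  sc <- c(cfg$width / hs[2], cfg$height / hs[1])
  opt <- lapply(model$params, adamw_init)
  t_step <- 0
  n_batches <- ceiling(length(items) / batch_size)
  total_steps <- epochs * n_batches
  best <- list(auc = -Inf, params = model$params, state = model$state)
  bad_epochs <- 0
  hist_epoch <- integer(0); hist_loss <- numeric(0); hist_auc <- numeric(0)

  with_seed(derive_seed(seed, "pose-train"), {
    for (ep in seq_len(epochs)) {
      radius <- max(1, radius_schedule(ep - 1))
      ord <- sample(seq_along(items))
      losses <- numeric(0)
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[b0:min(length(ord), b0 + batch_size - 1)]
        frames <- list(); targets <- list()
        for (i in idx) {
          it <- items[[i]]
          fr <- it$frame; po <- it$pose
          if (augment) {
            au <- augment_sample(fr, po, bank, floor(runif(1, 1, 1e8)),
                                 probs = augment_probs)
            fr <- au$frame; po <- au$pose
          }
          frames[[length(frames) + 1]] <- fr
          targets[[length(targets) + 1]] <-
            encode_pose(po, hs, sc, radius)$maps
        }
        x <- frames_to_batch(frames)
        tg <- array(unlist(targets, use.names = FALSE),
                    dim = c(hs[1], hs[2], 14, length(frames)))
        fw <- .pose_net_forward(model, x, training = TRUE)
        model$state <- fw$state
        n <- length(frames)
        losses <- c(losses, sum((fw$y - tg)^2) / (hs[1] * hs[2]) / n)
        gy <- 2 * (fw$y - tg) / (hs[1] * hs[2]) / n
        grads <- .pose_net_backward(model, fw$cache, gy)
        t_step <- t_step + 1
        lr_t <- if (lr_policy == "one-cycle")
          one_cycle_lr(t_step, total_steps, lr) else lr
        for (part in names(model$params)) {
          r <- adamw_step(model$params[[part]], grads[[part]],
                          opt[[part]], lr_t, t_step)
          model$params[[part]] <- r$params
          opt[[part]] <- r$opt
        }
      }
      val_auc <- NA_real_
      if (!is.null(val_items) && length(val_items) > 0) {
        val_auc <- .validation_auc(model, val_items)
        if (val_auc > best$auc) {
          best <- list(auc = val_auc, params = model$params,
                       state = model$state)
          bad_epochs <- 0
        } else {
          bad_epochs <- bad_epochs + 1
        }
      }
      hist_epoch <- c(hist_epoch, ep)
      hist_loss <- c(hist_loss, mean(losses))
      hist_auc <- c(hist_auc, val_auc)
      if (verbose)
        message(sprintf("epoch %d  loss %.5f  val AUC%% %.1f", ep,
                        mean(losses), val_auc))
      if (!is.null(val_items) && bad_epochs >= patience) break
    }
  })
  if (!is.null(val_items) && is.finite(best$auc)) {
    model$params <- best$params
    model$state <- best$state
    model$best_val_auc <- best$auc
  } else {
    model$best_val_auc <- NA_real_
  }
  model$history <- data.frame(epoch = hist_epoch, loss = hist_loss,
                              val_auc = hist_auc)
  model
}

.validation_auc <- function(model, val_items, flip = FALSE) {
  frames <- lapply(val_items, `[[`, "frame")
  gts <- lapply(val_items, `[[`, "pose")
  dec <- predict_poses(model, frames, flip = flip)
  preds <- lapply(dec, `[[`, "pose")
  auc_percent(pckh_curve(preds, gts))
}

#' Save / load a model checkpoint
#'
#' The weights go into an RDS file; a JSON sidecar records the class,
#' configuration and any training history for inspection without loading.
#'
#' @param model A `pose_net`, `pose_disc` or GAN model.
#' @param path Checkpoint path (sidecar written to `path.json`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(class = class(model)[1],
               best_val_auc = model$best_val_auc,
               n_params = n_params(model$params))
  if (inherits(model, "pose_net")) meta$config <- unclass(model$config)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
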