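# Two-phase training: priming, adaptation with on-the-fly augmentation,
# pseudo-labelling of the unannotated covered frames, discriminator-scored
# filtering at threshold tau, and iteration until validation stops
# improving.

#' Pseudo-label unannotated frames
#'
#' Runs the pose model with flip-averaged inference and returns one
#' heatmap stack per frame.
#'
#' @param model A trained `pose_net`.
#' @param frames List of [ir_frame()] (typically covered training frames).
#' @return List of [heatmap_stack()], one per frame (empty list for empty
#'   input).
#' @export
pseudo_label <- function(model, frames) {
  predict_heatmaps(model, frames, flip = TRUE)
}

#' Assemble a pseudo-label batch
#'
#' @param ids Character identifiers of the frames.
#' @param stacks Heatmap stacks from [pseudo_label()].
#' @param scores Discriminator scores in `[0, 1]`, aligned with `stacks`.
#' @param tau Selection threshold.
#' @param iteration Semi-supervised iteration index.
#' @return An object of class `pseudo_label_batch`.
#' @export
pseudo_label_batch <- function(ids, stacks, scores, tau = 0.7,
                               iteration = 0L) {
  stopifnot(length(ids) == length(stacks), length(ids) == length(scores),
            all(scores >= 0), all(scores <= 1))
  structure(list(ids = ids, stacks = stacks, scores = scores, tau = tau,
                 iteration = iteration),
            class = "pseudo_label_batch")
}

#' Filter pseudo-labels by discriminator score
#'
#' Selection is strict: exactly the items whose score exceeds `tau` are
#' kept (a score equal to `tau` is excluded).  Alternative policies used
#' for ablation: `"random"` keeps a uniform fraction of items regardless
#' of score, `"all"` keeps everything.
#'
#' @param batch A [pseudo_label_batch()].
#' @param policy `"discriminator"` (default), `"random"` or `"all"`.
#' @param random_fraction Fraction kept under the `"random"` policy.
#' @param seed Seed for the `"random"` policy.
#' @return The batch restricted to the selected items, with a `selected`
#'   integer index vector attached.
#' @export
filter_pseudo_labels <- function(batch, policy = c("discriminator",
                                                   "random", "all"),
                                 random_fraction = 0.1, seed = 0L) {
  policy <- match.arg(policy)
  keep <- switch(policy,
    discriminator = which(batch$scores > batch$tau),
    random = with_seed(seed, {
      n <- length(batch$ids)
      sort(sample(n, floor(random_fraction * n)))
    }),
    all = seq_along(batch$ids))
  out <- batch
  out$ids <- batch$ids[keep]
  out$stacks <- batch$stacks[keep]
  out$scores <- batch$scores[keep]
  out$selected <- keep
  out
}

# Manifest records -> list(frame, pose) item lists.
.manifest_items <- function(manifest, split, annotated_only = TRUE,
                            cover = NULL) {
  recs <- manifest$records
  recs <- recs[recs$split == split, ]
  if (annotated_only) recs <- recs[recs$annotated, ]
  if (!is.null(cover)) recs <- recs[recs$cover %in% cover, ]
  lapply(seq_len(nrow(recs)), function(i) {
    list(id = recs$image[i],
         frame = read_frame(file.path(manifest$dir, recs$image[i]),
                            recs$cover[i]),
         pose = manifest$poses[[recs$image[i]]])
  })
}

#' Run the full two-phase semi-supervised training scheme
#'
#' Phase 1 ("priming") trains the pose network without augmentation on the
#' annotated frames (or on a separate priming manifest when provided),
#' emulating pre-training on a generic RGB pose dataset.  Phase 2
#' ("adaptation") iterates: train with on-the-fly statistical augmentation
#' on the annotated data plus any selected pseudo-labelled covered frames,
#' select the best checkpoint by validation AUC%, pseudo-label the covered
#' training frames with flip-averaged inference, score the pseudo-labels
#' with the pose discriminator, keep those scoring above `tau`, and
#' repeat.  The loop stops when validation AUC% fails to improve or after
#' `max_iterations`.  Previously selected pseudo-labels are re-scored each
#' round and dropped if they fall below `tau`.
#'
#' @param manifest A manifest from [build_manifest()] / [load_manifest()].
#' @param config A configuration list from [default_config()] (any subset
#'   of fields can be overridden).
#' @param verbose Print progress.
#' @return A list with `model` (best pose net), `disc` (trained
#'   discriminator), `history` (data frame: iteration, val_auc,
#'   n_selected, selected_fraction), `selected_ids` (per-iteration list)
#'   and `best_val_auc`.
#' @export
run_training <- function(manifest, config = default_config(),
                         verbose = FALSE) {
  cfg <- config
  seed <- cfg$seed
  train_items <- .manifest_items(manifest, "train", annotated_only = TRUE)
  if (length(train_items) == 0) stop("manifest has no annotated training data")
  val_items <- .manifest_items(manifest, "val", annotated_only = TRUE)

  covered_recs <- manifest$records[
    manifest$records$split == "train" & !manifest$records$annotated, ]
  covered_frames <- lapply(seq_len(nrow(covered_recs)), function(i)
    read_frame(file.path(manifest$dir, covered_recs$image[i]),
               covered_recs$cover[i]))
  names(covered_frames) <- covered_recs$image

  bank <- if (length(covered_frames) > 0)
    estimate_attenuation_factors(covered_frames) else NULL

  net_cfg <- pose_net_config(height = manifest$height,
                             width = manifest$width,
                             backbone = cfg$model$backbone,
                             deconv_blocks = cfg$model$deconv_blocks,
                             deconv_channels = cfg$model$deconv_channels,
                             heatmap_stride = cfg$model$heatmap_stride)

  # Phase 1: priming (no augmentation).
  primed <- build_pose_net(net_cfg, seed = derive_seed(seed, "init"))
  if (cfg$schedules$priming_epochs > 0) {
    if (verbose) message("priming for ", cfg$schedules$priming_epochs,
                         " epochs")
    primed <- train_pose_net(
      primed, train_items, val_items = NULL,
      epochs = cfg$schedules$priming_epochs,
      batch_size = cfg$schedules$batch_size,
      lr = cfg$schedules$priming_lr, lr_policy = "constant",
      augment = FALSE, seed = derive_seed(seed, "priming"),
      verbose = verbose)
  }

  # Pose discriminator trained on GT vs deformed encodings.
  disc <- build_pose_discriminator(
    height = manifest$height, width = manifest$width,
    heatmap_shape = net_cfg$heatmap_shape,
    seed = derive_seed(seed, "disc-init"))
  disc <- train_pose_discriminator(
    disc, train_items, epochs = cfg$schedules$disc_epochs,
    batch_size = cfg$schedules$batch_size, lr = cfg$schedules$priming_lr,
    bank = bank, seed = derive_seed(seed, "disc"), verbose = verbose)

  adapt <- function(extra_items, iter) {
    m <- if (cfg$schedules$restart_each_iteration || is.null(best_model))
      primed else best_model
    train_pose_net(
      m, c(train_items, extra_items), val_items = val_items,
      epochs = cfg$schedules$adapt_epochs,
      batch_size = cfg$schedules$batch_size,
      lr = cfg$schedules$adapt_max_lr, lr_policy = "one-cycle",
      patience = cfg$schedules$patience, bank = bank,
      augment_probs = cfg$augment$probs, augment = TRUE,
      seed = derive_seed(seed, paste0("adapt-", iter)), verbose = verbose)
  }

  best_model <- NULL
  hist_iter <- integer(0); hist_auc <- numeric(0)
  hist_nsel <- integer(0); hist_frac <- numeric(0)
  selected_ids <- list()
  pseudo_items <- list()

  best_model <- adapt(list(), 0)
  best_auc <- best_model$best_val_auc
  hist_iter <- c(hist_iter, 0L)
  hist_auc <- c(hist_auc, best_auc)
  hist_nsel <- c(hist_nsel, 0L)
  hist_frac <- c(hist_frac, 0)
  if (verbose) message(sprintf("iteration 0: val AUC%% %.1f", best_auc))

  max_iter <- cfg$schedules$max_iterations
  it <- 0L
  while (it < max_iter && length(covered_frames) > 0) {
    it <- it + 1L
    stacks <- pseudo_label(best_model, covered_frames)
    scores <- discriminator_score(disc, covered_frames, stacks)
    batch <- pseudo_label_batch(names(covered_frames), stacks, scores,
                                tau = cfg$tau, iteration = it)
    sel <- filter_pseudo_labels(batch, policy = cfg$filter_policy,
                                random_fraction = cfg$random_fraction,
                                seed = derive_seed(seed, paste0("rf-", it)))
    selected_ids[[it]] <- sel$ids
    # decoded poses become the training supervision so targets can follow
    # the radius schedule
    pseudo_items <- lapply(seq_along(sel$ids), function(i) {
      list(id = sel$ids[i],
           frame = covered_frames[[sel$ids[i]]],
           pose = decode_pose(sel$stacks[[i]])$pose)
    })
    pseudo_items <- Filter(function(x) !any(is.na(x$pose)), pseudo_items)
    cand <- adapt(pseudo_items, it)
    frac <- length(sel$ids) / length(covered_frames)
    hist_iter <- c(hist_iter, it)
    hist_auc <- c(hist_auc, cand$best_val_auc)
    hist_nsel <- c(hist_nsel, length(sel$ids))
    hist_frac <- c(hist_frac, frac)
    if (verbose)
      message(sprintf(
        "iteration %d: selected %d/%d (%.0f%%), val AUC%% %.1f", it,
        length(sel$ids), length(covered_frames), 100 * frac,
        cand$best_val_auc))
    if (!is.na(cand$best_val_auc) && !is.na(best_auc) &&
        cand$best_val_auc > best_auc) {
      best_model <- cand
      best_auc <- cand$best_val_auc
    } else {
      break  # no validation improvement: stop iterating
    }
  }

  list(model = best_model, disc = disc,
       history = data.frame(iteration = hist_iter, val_auc = hist_auc,
                            n_selected = hist_nsel,
                            selected_fraction = hist_frac),
       selected_ids = selected_ids, best_val_auc = best_auc)
}
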