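# Run configuration: one structured list whose defaults carry the
# training recipe (optimiser schedules, the pseudo-label threshold, the
# refinement window, the metric grid), overridable from a YAML file.

#' Default run configuration
#'
#' Central defaults for the whole pipeline: AdamW with constant learning
#' rate 0.001 for the 25-epoch priming phase; one-cycle with maximum
#' learning rate 0.0009, up to 100 epochs and early-stopping patience 10
#' for adaptation; pseudo-label threshold `tau = 0.7`; up to 3
#' semi-supervised iterations; decoding window `d = 5` with 3 refinement
#' iterations; PCKh thresholds sampled at 0, 0.01, ..., 0.5.
#'
#' @param seed Global seed fanned out to every stochastic component via
#'   [derive_seed()].
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    tau = 0.7,
    filter_policy = "discriminator",
    random_fraction = 0.1,
    model = list(backbone = "tiny", deconv_blocks = 3L,
                 deconv_channels = 32L, heatmap_stride = 2),
    schedules = list(
      priming_epochs = 25L, priming_lr = 1e-3,
      adapt_epochs = 100L, adapt_max_lr = 9e-4, patience = 10L,
      disc_epochs = 30L, batch_size = 8L,
      max_iterations = 3L, restart_each_iteration = TRUE),
    augment = list(probs = c(cover = 0.8, noise = 0.5, occlude = 0.3,
                             flip = 0.5),
                   noise_sigma = 0.03, wrinkle_roughness = 0.3),
    refine = list(d = 5L, iterations = 3L),
    metric = list(thresholds = seq(0, 0.5, by = 0.01)),
    gan = list(width_multiplier = 0.25, noise_dim = 64L,
               epochs_solo = 10L, epochs_tandem = 10L,
               lr = 1e-3, lr_decay = 0.9, batch_size = 4L,
               steps_per_epoch = NULL)  # NULL: one pass over uncovered set
  )
}

# Recursively overlay `over` onto `base`.
.merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Load a YAML configuration over the defaults
#'
#' Missing keys fall back to [default_config()].
#'
#' @param path YAML file path (NULL returns the defaults).
#' @param seed Seed used for defaults when the file does not set one.
#' @return A configuration list.
#' @export
load_config <- function(path = NULL, seed = 1L) {
  cfg <- default_config(seed)
  if (!is.null(path)) {
    over <- yaml::read_yaml(path)
    if (!is.null(over$augment$probs))
      over$augment$probs <- unlist(over$augment$probs)
    cfg <- .merge_config(cfg, over)
  }
  cfg
}

#' Write a resolved configuration next to a run's outputs
#'
#' @param config Configuration list.
#' @param dir Output directory.
#' @return The file path, invisibly.
#' @export
write_run_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  run_id <- substr(paste(format(Sys.time(), "%Y%m%d%H%M%S"),
                         paste0(sample(c(letters, 0:9), 6, TRUE),
                                collapse = "")), 1, 24)
  config$run_id <- run_id
  path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(lapply(config, function(x)
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x), path)
  invisible(path)
}
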