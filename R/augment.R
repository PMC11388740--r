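# Statistical cover augmentation: exponential intensity attenuation, an
# empirical attenuation-factor bank estimated from covered frames, a
# procedural wrinkle field, plus sensor noise, heavy occlusion and
# left/right-aware horizontal flipping.

#' Exponential attenuation of an intensity
#'
#' Implements the Beer-Lambert-style model `I = I0 * exp(-alpha * x)` for a
#' cover of thickness `x` and attenuation coefficient `alpha`.
#'
#' @param intensity Initial intensity `I0` in `[0, 1]` (vectorised).
#' @param alpha Attenuation coefficient, `>= 0`.
#' @param thickness Cover thickness, `>= 0` (same units as `1/alpha`).
#' @return Attenuated intensity, never larger than the input.
#' @export
attenuate <- function(intensity, alpha, thickness) {
  if (any(alpha < 0)) stop("alpha must be non-negative")
  if (any(thickness < 0)) stop("thickness must be non-negative")
  stopifnot(all(intensity >= 0), all(intensity <= 1))
  intensity * exp(-alpha * thickness)
}

#' Construct an attenuation bank
#'
#' @param factors Numeric vector of attenuation factors in `(0, 1]`.
#' @param source_count Number of covered frames analysed to obtain them.
#' @return An object of class `attenuation_bank`.
#' @export
attenuation_bank <- function(factors, source_count = length(factors)) {
  factors <- as.numeric(factors)
  if (any(factors <= 0) || any(factors > 1))
    stop("attenuation factors must lie in (0, 1]")
  structure(list(factors = factors, source_count = source_count),
            class = "attenuation_bank")
}

#' @export
print.attenuation_bank <- function(x, ...) {
  cat(sprintf("<attenuation_bank n=%d mean=%.3f range=[%.3f, %.3f]>\n",
              length(x$factors), mean(x$factors), min(x$factors),
              max(x$factors)))
  invisible(x)
}

#' Estimate attenuation factors from covered frames
#'
#' For each covered frame the head region is assumed uncovered, so the
#' maximum intensity of the upper rows approximates the unattenuated body
#' intensity while the maximum of the remaining lower rows approximates the
#' attenuated one.  The per-frame factor is their ratio
#' `F = max(lower) / max(upper)`.  Ratios above 1 contradict the
#' exponential model (the head region was not the hottest) and are
#' discarded rather than clipped; frames whose upper region is entirely
#' zero are skipped with a warning.
#'
#' @param frames List of covered [ir_frame()] objects.
#' @param upper_fraction Fraction of rows treated as the uncovered head
#'   region (default one fourth).
#' @return An [attenuation_bank()].
#' @export
estimate_attenuation_factors <- function(frames, upper_fraction = 0.25) {
  if (length(frames) == 0) stop("need at least one covered frame")
  stopifnot(upper_fraction > 0, upper_fraction < 1)
  factors <- numeric(0)
  skipped <- 0L
  for (fr in frames) {
    px <- fr$pixels
    nu <- max(1L, floor(upper_fraction * nrow(px)))
    up <- max(px[seq_len(nu), , drop = FALSE])
    lo <- max(px[(nu + 1):nrow(px), , drop = FALSE])
    if (up <= 0) {
      skipped <- skipped + 1L
      next
    }
    f <- lo / up
    if (f > 0 && f <= 1) factors <- c(factors, f)
  }
  if (skipped > 0)
    warning(skipped, " frame(s) skipped: upper region entirely zero")
  if (length(factors) == 0)
    stop("no usable attenuation factors could be estimated")
  attenuation_bank(factors, source_count = length(frames))
}

#' Threshold a frame into a body mask
#'
#' The subject is markedly warmer than the bed, so a single global
#' threshold separates body from background.  `threshold = "otsu"` picks it
#' by maximising between-class variance on a 256-bin histogram.
#'
#' @param frame An [ir_frame()].
#' @param threshold Scalar in `[0, 1]`, or `"otsu"`.
#' @return A list with `mask` (logical matrix, TRUE = body) and
#'   `threshold_used`.
#' @export
body_mask <- function(frame, threshold = "otsu") {
  px <- frame$pixels
  if (identical(threshold, "otsu")) {
    threshold <- otsu_threshold(px)
  } else {
    if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
      stop("threshold must be in [0, 1] or \"otsu\"")
  }
  list(mask = px > threshold, threshold_used = threshold)
}

#' Otsu threshold on a 256-bin histogram
#'
#' @param px Numeric matrix in `[0, 1]`.
#' @param bins Number of histogram bins.
#' @return Threshold value in `[0, 1]`.
#' @export
otsu_threshold <- function(px, bins = 256L) {
  h <- tabulate(pmin(bins, floor(as.numeric(px) * bins) + 1L), bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(bins))
  mu_t <- mu[bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  (which.max(sigma_b)) / bins
}

#' Procedural wrinkle map
#'
#' A band-limited smooth random field standing in for rendered cloth
#' simulations: white noise is blurred with a Gaussian kernel and rescaled
#' to `[1 - roughness * spread, 1]`.  Value 1 means flat cloth (no extra
#' attenuation); darker values mimic folded cloth that attenuates more.
#'
#' @param shape `c(H, W)` of the map.
#' @param seed Integer RNG seed.
#' @param roughness Scalar in `(0, 1]` controlling the dynamic range.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param spread Maximum fraction of range removed at `roughness = 1`.
#' @return A list with `values` (H x W matrix in `[0, 1]`) and `seed`.
#' @export
generate_wrinkle_map <- function(shape, seed, roughness = 0.3,
                                 blur_sigma = 6, spread = 0.5) {
  stopifnot(roughness > 0, roughness <= 1)
  H <- shape[1]; W <- shape[2]
  z <- with_seed(seed, matrix(rnorm(H * W), H, W))
  z <- .gauss_blur(z, blur_sigma)
  rng <- range(z)
  z01 <- if (diff(rng) < 1e-12) matrix(0.5, H, W) else (z - rng[1]) / diff(rng)
  lo <- 1 - roughness * spread
  list(values = lo + (1 - lo) * z01, seed = seed)
}

#' @rdname generate_wrinkle_map
#' @export
flat_wrinkle_map <- function(shape) {
  list(values = matrix(1, shape[1], shape[2]), seed = NA_integer_)
}

.gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  # separable convolution with replicated edges
  pad_idx <- function(n) pmin(n, pmax(1, seq(1 - r, n + r)))
  mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
  col_f <- apply(mp, 2, function(v) stats::filter(v, k, sides = 2))
  col_f <- col_f[(r + 1):(r + nrow(m)), ]
  row_f <- t(apply(col_f, 1, function(v) stats::filter(v, k, sides = 2)))
  row_f[, (r + 1):(r + ncol(m))]
}

#' Apply a synthetic cover to a frame
#'
#' Pixels inside `mask` and within the row interval `region` are multiplied
#' by an effective factor `F_eff = F * (w_floor + (1 - w_floor) * wrinkle)`,
#' so the wrinkle map modulates the cover's attenuation between `F * w_floor`
#' (fully folded cloth) and `F` (flat cloth).  All other pixels are returned
#' bitwise unchanged, and no pixel ever gains intensity.
#'
#' @param frame An [ir_frame()].
#' @param mask Body mask from [body_mask()].
#' @param factor Attenuation factor `F` in `(0, 1]`.
#' @param wrinkle Wrinkle map from [generate_wrinkle_map()] (or
#'   [flat_wrinkle_map()]).
#' @param region `c(top_row, bottom_row)` of the covered band, 0-based,
#'   inclusive; must lie within the frame and inside the lower three
#'   fourths.
#' @param w_floor Minimum fraction of `F` retained under the darkest
#'   wrinkle (default 0.5).
#' @return An [ir_frame()] with `cover = "synthetic"`.
#' @export
synthesize_cover <- function(frame, mask, factor, wrinkle,
                             region, w_floor = 0.5) {
  stopifnot(factor > 0, factor <= 1, w_floor >= 0, w_floor <= 1)
  H <- nrow(frame$pixels)
  region <- as.integer(round(region))
  if (region[1] < 0 || region[2] > H - 1 || region[1] > region[2])
    stop("region must be a row interval within the frame")
  if (region[1] < floor(0.25 * H) - 1)
    stop("cover region must lie in the lower three fourths of the frame")
  px <- frame$pixels
  rows <- (region[1] + 1):(region[2] + 1)
  sel <- matrix(FALSE, nrow(px), ncol(px))
  sel[rows, ] <- TRUE
  sel <- sel & mask$mask
  f_eff <- factor * (w_floor + (1 - w_floor) * wrinkle$values)
  px[sel] <- px[sel] * f_eff[sel]
  ir_frame(px, cover = "synthetic")
}

#' Add Gaussian sensor noise
#'
#' @param frame An [ir_frame()].
#' @param sigma Noise standard deviation (`0` returns the frame unchanged).
#' @param seed Integer RNG seed.
#' @return A noisy frame, clipped to `[0, 1]`, same cover state.
#' @export
add_sensor_noise <- function(frame, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(frame)
  px <- frame$pixels
  noise <- with_seed(seed, matrix(rnorm(length(px), 0, sigma),
                                  nrow(px), ncol(px)))
  ir_frame(pmin(pmax(px + noise, 0), 1), cover = frame$cover)
}

#' Heavily attenuate a random rectangular region
#'
#' Simulates complete obstruction of part of the scene (an object on the
#' bed, a failing sensor region).
#'
#' @param frame An [ir_frame()].
#' @param seed Integer RNG seed.
#' @param max_area_fraction Maximum fraction of the frame the rectangle may
#'   occupy, in `(0, 1)`.
#' @param attenuation Multiplier applied inside the rectangle, in `[0, 1)`.
#' @return The occluded frame, same cover state.
#' @export
occlude_random_region <- function(frame, seed, max_area_fraction = 0.15,
                                  attenuation = 0.05) {
  stopifnot(max_area_fraction > 0, max_area_fraction < 1,
            attenuation >= 0, attenuation < 1)
  px <- frame$pixels
  H <- nrow(px); W <- ncol(px)
  with_seed(seed, {
    # sample a rectangle with area <= max_area_fraction * H * W
    max_area <- max_area_fraction * H * W
    rh <- sample.int(max(1L, min(H, floor(sqrt(max_area)))), 1)
    rw <- sample.int(max(1L, min(W, floor(max_area / rh))), 1)
    r0 <- sample.int(H - rh + 1L, 1)
    c0 <- sample.int(W - rw + 1L, 1)
    px[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L)] <-
      px[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L)] * attenuation
  })
  ir_frame(px, cover = frame$cover)
}

#' Horizontal flip of a frame and its pose
#'
#' Mirrors the image about the vertical axis (`x -> width - 1 - x`) and
#' swaps the left/right keypoint pairs from [mirror_pairs()], since after
#' flipping the anatomical left limbs appear where the right ones were.
#' Applying the operation twice restores the input exactly.
#'
#' @param frame An [ir_frame()].
#' @param pose Optional 14 x 2 pose matrix (or NULL).
#' @return A list with `frame` and `pose` (NULL if no pose given).
#' @export
hflip <- function(frame, pose = NULL) {
  px <- frame$pixels[, ncol(frame$pixels):1, drop = FALSE]
  out_pose <- NULL
  if (!is.null(pose)) {
    check_pose(pose)
    out_pose <- pose
    out_pose[, 1] <- (ncol(frame$pixels) - 1) - pose[, 1]
    mp <- mirror_pairs()
    swapped <- out_pose
    swapped[mp[, 1], ] <- out_pose[mp[, 2], ]
    swapped[mp[, 2], ] <- out_pose[mp[, 1], ]
    out_pose <- swapped
  }
  list(frame = ir_frame(px, cover = frame$cover), pose = out_pose)
}

#' On-the-fly training augmentation
#'
#' Independently applies synthetic cover, sensor noise, occlusion and
#' horizontal flip with the configured probabilities, compounding whichever
#' fire.  A cover factor is drawn from the bank once per synthesised image.
#'
#' @param frame Uncovered [ir_frame()].
#' @param pose 14 x 2 pose matrix.
#' @param bank [attenuation_bank()] to draw cover factors from (NULL
#'   disables the cover augmentation).
#' @param seed Integer RNG seed.
#' @param probs Named probabilities: `cover`, `noise`, `occlude`, `flip`.
#' @param noise_sigma Sensor-noise standard deviation.
#' @param wrinkle_roughness Roughness of the wrinkle field.
#' @return A list with the augmented `frame` and `pose`.
#' @export
augment_sample <- function(frame, pose, bank, seed,
                           probs = c(cover = 0.8, noise = 0.5,
                                     occlude = 0.3, flip = 0.5),
                           noise_sigma = 0.03, wrinkle_roughness = 0.3) {
  H <- nrow(frame$pixels)
  with_seed(seed, {
    u <- runif(4)
    sub <- floor(runif(4, 1, 1e8))
    if (!is.null(bank) && u[1] < probs[["cover"]]) {
      f <- sample(bank$factors, 1)
      mask <- body_mask(frame, "otsu")
      wr <- generate_wrinkle_map(dim(frame$pixels), sub[1],
                                 roughness = wrinkle_roughness)
      top <- round(runif(1, 0.25 * H, 0.6 * H))
      frame <- synthesize_cover(frame, mask, f, wr, c(top, H - 1))
    }
    if (u[2] < probs[["noise"]])
      frame <- add_sensor_noise(frame, noise_sigma, sub[2])
    if (u[3] < probs[["occlude"]])
      frame <- occlude_random_region(frame, sub[3])
    if (u[4] < probs[["flip"]]) {
      fl <- hflip(frame, pose)
      frame <- fl$frame
      pose <- fl$pose
    }
  })
  list(frame = frame, pose = pose)
}

#' Serialize / load an attenuation bank as JSON
#'
#' @param bank An [attenuation_bank()].
#' @param path File path.
#' @export
save_bank <- function(bank, path) {
  jsonlite::write_json(list(factors = bank$factors,
                            source_count = bank$source_count),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  attenuation_bank(j$factors, j$source_count)
}
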