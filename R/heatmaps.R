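# Gaussian heatmap encoding with a shrinking-radius schedule, and decoding
# to sub-pixel keypoints: argmax seeding, iterative d x d centre-of-mass
# refinement, and flip-averaged inference.

#' Refinement parameters for sub-pixel decoding
#'
#' @param d Centre-of-mass window size in heatmap pixels; odd, default 5.
#' @param iterations Number of refinement iterations, default 3.
#' @return A list with `d` and `iterations`.
#' @export
refinement_params <- function(d = 5L, iterations = 3L) {
  d <- as.integer(d)
  iterations <- as.integer(iterations)
  if (d < 1 || d %% 2L == 0L) stop("window size d must be odd and >= 1")
  if (iterations < 0) stop("iterations must be >= 0")
  list(d = d, iterations = iterations)
}

#' Construct a heatmap stack
#'
#' @param maps `H' x W' x 14` array of non-negative scores.
#' @param scale Ratio of input resolution to heatmap resolution; a scalar
#'   or `c(sx, sy)` for anisotropic scaling.
#' @param visible Logical vector of length 14; FALSE marks keypoints whose
#'   channel carries no information (all zero).
#' @return An object of class `heatmap_stack`.
#' @export
heatmap_stack <- function(maps, scale = 1, visible = rep(TRUE, dim(maps)[3])) {
  stopifnot(length(dim(maps)) == 3)
  if (dim(maps)[3] != 14) stop("a heatmap stack has exactly 14 channels")
  if (any(!is.finite(maps)) || any(maps < 0))
    stop("heatmap scores must be finite and non-negative")
  if (length(scale) == 1) scale <- c(scale, scale)
  structure(list(maps = maps, scale = scale, visible = visible),
            class = "heatmap_stack")
}

#' @export
print.heatmap_stack <- function(x, ...) {
  cat(sprintf("<heatmap_stack %dx%dx%d scale=(%.3g, %.3g) visible=%d/14>\n",
              dim(x$maps)[1], dim(x$maps)[2], dim(x$maps)[3],
              x$scale[1], x$scale[2], sum(x$visible)))
  invisible(x)
}

#' Gaussian radius schedule
#'
#' The target-kernel radius shrinks linearly from `start_radius` to
#' `end_radius` over the first `ramp_epochs` training epochs and stays at
#' `end_radius` afterwards.  Diffuse early targets help the network find
#' coarse keypoint locations before being asked to pinpoint them.
#'
#' @param epoch Epoch index, 0-based, `>= 0`.
#' @param start_radius Radius at epoch 0 (pixels).
#' @param end_radius Radius after the ramp (pixels).
#' @param ramp_epochs Length of the linear ramp in epochs.
#' @return Radius in pixels.
#' @export
radius_at_epoch <- function(epoch, start_radius = 3, end_radius = 1,
                            ramp_epochs = 30) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  frac <- pmin(1, epoch / ramp_epochs)
  start_radius + frac * (end_radius - start_radius)
}

#' Encode a pose as Gaussian heatmaps
#'
#' Each keypoint becomes an isotropic Gaussian (`sigma = radius / 2`,
#' truncated at 3 sigma) peaked at the keypoint position mapped into
#' heatmap coordinates by `1 / scale`.  With `normalize = "sum"` (default)
#' each in-bounds channel sums to 1, commensurate with a spatial-softmax
#' network output; `normalize = "peak"` instead scales the peak to 1 for
#' MSE-on-raw-heatmap training.  Keypoints mapping outside the heatmap
#' yield an all-zero channel flagged invisible.
#'
#' @param pose 14 x 2 pose matrix in input-image pixels.
#' @param shape `c(H', W')` heatmap shape.
#' @param scale Input-to-heatmap resolution ratio (scalar or `c(sx, sy)`).
#' @param radius Gaussian radius in heatmap pixels, `>= 1`.
#' @param normalize `"sum"` or `"peak"`.
#' @return A [heatmap_stack()].
#' @export
encode_pose <- function(pose, shape, scale = 1, radius = 3,
                        normalize = c("sum", "peak")) {
  check_pose(pose)
  normalize <- match.arg(normalize)
  if (radius < 1) stop("radius must be >= 1")
  Hh <- as.integer(shape[1]); Wh <- as.integer(shape[2])
  if (Hh < 1 || Wh < 1) stop("heatmap shape must be positive")
  if (length(scale) == 1) scale <- c(scale, scale)
  sigma <- radius / 2
  trunc2 <- (3 * sigma)^2
  maps <- array(0, dim = c(Hh, Wh, 14))
  visible <- rep(TRUE, 14)
  gx <- matrix(rep(0:(Wh - 1), each = Hh), Hh, Wh)
  gy <- matrix(rep(0:(Hh - 1), Wh), Hh, Wh)
  for (i in 1:14) {
    cx <- pose[i, 1] / scale[1]
    cy <- pose[i, 2] / scale[2]
    if (cx < 0 || cx > Wh - 1 || cy < 0 || cy > Hh - 1) {
      visible[i] <- FALSE
      next
    }
    d2 <- (gx - cx)^2 + (gy - cy)^2
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > trunc2] <- 0
    if (normalize == "sum") {
      s <- sum(g)
      if (s > 0) g <- g / s
    } else {
      m <- max(g)
      if (m > 0) g <- g / m
    }
    maps[, , i] <- g
  }
  heatmap_stack(maps, scale = scale, visible = visible)
}

#' Argmax seed of a single heatmap channel
#'
#' Returns the 0-based `(x, y)` pixel coordinates of the largest score.
#' Ties break to the smallest row, then the smallest column, so decoding
#' is deterministic.  A constant channel is undecodable and errors.
#'
#' @param map Numeric matrix (one heatmap channel).
#' @return Numeric `c(x, y)`, 0-based.
#' @export
argmax_seed <- function(map) {
  rng <- range(map)
  if (rng[1] == rng[2]) stop("constant channel: keypoint undecodable")
  idx <- which(map == rng[2], arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  c(x = unname(idx[1, 2]) - 1, y = unname(idx[1, 1]) - 1)
}

#' Iterative centre-of-mass refinement of a keypoint estimate
#'
#' Starting from an integer seed, each of `iterations` rounds (i) snaps the
#' current estimate to the nearest pixel (`floor(v + 0.5)`), (ii) computes
#' the intensity-weighted centroid of the `d x d` window centred there
#' (out-of-bounds pixels contribute zero), and (iii) moves the estimate to
#' the centroid.  If a window has zero total mass the seed is returned
#' unchanged with `converged = FALSE`.
#'
#' @param map Numeric matrix (one heatmap channel, non-negative).
#' @param seed Numeric `c(x, y)` starting estimate, 0-based.
#' @param params [refinement_params()].
#' @return A list with `xy` (sub-pixel `c(x, y)`) and `converged`.
#' @export
refine_keypoint <- function(map, seed, params = refinement_params()) {
  H <- nrow(map); W <- ncol(map)
  x <- seed[[1]]; y <- seed[[2]]
  if (x < 0 || x > W - 1 || y < 0 || y > H - 1)
    stop("seed lies outside the heatmap")
  half <- (params$d - 1L) %/% 2L
  # plain loops, accumulating in a fixed order, so results are exactly
  # reproducible down to the last bit (the window is at most d x d)
  for (n in seq_len(params$iterations)) {
    xi <- floor(x + 0.5)
    yi <- floor(y + 0.5)
    S <- 0
    sx <- 0
    sy <- 0
    for (i in (-half):half) {
      cx <- xi + i
      for (j in (-half):half) {
        cy <- yi + j
        v <- if (cx >= 0 && cx <= W - 1 && cy >= 0 && cy <= H - 1)
          map[cy + 1, cx + 1] else 0
        S <- S + v
        sx <- sx + v * cx
        sy <- sy + v * cy
      }
    }
    if (S == 0) return(list(xy = c(x = seed[[1]], y = seed[[2]]),
                            converged = FALSE))
    x <- sx / S
    y <- sy / S
  }
  list(xy = c(x = x, y = y), converged = TRUE)
}

#' Flip-averaged heatmaps
#'
#' Combines the prediction on an image with the prediction on its
#' horizontal mirror: the second stack is mirrored back and its left/right
#' channel pairs are swapped (the mirrored image's "left wrist" channel
#' describes the anatomical right wrist), then the element-wise mean of
#' the two stacks is returned.
#'
#' @param stack_original [heatmap_stack()] predicted on the original image.
#' @param stack_flipped [heatmap_stack()] predicted on the horizontally
#'   flipped image.
#' @return A [heatmap_stack()].
#' @export
flip_average <- function(stack_original, stack_flipped) {
  a <- stack_original$maps
  b <- stack_flipped$maps
  if (!identical(dim(a), dim(b))) stop("heatmap stacks differ in shape")
  b <- b[, dim(b)[2]:1, , drop = FALSE]       # mirror columns back
  mp <- mirror_pairs()
  bs <- b
  bs[, , mp[, 1]] <- b[, , mp[, 2]]
  bs[, , mp[, 2]] <- b[, , mp[, 1]]
  heatmap_stack((a + bs) / 2, scale = stack_original$scale,
                visible = stack_original$visible & stack_flipped$visible)
}

#' Decode a heatmap stack to a pose
#'
#' Per channel: argmax seeding, iterative centre-of-mass refinement, then
#' multiplication by the stack's scale to return to input-image
#' coordinates.  Undecodable (constant or all-zero) channels produce `NA`
#' coordinates and are flagged invisible.
#'
#' @param stack A [heatmap_stack()].
#' @param params [refinement_params()].
#' @return A list with `pose` (14 x 2 matrix, possibly containing NA) and
#'   `visible` (logical 14-vector).
#' @export
decode_pose <- function(stack, params = refinement_params()) {
  maps <- stack$maps
  pose <- matrix(NA_real_, 14, 2,
                 dimnames = list(keypoint_names(), c("x", "y")))
  visible <- rep(TRUE, 14)
  for (i in 1:14) {
    ch <- maps[, , i]
    if (min(ch) == max(ch)) {
      visible[i] <- FALSE
      next
    }
    seed <- argmax_seed(ch)
    ref <- refine_keypoint(ch, seed, params)
    pose[i, ] <- c(ref$xy[[1]] * stack$scale[1], ref$xy[[2]] * stack$scale[2])
  }
  list(pose = pose, visible = visible)
}

#' Serialize / load a heatmap stack
#'
#' Stored as a gzip-compressed stream of doubles with a JSON header
#' recording shape, scale, visibility and channel order.
#'
#' @param stack A [heatmap_stack()].
#' @param path Output path (two files: `path` and `path.json`).
#' @export
save_heatmaps <- function(stack, path) {
  con <- gzfile(path, "wb")
  writeBin(as.numeric(stack$maps), con, size = 8)
  close(con)
  jsonlite::write_json(list(shape = dim(stack$maps), scale = stack$scale,
                            visible = stack$visible,
                            channels = keypoint_names()),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_heatmaps
#' @export
load_heatmaps <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(path, "rb")
  vals <- readBin(con, "double", n = prod(hdr$shape), size = 8)
  close(con)
  heatmap_stack(array(vals, dim = hdr$shape), scale = hdr$scale,
                visible = hdr$visible)
}
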