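# Synthetic LWIR in-bed fixtures: articulated 14-keypoint skeletons rendered
# as warm capsules on a cool background, with covered variants produced by
# the statistical cover synthesis so attenuation estimation can be tested
# against recorded ground truth.

#' Construct an IR frame
#'
#' A frame is a single-channel intensity grid with all values in `[0, 1]`
#' plus a provenance tag describing its cover state.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]` (rows = image rows).
#' @param cover One of `"none"`, `"thin"`, `"thick"`, `"synthetic"`.
#' @return An object of class `ir_frame` with fields `pixels` and `cover`.
#' @export
ir_frame <- function(pixels, cover = "none") {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 8 || ncol(pixels) < 8)
    stop("frame must be at least 8x8 pixels")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1))
    stop("frame intensities must be finite and within [0, 1]")
  cover <- match.arg(cover, c("none", "thin", "thick", "synthetic"))
  structure(list(pixels = pixels, cover = cover), class = "ir_frame")
}

#' @export
print.ir_frame <- function(x, ...) {
  cat(sprintf("<ir_frame %dx%d cover=%s range=[%.3f, %.3f]>\n",
              nrow(x$pixels), ncol(x$pixels), x$cover,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Keypoint order, mirror pairs and skeleton edges
#'
#' Keypoints follow the LSP-style 14-joint convention:
#' right ankle, right knee, right hip, left hip, left knee, left ankle,
#' right wrist, right elbow, right shoulder, left shoulder, left elbow,
#' left wrist, neck, head top.  `mirror_pairs()` lists the left/right
#' partner indices used when flipping images horizontally, and
#' `skeleton_edges()` the parent-child bone segments used for rendering.
#'
#' @return `keypoint_names()`: character vector of length 14.
#' @export
keypoint_names <- function() {
  c("r_ankle", "r_knee", "r_hip", "l_hip", "l_knee", "l_ankle",
    "r_wrist", "r_elbow", "r_shoulder", "l_shoulder", "l_elbow", "l_wrist",
    "neck", "head_top")
}

#' @rdname keypoint_names
#' @return `mirror_pairs()`: two-column integer matrix of mirror partners.
#' @export
mirror_pairs <- function() {
  cbind(c(1L, 2L, 3L, 7L, 8L, 9L), c(6L, 5L, 4L, 12L, 11L, 10L))
}

#' @rdname keypoint_names
#' @return `skeleton_edges()`: two-column integer matrix of bone segments.
#' @export
skeleton_edges <- function() {
  rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L),
        c(7L, 8L), c(8L, 9L), c(9L, 13L), c(13L, 10L), c(10L, 11L),
        c(11L, 12L), c(13L, 14L))
}

#' Validate a pose matrix
#'
#' @param pose A 14 x 2 numeric matrix of `(x, y)` pixel coordinates
#'   (x = column, y = row, 0-based, pixel centres at integers).
#' @param allow_outside Allow coordinates outside any frame (used for
#'   deformed negative-example poses).
#' @return The pose, invisibly; errors if malformed.
#' @export
check_pose <- function(pose, allow_outside = TRUE) {
  if (!is.matrix(pose) || nrow(pose) != 14 || ncol(pose) != 2)
    stop("a pose must be a 14 x 2 matrix of (x, y) coordinates")
  if (any(!is.finite(pose))) stop("pose coordinates must be finite")
  invisible(pose)
}

#' Anthropometric prior for the fixture skeleton
#'
#' Segment-length ranges are fractions of frame height, loosely matching
#' adult body proportions viewed from above a bed.  These bounds are also
#' what the generator promises: every sampled pose respects them.
#'
#' @param height,width Frame dimensions in pixels.
#' @return A list of `c(min, max)` length ranges in pixels plus angle ranges
#'   in radians.
#' @export
pose_prior <- function(height = 160, width = 120) {
  H <- height
  list(
    head = c(0.075, 0.095) * H,
    torso = c(0.27, 0.32) * H,
    shoulder_hw = c(0.075, 0.095) * H,
    hip_hw = c(0.055, 0.075) * H,
    upper_arm = c(0.13, 0.16) * H,
    forearm = c(0.12, 0.15) * H,
    thigh = c(0.18, 0.22) * H,
    shank = c(0.17, 0.21) * H,
    arm_abduct = c(-0.2, 0.65),     # upper-arm angle from straight down
    elbow_bend = c(-0.3, 0.9),
    leg_abduct = c(-0.12, 0.38),
    knee_bend = c(-0.25, 0.25),
    height = height, width = width
  )
}

rot_down <- function(len, ang, sign) {
  # unit "down" direction rotated by ang; sign = +1 for left side (+x),
  # -1 for right side (-x), so positive angles abduct away from the body.
  c(sign * len * sin(ang), len * cos(ang))
}

#' Sample an articulated lying pose
#'
#' Draws joint angles and segment lengths from [pose_prior()] to build a
#' 14-keypoint skeleton of a subject lying head-up in the frame.  The same
#' seed always yields the same pose; out-of-frame samples are rejected and
#' redrawn deterministically.
#'
#' @param seed Integer RNG seed.
#' @param family Pose family: `"supine"`, `"side-left"` or `"side-right"`.
#' @param height,width Frame dimensions in pixels.
#' @param prior Prior from [pose_prior()].
#' @return A 14 x 2 pose matrix (columns x, y).
#' @export
generate_subject_pose <- function(seed, family = "supine",
                                  height = 160, width = 120,
                                  prior = pose_prior(height, width)) {
  family <- match.arg(family, c("supine", "side-left", "side-right"))
  with_seed(seed, {
    for (attempt in 1:200) {
      p <- .sample_pose_once(family, height, width, prior)
      if (.pose_in_frame(p, height, width)) return(p)
    }
    stop("could not sample an in-frame pose; frame too small for the prior")
  })
}

.sample_pose_once <- function(family, height, width, prior) {
  ru <- function(r) runif(1, r[1], r[2])
  H <- height; W <- width
  tilt <- switch(family, supine = rnorm(1, 0, 0.04),
                 `side-left` = rnorm(1, 0.1, 0.04),
                 `side-right` = rnorm(1, -0.1, 0.04))
  cx <- runif(1, 0.44 * W, 0.56 * W)
  head_y <- runif(1, 0.06 * H, 0.13 * H)
  head_len <- ru(prior$head)
  torso_len <- ru(prior$torso)

  head_top <- c(cx, head_y)
  axis <- c(sin(tilt), cos(tilt))
  neck <- head_top + head_len * axis
  pelvis <- neck + torso_len * axis
  perp <- c(axis[2], -axis[1])  # points to subject's left (+x side)

  sh_hw <- ru(prior$shoulder_hw)
  hip_hw <- ru(prior$hip_hw)
  r_sh <- neck - sh_hw * perp
  l_sh <- neck + sh_hw * perp
  r_hip <- pelvis - hip_hw * perp
  l_hip <- pelvis + hip_hw * perp

  bend_bias <- switch(family, supine = 0, `side-left` = 0.35,
                      `side-right` = -0.35)

  limb <- function(origin, sign, l1r, l2r, a1r, a2r, bias) {
    a1 <- ru(a1r) + bias * sign
    a2 <- ru(a2r)
    mid <- origin + rot_down(ru(l1r), a1, sign)
    end <- mid + rot_down(ru(l2r), a1 + a2, sign)
    rbind(mid, end)
  }

  arm_r <- limb(r_sh, -1, prior$upper_arm, prior$forearm,
                prior$arm_abduct, prior$elbow_bend, bend_bias)
  arm_l <- limb(l_sh, +1, prior$upper_arm, prior$forearm,
                prior$arm_abduct, prior$elbow_bend, bend_bias)
  leg_r <- limb(r_hip, -1, prior$thigh, prior$shank,
                prior$leg_abduct, prior$knee_bend, bend_bias * 0.6)
  leg_l <- limb(l_hip, +1, prior$thigh, prior$shank,
                prior$leg_abduct, prior$knee_bend, bend_bias * 0.6)

  pose <- rbind(
    leg_r[2, ], leg_r[1, ], r_hip, l_hip, leg_l[1, ], leg_l[2, ],
    arm_r[2, ], arm_r[1, ], r_sh, l_sh, arm_l[1, ], arm_l[2, ],
    neck, head_top)
  dimnames(pose) <- list(keypoint_names(), c("x", "y"))
  pose
}

.pose_in_frame <- function(pose, height, width, margin = 2) {
  all(pose[, 1] >= margin & pose[, 1] <= width - 1 - margin &
      pose[, 2] >= margin & pose[, 2] <= height - 1 - margin)
}

# Distance from every pixel centre to segment p-q, vectorised over the grid.
.seg_dist <- function(gx, gy, p, q) {
  v <- q - p
  L2 <- sum(v^2)
  if (L2 < 1e-12) {
    sqrt((gx - p[1])^2 + (gy - p[2])^2)
  } else {
    t <- ((gx - p[1]) * v[1] + (gy - p[2]) * v[2]) / L2
    t <- pmin(1, pmax(0, t))
    sqrt((gx - (p[1] + t * v[1]))^2 + (gy - (p[2] + t * v[2]))^2)
  }
}

#' Render a pose as a synthetic LWIR frame
#'
#' Bones are drawn as anti-aliased warm capsules (1-pixel linear edge ramp),
#' the torso as a wide capsule between neck and pelvis, and the head as a
#' disk.  Per-part emissivity multipliers in `[0.92, 1]` (seeded) give mild
#' intensity variation unless `uniform_body = TRUE`, in which case the whole
#' body renders at exactly `body_intensity` — the configuration used for
#' attenuation-recovery fixtures.
#'
#' @param pose 14 x 2 pose matrix.
#' @param seed Integer seed for the per-part intensity variation.
#' @param body_intensity Peak body intensity in `(0, 1]`.
#' @param background_intensity Background level, strictly below
#'   `body_intensity`.
#' @param height,width Frame dimensions.
#' @param uniform_body Disable per-part intensity variation.
#' @return An [ir_frame()] with `cover = "none"`.
#' @export
render_frame <- function(pose, seed = 0L, body_intensity = 0.8,
                         background_intensity = 0.1,
                         height = 160, width = 120, uniform_body = FALSE) {
  check_pose(pose)
  stopifnot(body_intensity > background_intensity,
            body_intensity > 0, body_intensity <= 1,
            background_intensity >= 0)
  if (sqrt(sum((pose[13, ] - pose[14, ])^2)) < 1e-9)
    stop("degenerate pose: neck and head top coincide")

  H <- height; W <- width
  gx <- matrix(rep(0:(W - 1), each = H), H, W)
  gy <- matrix(rep(0:(H - 1), W), H, W)

  neck <- pose[13, ]; head_top <- pose[14, ]
  pelvis <- (pose[3, ] + pose[4, ]) / 2
  sh_w <- sqrt(sum((pose[9, ] - pose[10, ])^2))
  head_len <- sqrt(sum((neck - head_top)^2))

  parts <- list(
    list(p = neck, q = pelvis, r = 0.55 * sh_w),                 # torso
    list(p = pose[9, ], q = pose[10, ], r = 0.22 * sh_w),        # shoulders
    list(p = pose[3, ], q = pose[4, ], r = 0.26 * sh_w),         # hips
    list(p = head_top + 0.45 * (neck - head_top),
         q = head_top + 0.55 * (neck - head_top), r = 0.62 * head_len),
    list(p = pose[2, ], q = pose[1, ], r = 0.030 * H),           # r shank
    list(p = pose[3, ], q = pose[2, ], r = 0.038 * H),           # r thigh
    list(p = pose[4, ], q = pose[5, ], r = 0.038 * H),           # l thigh
    list(p = pose[5, ], q = pose[6, ], r = 0.030 * H),           # l shank
    list(p = pose[9, ], q = pose[8, ], r = 0.028 * H),           # r upper arm
    list(p = pose[8, ], q = pose[7, ], r = 0.024 * H),           # r forearm
    list(p = pose[10, ], q = pose[11, ], r = 0.028 * H),         # l upper arm
    list(p = pose[11, ], q = pose[12, ], r = 0.024 * H)          # l forearm
  )

  mult <- with_seed(seed, runif(length(parts), 0.92, 1))
  mult[1] <- 1  # torso always carries the peak intensity
  if (uniform_body) mult[] <- 1

  body <- matrix(0, H, W)
  for (i in seq_along(parts)) {
    d <- .seg_dist(gx, gy, parts[[i]]$p, parts[[i]]$q)
    w <- pmin(1, pmax(0, parts[[i]]$r + 0.5 - d))  # 1 px anti-alias ramp
    body <- pmax(body, w * mult[i])
  }
  px <- pmax(body * body_intensity, background_intensity)
  ir_frame(pmin(px, 1), cover = "none")
}

#' Write / read a frame as 8-bit grayscale PNG
#'
#' @param frame An [ir_frame()].
#' @param path Output file path.
#' @return `write_frame()`: the path, invisibly. `read_frame()`: an
#'   [ir_frame()].
#' @export
write_frame <- function(frame, path) {
  png::writePNG(frame$pixels, target = path)
  invisible(path)
}

#' @rdname write_frame
#' @param cover Cover state to tag the loaded frame with.
#' @export
read_frame <- function(path, cover = "none") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  ir_frame(px, cover = cover)
}

#' Build a synthetic dataset manifest on disk
#'
#' Emulates the structure of an in-bed LWIR study: annotated uncovered
#' training frames, unannotated covered training frames (thin and thick
#' covers), and annotated covered validation/test frames.  Covered frames
#' are produced by [synthesize_cover()] with a recorded true attenuation
#' factor, written to `attenuation_true.json`, so estimation can be checked
#' against ground truth.  Thin covers draw F from `U(0.72, 0.90)`, thick
#' covers from `U(0.42, 0.62)` (consistent with exponential attenuation at
#' roughly triple thickness).
#'
#' @param n_uncovered,n_thin,n_thick Training frame counts.
#' @param n_val,n_test Covered validation / test frame counts (split evenly
#'   between thin and thick).
#' @param seed Integer seed; the same seed reproduces the directory bit for
#'   bit.
#' @param out_dir Output directory (created if needed).
#' @param height,width Frame dimensions.
#' @param wrinkle_roughness Roughness of the synthetic wrinkle field applied
#'   to covers; 0 disables wrinkling.
#' @param uniform_body Render bodies at uniform intensity (used by
#'   attenuation-recovery tests).
#' @param families Pose families sampled with probabilities
#'   `family_probs`.
#' @param family_probs Sampling probabilities for `families`.
#' @return The manifest: a list with `records` (data frame), `poses`
#'   (list of 14 x 2 matrices or NULL), `true_factors`, `seed`, `dir`,
#'   `height`, `width`.
#' @export
build_manifest <- function(n_uncovered, n_thin, n_thick, n_val, n_test,
                           seed, out_dir, height = 160, width = 120,
                           wrinkle_roughness = 0.3, uniform_body = FALSE,
                           families = c("supine", "side-left", "side-right"),
                           family_probs = c(0.6, 0.2, 0.2)) {
  stopifnot(n_uncovered >= 0, n_thin >= 0, n_thick >= 0,
            n_val >= 0, n_test >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  specs <- list()
  add <- function(n, cover, split, annotated) {
    if (n > 0)
      for (i in seq_len(n))
        specs[[length(specs) + 1]] <<- list(cover = cover, split = split,
                                            annotated = annotated)
    invisible(NULL)
  }
  add(n_uncovered, "none", "train", TRUE)
  add(n_thin, "thin", "train", FALSE)
  add(n_thick, "thick", "train", FALSE)
  add(ceiling(n_val / 2), "thin", "val", TRUE)
  add(floor(n_val / 2), "thick", "val", TRUE)
  add(ceiling(n_test / 2), "thin", "test", TRUE)
  add(floor(n_test / 2), "thick", "test", TRUE)

  records <- data.frame(image = character(0), cover = character(0),
                        split = character(0), annotated = logical(0),
                        stringsAsFactors = FALSE)
  poses <- list()
  true_factors <- list()

  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    s_i <- derive_seed(seed, paste0("fixture-", i))
    fam <- with_seed(derive_seed(seed, paste0("family-", i)),
                     sample(families, 1, prob = family_probs))
    pose <- generate_subject_pose(s_i, fam, height, width)
    frame <- render_frame(pose, seed = s_i + 1L, height = height,
                          width = width, uniform_body = uniform_body)
    fname <- sprintf("frame_%04d.png", i)

    if (sp$cover != "none") {
      f_true <- with_seed(derive_seed(seed, paste0("factor-", i)), {
        if (sp$cover == "thin") runif(1, 0.72, 0.90) else runif(1, 0.42, 0.62)
      })
      # mask at just above the background level so the cover also reaches
      # the anti-aliased body edges; an Otsu mask would leave a bright
      # unattenuated halo that no real covered frame has
      mask <- body_mask(frame, 0.15)
      wr <- if (wrinkle_roughness > 0) {
        generate_wrinkle_map(c(height, width),
                             derive_seed(seed, paste0("wrinkle-", i)),
                             roughness = wrinkle_roughness)
      } else {
        flat_wrinkle_map(c(height, width))
      }
      # blanket from the chest down: everything below the uncovered head
      # quarter is attenuated, matching the estimation assumption
      top <- floor(0.25 * height)
      covered <- synthesize_cover(frame, mask, f_true, wr,
                                  region = c(top, height - 1))
      frame <- ir_frame(covered$pixels, cover = sp$cover)
      true_factors[[fname]] <- f_true
    }

    write_frame(frame, file.path(out_dir, fname))
    records <- rbind(records, data.frame(image = fname, cover = sp$cover,
                                         split = sp$split,
                                         annotated = sp$annotated,
                                         stringsAsFactors = FALSE))
    poses[fname] <- list(if (sp$annotated) pose else NULL)
  }

  manifest <- list(records = records, poses = poses,
                   true_factors = true_factors, seed = seed, dir = out_dir,
                   height = height, width = width)
  .write_manifest_json(manifest, out_dir)
  manifest
}

.write_manifest_json <- function(manifest, out_dir) {
  recs <- lapply(seq_len(nrow(manifest$records)), function(i) {
    r <- manifest$records[i, ]
    pose <- manifest$poses[[r$image]]
    list(image = r$image, cover = r$cover, split = r$split,
         keypoints = if (is.null(pose)) NULL else unname(apply(pose, 1, c,
                                                               simplify = FALSE)))
  })
  jsonlite::write_json(
    list(seed = manifest$seed, height = manifest$height,
         width = manifest$width, records = recs),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  if (length(manifest$true_factors))
    jsonlite::write_json(manifest$true_factors,
                         file.path(out_dir, "attenuation_true.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Load a manifest written by [build_manifest()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A manifest list with the same shape as [build_manifest()]'s
#'   return value.
#' @export
load_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  j <- jsonlite::read_json(path)
  records <- data.frame(
    image = vapply(j$records, `[[`, "", "image"),
    cover = vapply(j$records, `[[`, "", "cover"),
    split = vapply(j$records, `[[`, "", "split"),
    annotated = vapply(j$records, function(r) !is.null(r$keypoints), TRUE),
    stringsAsFactors = FALSE)
  poses <- setNames(lapply(j$records, function(r) {
    if (is.null(r$keypoints)) return(NULL)
    m <- t(vapply(r$keypoints, function(k) as.numeric(unlist(k)), numeric(2)))
    dimnames(m) <- list(keypoint_names(), c("x", "y"))
    m
  }), records$image)
  tf_path <- file.path(dir, "attenuation_true.json")
  true_factors <- if (file.exists(tf_path)) {
    lapply(jsonlite::read_json(tf_path), as.numeric)
  } else list()
  list(records = records, poses = poses, true_factors = true_factors,
       seed = j$seed, dir = dir, height = j$height, width = j$width)
}

#' Load the frames referenced by a manifest
#'
#' @param manifest A manifest list.
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @param cover Optional cover filter.
#' @return A named list of [ir_frame()] objects keyed by image name.
#' @export
manifest_frames <- function(manifest, split = NULL, cover = NULL) {
  recs <- manifest$records
  if (!is.null(split)) recs <- recs[recs$split %in% split, ]
  if (!is.null(cover)) recs <- recs[recs$cover %in% cover, ]
  setNames(lapply(seq_len(nrow(recs)), function(i)
    read_frame(file.path(manifest$dir, recs$image[i]), recs$cover[i])),
    recs$image)
}
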