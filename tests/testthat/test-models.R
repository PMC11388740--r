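test_that("the pose net emits one unit-sum softmax channel per keypoint", {
  cfg <- pose_net_config(height = 64, width = 48)
  net <- build_pose_net(cfg, seed = 1)
  sc <- tiny_scene()
  t0 <- Sys.time()
  hm <- predict_heatmaps(net, list(sc$frame))
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 1)
  expect_equal(dim(hm[[1]]$maps), c(32, 24, 14))
  sums <- apply(hm[[1]]$maps, 3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  # evaluation mode is deterministic
  hm2 <- predict_heatmaps(net, list(sc$frame))
  expect_identical(hm[[1]]$maps, hm2[[1]]$maps)
  expect_error(pose_net_config(backbone = "resnet999"))
})

test_that("the upscaled configuration produces 114 x 114 x 14 heatmaps", {
  cfg <- pose_net_config(height = 160, width = 120, input_size = 440,
                         heatmap_size = 114, deconv_channels = 8L,
                         stage_channels = c(4L, 8L, 8L, 8L))
  net <- build_pose_net(cfg, seed = 2)
  fr <- render_frame(random_pose(8, 160, 120), height = 160, width = 120)
  hm <- predict_heatmaps(net, list(fr))
  expect_equal(dim(hm[[1]]$maps), c(114, 114, 14))
})

test_that("the pose loss is the summed per-channel MSE with its identities", {
  st <- encode_pose(random_pose(5), c(32, 24), 2, 3)
  expect_equal(pose_loss(st, st), 0)
  zeros <- array(0, dim = c(32, 24, 14))
  const <- array(0.3, dim = c(32, 24, 14))
  expect_equal(pose_loss(const, zeros), 14 * 0.3^2, tolerance = 1e-12)
  a <- array(runif(32 * 24 * 14), dim = c(32, 24, 14))
  b <- array(runif(32 * 24 * 14), dim = c(32, 24, 14))
  expect_equal(pose_loss(a, b), pose_loss(b, a))
  expect_gt(pose_loss(a, b), 0)
  expect_error(pose_loss(a, array(0, c(16, 12, 14))))
})

test_that("pose deformations generate distinct implausible annotations", {
  pose <- random_pose(9)
  d1 <- deform_heatmaps(pose, seed = 4, mode = "limb-shrink",
                        shape = c(32, 24), scale = 2)
  d1b <- deform_heatmaps(pose, seed = 4, mode = "limb-shrink",
                         shape = c(32, 24), scale = 2)
  expect_equal(d1$pose, d1b$pose)
  expect_gt(max(abs(d1$pose - pose)), 0)
  # distal joints move onto the parent-distal segment at ratio 0.3 - 0.7
  distal <- c(1, 6, 7, 12)
  parent <- c(2, 5, 8, 11)
  for (k in seq_along(distal)) {
    v_full <- pose[distal[k], ] - pose[parent[k], ]
    v_new <- d1$pose[distal[k], ] - pose[parent[k], ]
    ratio <- sum(v_new * v_full) / sum(v_full^2)
    expect_gte(ratio, 0.3 - 1e-9)
    expect_lte(ratio, 0.7 + 1e-9)
    cross <- v_new[1] * v_full[2] - v_new[2] * v_full[1]
    expect_lt(abs(cross), 1e-9)   # stays on the segment
  }
  # jitter moves joints by at least twice the PCKh@0.5 tolerance
  l <- sqrt(sum((pose[14, ] - pose[13, ])^2))
  d2 <- deform_heatmaps(pose, seed = 6, mode = "jitter",
                        shape = c(32, 24), scale = 2)
  moved <- sqrt(rowSums((d2$pose - pose)^2))
  expect_true(all(moved[moved > 1e-9] >= l - 1e-9))
  # left/right swap exchanges exactly the mirror pairs
  d3 <- deform_heatmaps(pose, seed = 1, mode = "lr-swap",
                        shape = c(32, 24), scale = 2)
  mp <- mirror_pairs()
  expect_equal(d3$pose[mp[, 1], ], pose[mp[, 2], ], ignore_attr = TRUE)
  expect_equal(d3$pose[13:14, ], pose[13:14, ])
  expect_error(deform_heatmaps(pose, 1, mode = "melt"))
})

test_that("binary cross entropy matches its closed forms and stays finite", {
  expect_equal(discriminator_loss(0.5, 1), log(2), tolerance = 1e-9)
  expect_equal(discriminator_loss(0.5, 0), log(2), tolerance = 1e-9)
  expect_lt(discriminator_loss(1 - 1e-9, 1), 1e-6)
  big <- discriminator_loss(1 - 1e-12, 0)
  expect_true(is.finite(big))
  expect_gt(big, 10)
})

test_that("the pose discriminator scores in [0, 1] and attention gates features", {
  disc <- build_pose_discriminator(height = 64, width = 48,
                                   heatmap_shape = c(32, 24), seed = 3)
  sc <- tiny_scene()
  st <- encode_pose(sc$pose, c(32, 24), 2, 2)
  s <- discriminator_score(disc, list(sc$frame), list(st))
  expect_true(s >= 0 && s <= 1)

  # all-zero heatmaps null out the attention-multiplied features
  x <- irbedpose:::frames_to_batch(list(sc$frame))
  hm0 <- array(0, dim = c(32, 24, 14, 1))
  fw <- irbedpose:::.disc_forward(disc, x, hm0, training = FALSE)
  expect_true(all(fw$cache$feat * fw$cache$att_b == 0))
})

test_that("short supervised training monotonically reduces the pose loss", {
  d <- file.path(tempdir(), "train-smoke")
  m <- if (file.exists(file.path(d, "manifest.json"))) load_manifest(d)
       else build_manifest(20, 0, 0, 0, 0, seed = 41, out_dir = d,
                           height = 64, width = 48)
  items <- irbedpose:::.manifest_items(m, "train")
  net <- build_pose_net(pose_net_config(height = 64, width = 48), seed = 1)
  net <- train_pose_net(net, items, val_items = NULL, epochs = 6,
                        augment = FALSE, seed = 2)
  expect_equal(nrow(net$history), 6)
  expect_lt(net$history$loss[6], net$history$loss[1])
  expect_true(all(diff(net$history$loss[1:4]) < 0))
})
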