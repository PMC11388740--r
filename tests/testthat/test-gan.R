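test_that("the generator preserves shape and responds to its noise input", {
  gen <- build_generator(height = 48, width = 32, width_multiplier = 0.25,
                         seed = 1)
  xu <- render_frame(random_pose(1, 48, 32), height = 48, width = 32)
  xc <- render_frame(random_pose(2, 48, 32), height = 48, width = 32)
  s1 <- gan_synthesize(gen, xu, xc, seed = 1)
  s2 <- gan_synthesize(gen, xu, xc, seed = 2)
  expect_equal(dim(s1$pixels), dim(xu$pixels))
  expect_equal(s1$cover, "synthetic")
  expect_gt(max(abs(s1$pixels - s2$pixels)), 0)
  xu_big <- render_frame(random_pose(1, 64, 48), height = 64, width = 48)
  expect_error(
    irbedpose:::.gen_forward(gen,
                             irbedpose:::frames_to_batch(list(xu_big)),
                             irbedpose:::frames_to_batch(list(xu)),
                             gan_noise(1, 64, 1)))
})

test_that("the patch discriminator maps inputs to a one-sixteenth score map", {
  disc <- build_gan_discriminator(height = 160, width = 128,
                                  width_multiplier = 0.125, seed = 2)
  x <- array(runif(160 * 128), dim = c(160, 128, 1, 1))
  out <- irbedpose:::nn_forward(disc$spec, disc$params, disc$state, x)$y
  expect_equal(dim(out)[1:2], c(10, 8))
  expect_true(all(is.finite(out)))
  expect_error(build_gan_discriminator(height = 160, width = 120),
               "divisible")
  padded <- pad_frame_width(matrix(0.5, 160, 120))
  expect_equal(ncol(padded), 128)
})

test_that("generator loss components vanish on the constructed perfect case", {
  d <- c(12, 16, 1, 2)
  xu <- array(0.8, dim = d)
  xc <- array(0.4, dim = d)
  xs <- xu * 0.4 / 0.8                   # matches mean, std and scaled frame
  ones_map <- array(1, dim = c(3, 4, 1, 2))
  L <- generator_loss(xs, xu, xc, disc_out = ones_map)
  expect_equal(L$g1, 0)
  expect_equal(L$g2, 0)
  expect_equal(L$g3, 0)
  expect_equal(L$g4, 0)
  expect_equal(L$total, 0)

  # worked mean mismatch: (0.5 - 0.3)^2 = 0.04
  xs2 <- array(0.5, dim = d)
  xc2 <- array(0.3, dim = d)
  L2 <- generator_loss(xs2, xu, xc2)
  expect_equal(L2$g3, 0.04, tolerance = 1e-12)
  expect_error(generator_loss(xs, array(0, dim = d), xc))

  # analytic gradient of g2 + g3 + g4 agrees with finite differences
  set.seed(8)
  xs3 <- array(runif(prod(d)), dim = d)
  xu3 <- array(runif(prod(d), 0.3, 0.9), dim = d)
  xc3 <- array(runif(prod(d), 0.1, 0.6), dim = d)
  g <- irbedpose:::.generator_loss_grad(xs3, xu3, xc3)
  eps <- 1e-6
  for (j in sample(prod(d), 5)) {
    x1 <- xs3; x1[j] <- x1[j] + eps
    x2 <- xs3; x2[j] <- x2[j] - eps
    f1 <- with(generator_loss(x1, xu3, xc3), g2 + g3 + g4)
    f2 <- with(generator_loss(x2, xu3, xc3), g2 + g3 + g4)
    expect_equal(g[j], (f1 - f2) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("discriminator loss rewards ones-on-real and zeros-on-synthetic", {
  perfect_r <- array(1, dim = c(3, 2, 1, 2))
  perfect_s <- array(0, dim = c(3, 2, 1, 2))
  expect_equal(gan_discriminator_loss(perfect_r, perfect_s), 0)
  half <- array(0.5, dim = c(3, 2, 1, 2))
  expect_equal(gan_discriminator_loss(half, half), 0.25)
  # constant-map symmetry: swapping real <-> 1 - synthetic is neutral
  a <- array(0.8, dim = c(3, 2, 1, 2))
  b <- array(0.3, dim = c(3, 2, 1, 2))
  expect_equal(gan_discriminator_loss(a, b),
               gan_discriminator_loss(1 - b, 1 - a))
  expect_error(gan_discriminator_loss(a, array(0, c(2, 2, 1, 2))))
})

test_that("two-phase GAN training decays the learning rate and descends", {
  d <- file.path(tempdir(), "gan-smoke")
  m <- if (file.exists(file.path(d, "manifest.json"))) load_manifest(d)
       else build_manifest(8, 4, 4, 0, 0, seed = 21, out_dir = d,
                           height = 48, width = 32)
  cfg <- default_config(seed = 9)
  cfg$gan$epochs_solo <- 5L
  cfg$gan$epochs_tandem <- 2L
  cfg$gan$batch_size <- 4L
  res <- train_gan(m, cfg)
  h <- res$history
  expect_equal(nrow(h), 7)
  expect_equal(h$lr, 1e-3 * 0.9^(0:6), tolerance = 1e-12)
  expect_equal(h$phase, c(rep("solo", 5), rep("tandem", 2)))
  # style-matching part of the loss drops during the warm-up
  expect_lt(h$g2[5] + h$g3[5] + h$g4[5], h$g2[1] + h$g3[1] + h$g4[1])
  expect_true(all(is.finite(h$lg)))
  expect_true(all(h[, c("g1", "g2", "g3", "g4")] >= 0, na.rm = TRUE))
  expect_true(all(is.finite(h$ld[h$phase == "tandem"])))

  only_unc <- m
  only_unc$records <- m$records[m$records$cover == "none", ]
  expect_error(train_gan(only_unc, cfg), "covered")
})

test_that("the warm-up phase pulls synthetic mean intensity towards the style frames", {
  d <- file.path(tempdir(), "gan-g3")
  m <- if (file.exists(file.path(d, "manifest.json"))) load_manifest(d)
       else build_manifest(8, 4, 4, 0, 0, seed = 21, out_dir = d,
                           height = 48, width = 32)
  cfg <- default_config(seed = 9)
  cfg$gan$epochs_solo <- 8L
  cfg$gan$epochs_tandem <- 0L
  cfg$gan$batch_size <- 4L
  cfg$gan$steps_per_epoch <- 20L
  res <- train_gan(m, cfg)
  g3 <- res$history$g3
  expect_lt(g3[8], g3[1] / 5)
  # after the warm-up, the per-pair mean mismatch (rms, from the g3 term)
  # is below the raw uncovered-to-covered mean intensity gap
  xu <- manifest_frames(m, "train", "none")
  xc <- manifest_frames(m, "train", c("thin", "thick"))
  gap <- mean(abs(sapply(xu, function(f) mean(f$pixels)) -
                  mean(sapply(xc, function(f) mean(f$pixels)))))
  expect_lt(sqrt(g3[8]), gap)
})
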