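test_that("exponential attenuation follows the Beer-Lambert form", {
  expect_equal(attenuate(0.8, 1.3, 0), 0.8)
  expect_equal(attenuate(0.8, 0, 3), 0.8)
  expect_equal(attenuate(1.0, log(2), 1.0), 0.5)
  expect_error(attenuate(0.5, -1, 1))
  expect_error(attenuate(0.5, 1, -1))
})

test_that("attenuation factors are the lower/upper max ratio, with the clipping policy", {
  # constructed two-block image: upper max 0.8, lower max 0.4
  px <- matrix(0.05, 40, 30)
  px[1:10, 10:20] <- 0.8
  px[25:35, 10:20] <- 0.4
  bank <- estimate_attenuation_factors(list(ir_frame(px, "thin")))
  expect_equal(bank$factors, 0.5)

  # identical maxima -> F = 1 (kept: 1 is attainable under the model)
  px2 <- matrix(0.1, 40, 30)
  px2[5, 5] <- 0.7
  px2[30, 5] <- 0.7
  expect_equal(estimate_attenuation_factors(list(ir_frame(px2)))$factors, 1)

  # hotter lower region violates the model -> discarded, not clipped
  px3 <- matrix(0.1, 40, 30)
  px3[5, 5] <- 0.3
  px3[30, 5] <- 0.9
  expect_error(estimate_attenuation_factors(list(ir_frame(px3))))
  mixed <- estimate_attenuation_factors(list(ir_frame(px), ir_frame(px3)))
  expect_equal(mixed$factors, 0.5)

  # zero upper region -> frame skipped with a warning
  px4 <- matrix(0, 40, 30)
  px4[30, 5] <- 0.5
  expect_warning(b <- estimate_attenuation_factors(list(ir_frame(px),
                                                        ir_frame(px4))))
  expect_equal(b$factors, 0.5)
  expect_error(estimate_attenuation_factors(list()))
})

test_that("attenuation recovery on fixtures matches the recorded truth", {
  d <- file.path(tempdir(), "recovery-smoke")
  m <- build_manifest(0, 6, 0, 0, 0, seed = 13, out_dir = d, height = 64,
                      width = 48, uniform_body = TRUE, wrinkle_roughness = 0)
  bank <- estimate_attenuation_factors(manifest_frames(m, "train"))
  expect_equal(bank$factors, unname(unlist(m$true_factors)),
               tolerance = 0.02)
})

test_that("body masks threshold warm pixels, including Otsu selection", {
  f0 <- ir_frame(matrix(0, 16, 16))
  expect_equal(sum(body_mask(f0, 0.5)$mask), 0)
  two <- matrix(0.1, 16, 16)
  two[5:8, 5:8] <- 0.9
  bm <- body_mask(ir_frame(two), 0.5)
  expect_identical(bm$mask, two > 0.5)
  expect_error(body_mask(f0, 1.5))

  sc <- tiny_scene()
  ot <- body_mask(sc$frame, "otsu")
  warm <- sc$frame$pixels >= 0.4            # body intensity / 2
  expect_gte(sum(ot$mask & warm) / sum(warm), 0.95)
})

test_that("wrinkle maps are smooth, bounded, seeded random fields", {
  w1 <- generate_wrinkle_map(c(40, 30), seed = 1, roughness = 0.3)
  w2 <- generate_wrinkle_map(c(40, 30), seed = 1, roughness = 0.3)
  expect_identical(w1$values, w2$values)
  expect_true(all(w1$values >= 1 - 0.3 * 0.5 - 1e-12))
  expect_true(all(w1$values <= 1 + 1e-12))
  expect_gte(mean(w1$values < max(w1$values)), 0.01)
  # distinct seeds give substantially different fields
  maps <- lapply(1:10, function(s)
    generate_wrinkle_map(c(40, 30), s, 0.3)$values)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gte(mean(abs(maps[[i]] - maps[[j]]) > 1e-9), 0.10)
  }
  # vanishing roughness approaches the flat map
  w_eps <- generate_wrinkle_map(c(40, 30), 1, roughness = 1e-3)
  expect_gte(min(w_eps$values), 1 - 1e-3)
  expect_error(generate_wrinkle_map(c(40, 30), 1, roughness = 0))
})

test_that("synthetic covers only darken masked pixels inside the region", {
  sc <- tiny_scene()
  mask <- body_mask(sc$frame, "otsu")
  flat <- flat_wrinkle_map(dim(sc$frame$pixels))

  out_id <- synthesize_cover(sc$frame, mask, factor = 1, wrinkle = flat,
                             region = c(16, 63))
  expect_identical(out_id$pixels, sc$frame$pixels)
  expect_equal(out_id$cover, "synthetic")

  # constant body, full mask: covered pixels are exactly frame x F
  const <- ir_frame(matrix(0.8, 64, 48))
  full <- list(mask = matrix(TRUE, 64, 48), threshold_used = 0)
  cov <- synthesize_cover(const, full, 0.5, flat, region = c(16, 63))
  expect_true(all(abs(cov$pixels[17:64, ] - 0.4) < 1e-12))
  expect_true(all(cov$pixels[1:16, ] == 0.8))

  wr <- generate_wrinkle_map(c(64, 48), 3, 0.5)
  cov2 <- synthesize_cover(sc$frame, mask, 0.6, wr, region = c(20, 63))
  sel <- mask$mask
  sel[1:20, ] <- FALSE
  expect_identical(cov2$pixels[!sel], sc$frame$pixels[!sel])
  expect_true(all(cov2$pixels <= sc$frame$pixels + 1e-12))
  expect_error(synthesize_cover(sc$frame, mask, 0.6, wr, region = c(20, 99)))
  expect_error(synthesize_cover(sc$frame, mask, 0.6, wr, region = c(2, 63)))
})

test_that("sensor noise has the requested moments and seeding", {
  const <- ir_frame(matrix(0.5, 200, 150))
  expect_identical(add_sensor_noise(const, 0, 1)$pixels, const$pixels)
  n1 <- add_sensor_noise(const, 0.05, 42)
  n2 <- add_sensor_noise(const, 0.05, 42)
  expect_identical(n1$pixels, n2$pixels)
  expect_equal(mean(n1$pixels), 0.5, tolerance = 0.01)
  expect_equal(sd(as.numeric(n1$pixels)), 0.05, tolerance = 0.2 * 0.05)
})

test_that("occlusion modifies one bounded rectangle only", {
  sc <- tiny_scene()
  base <- ir_frame(matrix(0.6, 160, 120))
  occ <- occlude_random_region(base, seed = 9, max_area_fraction = 0.01,
                               attenuation = 0)
  changed <- occ$pixels != base$pixels
  expect_lte(sum(changed), 0.01 * 160 * 120)
  expect_true(all(occ$pixels[changed] == 0))
  occ2 <- occlude_random_region(base, seed = 9, max_area_fraction = 0.01,
                                attenuation = 0)
  expect_identical(occ$pixels, occ2$pixels)
})

test_that("horizontal flip is an involution that swaps left and right", {
  sc <- tiny_scene()
  fl <- hflip(sc$frame, sc$pose)
  back <- hflip(fl$frame, fl$pose)
  expect_identical(back$frame$pixels, sc$frame$pixels)
  expect_equal(back$pose, sc$pose)

  # boundary: x = 0 maps to width - 1
  pose <- sc$pose
  pose[7, ] <- c(0, 50)
  f120 <- render_frame(random_pose(2, 160, 120), height = 160, width = 120)
  flb <- hflip(f120, rbind(pose[1:6, ], c(0, 50), pose[8:14, ]))
  expect_equal(unname(flb$pose[12, 1]), 119)  # lands in the l_wrist slot

  # worked example: r_wrist (10, 50), l_wrist (100, 50), width 120
  p <- matrix(50, 14, 2)
  p[, 1] <- 60
  p[7, ] <- c(10, 50)
  p[12, ] <- c(100, 50)
  fl2 <- hflip(f120, p)
  expect_equal(unname(fl2$pose[7, ]), c(119 - 100, 50))
  expect_equal(unname(fl2$pose[12, ]), c(119 - 10, 50))
})

test_that("compound augmentation preserves frame validity and is seeded", {
  sc <- tiny_scene()
  bank <- attenuation_bank(c(0.5, 0.7))
  a1 <- augment_sample(sc$frame, sc$pose, bank, seed = 11)
  a2 <- augment_sample(sc$frame, sc$pose, bank, seed = 11)
  expect_identical(a1$frame$pixels, a2$frame$pixels)
  expect_equal(a1$pose, a2$pose)
  expect_true(all(a1$frame$pixels >= 0 & a1$frame$pixels <= 1))
  expect_error(attenuation_bank(c(0.5, 1.2)))
  b <- attenuation_bank(c(0.4, 0.9), source_count = 5)
  p <- file.path(tempdir(), "bank.json")
  save_bank(b, p)
  b2 <- load_bank(p)
  expect_equal(b$factors, b2$factors)
  expect_equal(b2$source_count, 5)
})
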