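test_that("the radius schedule shrinks linearly from 3 to 1 over 30 epochs", {
  expect_equal(radius_at_epoch(0), 3)
  expect_equal(radius_at_epoch(15), 2)
  expect_equal(radius_at_epoch(30), 1)
  expect_equal(radius_at_epoch(100), 1)
  expect_error(radius_at_epoch(-1))
})

test_that("encoding places unit-sum Gaussians at the mapped keypoints", {
  pose <- matrix(0, 14, 2)
  pose[, 1] <- seq(4, 56, length.out = 14) * 2
  pose[, 2] <- seq(6, 100, length.out = 14)
  st <- encode_pose(pose, c(60, 60), scale = c(2, 2), radius = 3)
  sums <- apply(st$maps, 3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  for (i in c(1, 7, 14)) {
    am <- argmax_seed(st$maps[, , i])
    expect_equal(unname(am["x"]), round(pose[i, 1] / 2))
    expect_equal(unname(am["y"]), round(pose[i, 2] / 2))
  }
  # peak-normalised mode for MSE-on-raw-heatmap training
  stp <- encode_pose(pose, c(60, 60), scale = 2, radius = 3,
                     normalize = "peak")
  expect_true(all(abs(apply(stp$maps, 3, max) - 1) < 1e-12))
  # out-of-bounds keypoint -> zero channel flagged invisible
  pose[3, ] <- c(500, 500)
  st2 <- encode_pose(pose, c(60, 60), scale = 2, radius = 3)
  expect_false(st2$visible[3])
  expect_true(all(st2$maps[, , 3] == 0))
  expect_error(encode_pose(pose, c(0, 60), 2, 3))
  expect_error(encode_pose(pose, c(60, 60), 2, 0.5))
})

test_that("argmax seeding breaks ties towards the smallest row then column", {
  m <- matrix(0, 12, 12)
  m[8, 10] <- 1                      # (x=9, y=7) 0-based
  expect_equal(argmax_seed(m), c(x = 9, y = 7))
  m2 <- matrix(0, 12, 12)
  m2[4, 4] <- 1
  m2[4, 10] <- 1
  expect_equal(argmax_seed(m2), c(x = 3, y = 3))
  m3 <- matrix(0, 12, 12)
  m3[9, 6] <- 1
  m3[4, 6] <- 1
  expect_equal(argmax_seed(m3), c(x = 5, y = 3))
  expect_error(argmax_seed(matrix(0.2, 5, 5)), "constant")
})

test_that("refinement agrees exactly with the brute-force transcription", {
  set.seed(7)
  for (rep in 1:100) {
    H <- sample(10:24, 1)
    W <- sample(10:24, 1)
    m <- matrix(0, H, W)
    k <- sample(3:8, 1)
    m[sample(H * W, k)] <- runif(k)
    sd0 <- c(sample(0:(W - 1), 1), sample(0:(H - 1), 1))
    got <- refine_keypoint(m, sd0, refinement_params(5, 3))
    want <- refine_oracle(m, sd0[1], sd0[2], d = 5, N = 3)
    expect_identical(unname(got$xy), want)
  }
})

test_that("refinement handles symmetric, two-pixel, and zero-mass cases", {
  g <- encode_pose(matrix(c(10, 10), 14, 2, byrow = TRUE), c(24, 24),
                   scale = 1, radius = 3)$maps[, , 1]
  r <- refine_keypoint(g, argmax_seed(g))
  expect_equal(unname(r$xy), c(10, 10), tolerance = 1e-9)

  two <- matrix(0, 20, 20)
  two[11, 11] <- 1    # (x=10, y=10)
  two[11, 12] <- 1    # (x=11, y=10)
  r2 <- refine_keypoint(two, c(10, 10), refinement_params(5, 3))
  expect_equal(unname(r2$xy), c(10.5, 10))

  empty <- matrix(0, 20, 20)
  empty[1, 1] <- 1
  r3 <- refine_keypoint(empty, c(15, 15), refinement_params(5, 3))
  expect_false(r3$converged)
  expect_equal(unname(r3$xy), c(15, 15))
  expect_error(refinement_params(d = 4))
  expect_error(refine_keypoint(two, c(40, 2)))
})

test_that("flip averaging mirrors, swaps channel pairs, and is idempotent on symmetric stacks", {
  pose <- random_pose(12)
  st <- encode_pose(pose, c(32, 24), scale = 2, radius = 3)

  # a stack passed through flip-then-flip-back equals the original
  flipped <- st$maps[, 24:1, ]
  mp <- mirror_pairs()
  fs <- flipped
  fs[, , mp[, 1]] <- flipped[, , mp[, 2]]
  fs[, , mp[, 2]] <- flipped[, , mp[, 1]]
  avg <- flip_average(st, heatmap_stack(fs, scale = st$scale))
  expect_equal(avg$maps, st$maps, tolerance = 1e-12)

  # laterally symmetric stack: averaging with itself changes nothing
  sym <- st$maps + st$maps[, 24:1, ]
  sym_sw <- sym
  sym_sw[, , mp[, 1]] <- sym[, , mp[, 2]]
  sym_sw[, , mp[, 2]] <- sym[, , mp[, 1]]
  sym <- (sym + sym_sw) / 2   # symmetric across sides and pairs
  ss <- heatmap_stack(sym, scale = 1)
  expect_equal(flip_average(ss, ss)$maps, sym, tolerance = 1e-12)

  # peaks offset +/- 1 about a column midline average to equal values
  a <- array(0, dim = c(9, 10, 14))
  b <- array(0, dim = c(9, 10, 14))
  a[5, 5, ] <- 1        # x = 4
  b[5, 5, ] <- 1        # mirrors back to x = 10 - 1 - 4 = 5
  av <- flip_average(heatmap_stack(a, 1), heatmap_stack(b, 1))
  expect_equal(av$maps[5, 5, 1], av$maps[5, 6, 1])
  expect_error(flip_average(heatmap_stack(a, 1),
                            heatmap_stack(array(0, c(5, 5, 14)), 1)))
})

test_that("encode-decode round trips stay within half a heatmap pixel", {
  set.seed(11)
  for (radius in c(1, 2, 3)) {
    for (rep in 1:12) {
      pose <- cbind(runif(14, 2 * 3, 2 * 20), runif(14, 2 * 3, 2 * 28))
      st <- encode_pose(pose, c(32, 24), scale = 2, radius = radius)
      dec <- decode_pose(st)
      err <- sqrt(rowSums((dec$pose - pose)^2)) / 2   # in heatmap pixels
      expect_lt(max(err), 0.5)
    }
  }
  # all-zero channel decodes to an invisible NA keypoint
  maps <- encode_pose(random_pose(1), c(32, 24), 2, 3)$maps
  maps[, , 5] <- 0
  dec <- decode_pose(heatmap_stack(maps, 2))
  expect_false(dec$visible[5])
  expect_true(all(is.na(dec$pose[5, ])))
})

test_that("heatmap stacks serialize with their JSON header", {
  st <- encode_pose(random_pose(4), c(32, 24), scale = c(2, 2), radius = 2)
  p <- file.path(tempdir(), "stack.bin")
  save_heatmaps(st, p)
  st2 <- load_heatmaps(p)
  expect_equal(st$maps, st2$maps, tolerance = 1e-15)
  expect_equal(st$scale, st2$scale)
  expect_equal(st$visible, st2$visible)
})
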