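test_that("nuisance regression removes its own design exactly", {
  geom <- make_geom(c(3, 3, 3))
  T <- 20
  # every voxel an exact linear ramp, zero motion -> residuals all ~0
  ramp <- array(rep(seq_len(T), each = 27) * 0.7 + 3, c(3, 3, 3, T))
  rd <- run_data(image4d(ramp, geom, 2), zero_motion(T))
  suppressWarnings(cleaned <- clean_run(rd))
  expect_lt(max(abs(cleaned$data)), 1e-10)
})

test_that("series orthogonal to the design pass through mean-centred", {
  geom <- make_geom(c(2, 2, 2))
  T <- 24
  # symmetric about the midpoint, hence orthogonal to the centred trend
  s <- (seq_len(T) - (T + 1) / 2)^2
  a <- array(rep(s, each = 8), c(2, 2, 2, T))
  rd <- run_data(image4d(a, geom, 2), zero_motion(T))
  suppressWarnings(cleaned <- clean_run(rd))
  expect_equal(cleaned$data[1, 1, 1, ], s - mean(s), tolerance = 1e-10)
})

test_that("residuals match an independent normal-equations oracle", {
  geom <- make_geom(c(3, 3, 3))
  T <- 40
  img <- make_image(c(3, 3, 3), T = T, seed = 7)
  mot <- random_motion(T, seed = 8)
  rd <- run_data(img, mot, "r")
  cleaned <- clean_run(rd)
  trend <- seq_len(T) - (T + 1) / 2
  X <- cbind(1, trend / max(abs(trend)), mot)
  for (v in list(c(1, 1, 1), c(2, 3, 1), c(3, 3, 3))) {
    y <- img$data[v[1], v[2], v[3], ]
    expect_equal(cleaned$data[v[1], v[2], v[3], ],
                 ols_resid_oracle(X, y), tolerance = 1e-8)
  }
  expect_lt(max(abs(apply(matrix(cleaned$data, 27, T), 1, mean))), 1e-10)
})

test_that("constant motion columns are dropped with a warning, not an error", {
  T <- 30
  img <- make_image(c(2, 2, 2), T = T, seed = 3)
  mot <- zero_motion(T)  # all six columns constant -> rank deficient
  expect_warning(cleaned <- clean_run(run_data(img, mot)),
                 "rank-deficient")
  expect_s3_class(cleaned, "image4d")
})

test_that("Gaussian smoothing preserves constants and fwhm 0 is identity", {
  geom <- make_geom(c(9, 9, 9))
  const <- image4d(array(3.7, c(9, 9, 9, 2)), geom, 2)
  sm <- smooth_gaussian(const, 2)
  expect_lt(max(abs(sm$data - 3.7)), 1e-10)
  img <- make_image(c(9, 9, 9), T = 3, seed = 5)
  expect_identical(smooth_gaussian(img, 0)$data, img$data)
  expect_error(smooth_gaussian(img, -1), ">= 0")
})

test_that("impulse response matches the closed-form Gaussian kernel", {
  geom <- make_geom(c(15, 15, 15))
  a <- array(0, c(15, 15, 15, 2))
  a[8, 8, 8, ] <- 1
  sm <- smooth_gaussian(image4d(a, geom, 2), fwhm_mm = 2)
  sd_mm <- 2 / (2 * sqrt(2 * log(2)))
  expect_equal(sd_mm, 0.8493218, tolerance = 1e-6)
  w <- exp(-(-4:4)^2 / (2 * sd_mm^2))
  w <- w / sum(w)
  # separable kernel: value at offset (dx,dy,dz) is w[dx]*w[dy]*w[dz]
  for (off in list(c(0, 0, 0), c(1, 0, 0), c(1, 2, 0), c(2, 2, 2))) {
    expect_equal(sm$data[8 + off[1], 8 + off[2], 8 + off[3], 1],
                 w[5 + off[1]] * w[5 + off[2]] * w[5 + off[3]],
                 tolerance = 1e-6)
  }
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-3)  # mass conserved
})

test_that("slab seed series is the arithmetic mean of member voxels", {
  geom <- make_geom(c(4, 10, 4))
  img <- make_image(c(4, 10, 4), T = 15, seed = 2, geom = geom)
  mask <- box_mask(geom, c(-2, 2), c(-4.5, 4.5), c(-2, 2), "seed")
  lab <- slice_mask(mask, "AP", 2)
  vox <- slab_voxels(lab, 1)
  oracle <- colMeans(matrix(img$data, prod(geom$dims))[vox, ])
  expect_equal(slab_seed_series(img, lab, 1), oracle, tolerance = 1e-12)
  # single-voxel slab returns that voxel's series
  v1 <- array(FALSE, c(4, 10, 4)); v1[2, 2, 2] <- TRUE
  lab1 <- slice_mask(roi_mask(v1, geom, "pt"), "AP", 2)
  expect_equal(slab_seed_series(img, lab1, 0), img$data[2, 2, 2, ])
  # cancellation: x and -x average to zero
  a <- array(0, c(4, 10, 4, 15))
  x <- rnorm(15)
  v2 <- array(FALSE, c(4, 10, 4)); v2[1, 1, 1] <- v2[2, 1, 1] <- TRUE
  a[1, 1, 1, ] <- x; a[2, 1, 1, ] <- -x
  lab2 <- slice_mask(roi_mask(v2, geom, "pair"), "AP", 2)
  expect_equal(slab_seed_series(image4d(a, geom, 2), lab2, 0),
               rep(0, 15))
  expect_error(slab_seed_series(img, lab, 99), "out of range")
})

test_that("correlation maps agree with the covariance-ratio oracle", {
  geom <- make_geom(c(3, 3, 3))
  T <- 30
  img <- make_image(c(3, 3, 3), T = T, seed = 11)
  cortex <- roi_mask(array(TRUE, c(3, 3, 3)), geom, "all")
  seed <- rnorm(T)
  r <- run_correlation_map(img, seed, cortex)
  Y <- matrix(img$data, 27)
  oracle <- apply(Y, 1, function(y)
    sum((y - mean(y)) * (seed - mean(seed))) /
      sqrt(sum((y - mean(y))^2) * sum((seed - mean(seed))^2)))
  expect_equal(r, oracle, tolerance = 1e-10)
  expect_true(all(abs(r) <= 1))
  # voxel identical to the seed: r = 1; orthogonal sinusoids: r ~ 0
  a <- img$data
  a[1, 1, 1, ] <- seed
  a[2, 1, 1, ] <- cos(2 * pi * (1:T) / 10)
  img2 <- image4d(a, geom, 2)
  r2 <- run_correlation_map(img2, sin(2 * pi * (1:T) / 10), cortex)
  expect_lt(abs(r2[2]), 1e-6)
  r3 <- run_correlation_map(img2, seed, cortex)
  expect_equal(r3[1], 1)
  # zero-variance voxel is missing, not an error
  a[3, 1, 1, ] <- 5
  r4 <- run_correlation_map(image4d(a, geom, 2), seed, cortex)
  expect_true(is.na(r4[3]))
})

test_that("Fisher transform has its closed-form values and symmetries", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))          # odd function
  expect_true(all(diff(fisher_z(r)) > 0))           # strictly increasing
  z <- seq(-4.999, 4.999, length.out = 101)
  expect_equal(fisher_z(fisher_z_inv(z)), z, tolerance = 1e-9)
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("across-run t-test reproduces the Student-t oracle", {
  res <- across_run_tmap(matrix(c(0.1, 0.2, 0.3), 3, 1), alpha = 0.001)
  expect_equal(res$t[1], 0.2 / (0.1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$t[1], 3.4641016, tolerance = 1e-6)
  expect_equal(res$df, 2L)
  expect_equal(res$p[1], 2 * pt(-3.4641016, 2), tolerance = 1e-6)
  expect_false(res$significant[1])                  # 0.074 >= 0.001
  # symmetric z around zero: t = 0, p = 1
  res0 <- across_run_tmap(matrix(c(-0.4, 0, 0.4), 3, 1))
  expect_equal(res0$t[1], 0)
  expect_equal(res0$p[1], 1)
  # identical nonzero z across runs: degenerate-variance convention
  resd <- across_run_tmap(matrix(0.3, 4, 1), alpha = 0.001)
  expect_true(resd$significant[1])
  expect_equal(resd$p[1], 0)
  resz <- across_run_tmap(matrix(0, 4, 1))
  expect_equal(resz$p[1], 1)
  expect_error(across_run_tmap(matrix(1, 1, 3)), "2 runs")
  # missing z propagates to a non-significant NA voxel
  resna <- across_run_tmap(matrix(c(0.1, NA, 0.3), 3, 1))
  expect_true(is.na(resna$p[1]))
  expect_false(resna$significant[1])
})

test_that("stat-map stacks export one t/p/mean-z volume per slab", {
  geom <- make_geom(c(4, 6, 4))
  img_a <- make_image(c(4, 6, 4), T = 20, seed = 41, geom = geom)
  img_b <- make_image(c(4, 6, 4), T = 20, seed = 42, geom = geom)
  seedm <- box_mask(geom, c(-1, 1), c(-2.5, 0.5), c(-1, 1), "seed")
  cortex <- roi_mask(!seedm$voxels, geom, "ctx")
  lab <- slice_mask(seedm, "AP", 2)
  st <- subject_stat_stack(list(img_a, img_b), lab, cortex, alpha = 0.05,
                           subject_id = "s1")
  dir <- withr::local_tempdir()
  paths <- write_stat_map_stack(st, dir)
  expect_length(paths, 3 * lab$n_slabs)
  expect_true(all(file.exists(paths)))
  vol <- RNifti::readNifti(paths[[1]])
  expect_equal(vol[st$voxel_idx[3]], st$t[1, 3], tolerance = 1e-6)
})

test_that("the statistic chain is invariant to positive rescaling", {
  geom <- make_geom(c(4, 6, 4))
  T <- 40
  img_a <- make_image(c(4, 6, 4), T = T, seed = 9, geom = geom)
  img_b <- make_image(c(4, 6, 4), T = T, seed = 19, geom = geom)
  seedm <- box_mask(geom, c(-1, 1), c(-2.5, 0.5), c(-1, 1), "seed")
  cortex <- roi_mask(!seedm$voxels, geom, "ctx")
  lab <- slice_mask(seedm, "AP", 2)
  mot <- random_motion(T, seed = 10)
  pre <- function(im) clean_run(run_data(smooth_gaussian(im, 2), mot))
  go <- function(scale) {
    subject_stat_stack(
      list(pre(image4d(img_a$data * scale, geom, 2)),
           pre(image4d(img_b$data * scale, geom, 2))),
      lab, cortex, alpha = 0.05)
  }
  s1 <- go(1)
  s2 <- go(13.7)
  expect_equal(s1$t, s2$t, tolerance = 1e-8)
  expect_equal(s1$mean_z, s2$mean_z, tolerance = 1e-8)
  expect_equal(s1$p, s2$p, tolerance = 1e-8)
})
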