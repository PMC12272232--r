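test_that("sulcus parameterization maps world coordinates linearly to [0, 1]", {
  geom <- make_geom(c(4, 16, 4))
  # two voxels 10 mm apart -> positions 0 and 1
  v <- array(FALSE, c(4, 16, 4)); v[2, 3, 2] <- v[2, 13, 2] <- TRUE
  p2 <- parameterize_sulcus(roi_mask(v, geom, "pair"), "AP")
  expect_setequal(p2$position, c(0, 1))
  # 11 collinear voxels at 1 mm spacing -> positions k/10
  v <- array(FALSE, c(4, 16, 4)); v[2, 3:13, 2] <- TRUE
  p11 <- parameterize_sulcus(roi_mask(v, geom, "line"), "AP")
  expect_equal(sort(p11$position), (0:10) / 10)
  # monotone in the world coordinate
  y <- voxel_world_coords(geom, arrayInd(p11$voxel_idx, geom$dims))[, 2]
  expect_equal(order(p11$position), order(y))
  # zero extent along the axis is an error
  v <- array(FALSE, c(4, 16, 4)); v[2, 5, 2] <- v[3, 5, 2] <- TRUE
  expect_error(parameterize_sulcus(roi_mask(v, geom, "flat"), "AP"),
               "zero extent")
})

test_that("mirrored masks keep their positions under hemisphere-aware LM", {
  geom <- make_geom(c(16, 4, 4))
  left <- box_mask(geom, c(-7.5, -2.5), c(-1, 1), c(-1, 1), "L")
  right <- box_mask(geom, c(2.5, 7.5), c(-1, 1), c(-1, 1), "R")
  pl <- parameterize_sulcus(left, "LM", hemisphere = "L")
  pr <- parameterize_sulcus(right, "LM", hemisphere = "R")
  xl <- voxel_world_coords(geom, arrayInd(pl$voxel_idx, geom$dims))[, 1]
  xr <- voxel_world_coords(geom, arrayInd(pr$voxel_idx, geom$dims))[, 1]
  m <- match(round(-xl, 6), round(xr, 6))
  expect_equal(pr$position[m], pl$position)
})

make_gradient_maps <- function(x, y_fun, n_slabs = 11,
                               geom = make_geom(c(4, 30, 4))) {
  # one subject whose winners realize winner-position = y_fun(x)
  nv <- length(x)
  sul <- array(FALSE, geom$dims)
  sul[2, seq_len(nv), 2] <- TRUE
  mask <- roi_mask(sul, geom, "sulcus")
  idx <- which(sul)
  y <- y_fun(x)
  winners <- as.integer(round(y * (n_slabs - 1)))
  stat <- matrix(0, n_slabs, nv)
  p <- matrix(1, n_slabs, nv)
  for (v in seq_len(nv)) {
    stat[winners[v] + 1L, v] <- 10
    p[winners[v] + 1L, v] <- 1e-9
  }
  st <- fake_stack(stat, p, alpha = 0.001, geom = geom)
  st$voxel_idx <- idx
  map <- winner_take_all(st)
  path <- structure(list(name = "sulcus", hemisphere = "L",
                         position_axis = "AP", voxel_idx = idx,
                         position = x, geometry = geom),
                    class = "sulcus_path")
  list(map = map, path = path)
}

test_that("planted exact lines give |r| = 1 with the right polarity", {
  x <- (0:20) / 20
  d <- make_gradient_maps(x, function(x) x, n_slabs = 21)
  fit <- fit_gradient(list(d$map), d$path)
  expect_equal(fit$r, 1)
  expect_gt(fit$slope, 0)
  expect_equal(fit$polarity, "direct")
  rev <- make_gradient_maps(x, function(x) 1 - x, n_slabs = 21)
  fitr <- fit_gradient(list(rev$map), rev$path)
  expect_equal(fitr$r, -1)
  expect_equal(fitr$polarity, "reversed")
  # slope magnitudes match, signs flip
  expect_equal(fit$slope, -fitr$slope, tolerance = 1e-10)
})

test_that("noisy gradients match the independent normal-equations oracle", {
  set.seed(99)
  n <- 500
  x <- runif(n)
  y_clean <- 0.2 + 0.5 * x
  noise <- rnorm(n, sd = 0.1)
  # realize y on the 101-point winner grid the maps can represent
  y_grid <- pmin(pmax(y_clean + noise, 0), 1)
  d <- make_gradient_maps(x, function(...) y_grid, n_slabs = 101,
                          geom = make_geom(c(4, 501, 4)))
  fit <- fit_gradient(list(d$map), d$path)
  y_real <- wta_positions(d$map)
  oracle <- ols_fit_oracle(x, y_real)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-8)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-8)
  expect_equal(fit$p, oracle$p, tolerance = 1e-8)
  expect_equal(fit$r, cor(x, y_real), tolerance = 1e-10)
  expect_equal(fit$n_points, n)
})

test_that("dual gradients are flagged by the piecewise-BIC check", {
  x <- (0:40) / 40
  # V-shaped profile: a line explains nothing, two segments explain all
  v <- make_gradient_maps(x, function(x) abs(x - 0.5) * 2, n_slabs = 41,
                          geom = make_geom(c(4, 50, 4)))
  fit_v <- fit_gradient(list(v$map), v$path)
  expect_true(fit_v$nonmonotone)
  expect_equal(fit_v$polarity, "none")
  # a clean monotone line is not flagged
  d <- make_gradient_maps(x, function(x) x, n_slabs = 41,
                          geom = make_geom(c(4, 50, 4)))
  expect_false(fit_gradient(list(d$map), d$path)$nonmonotone)
})

test_that("too few points or flat positions raise errors", {
  x <- (0:20) / 20
  d <- make_gradient_maps(x, function(x) x, n_slabs = 21)
  short <- d$path
  short$voxel_idx <- short$voxel_idx[1:5]
  short$position <- short$position[1:5]
  expect_error(fit_gradient(list(d$map), short), ">= 10")
})

test_that("axis selection applies the two-hemisphere significance rule", {
  mk_fit <- function(ax, h, slope, r, p)
    data.frame(sulcus = "S", hemisphere = h, pulvinar_axis = ax,
               slope = slope, intercept = 0, r = r, p = p,
               n_points = 50L, polarity = "none",
               stringsAsFactors = FALSE)
  # AP significant in both hemispheres with agreeing sign -> AP
  fits <- rbind(mk_fit("AP", "L", 0.8, 0.7, 1e-6),
                mk_fit("AP", "R", 0.6, 0.6, 1e-4),
                mk_fit("VD", "L", 0.5, 0.4, 0.03),
                mk_fit("VD", "R", 0.2, 0.1, 0.4),   # right not significant
                mk_fit("LM", "L", -0.3, -0.2, 0.2),
                mk_fit("LM", "R", 0.3, 0.2, 0.2))
  sel <- select_axis(fits)
  expect_equal(sel$selected, "AP")
  expect_equal(sel$polarity, "direct")
  # VD significant in the left only -> none qualifies
  fits2 <- fits
  fits2$p[fits2$pulvinar_axis == "AP"] <- 0.5
  expect_equal(select_axis(fits2)$selected, "none")
  # both AP and VD qualify: the larger min |r| wins
  fits3 <- rbind(mk_fit("AP", "L", 0.8, 0.4, 1e-6),
                 mk_fit("AP", "R", 0.6, 0.5, 1e-4),
                 mk_fit("VD", "L", 0.5, 0.2, 0.01),
                 mk_fit("VD", "R", 0.4, 0.3, 0.01),
                 mk_fit("LM", "L", -0.3, -0.2, 0.2),
                 mk_fit("LM", "R", 0.3, 0.2, 0.2))
  expect_equal(select_axis(fits3)$selected, "AP")
  # disagreeing slope signs disqualify even when both are significant
  fits4 <- fits
  fits4$slope[fits4$pulvinar_axis == "AP" & fits4$hemisphere == "R"] <- -0.6
  expect_equal(select_axis(fits4)$selected, "none")
  # reversed polarity is reported from the common slope sign
  fits5 <- fits
  fits5$slope[fits5$pulvinar_axis == "AP"] <- c(-0.8, -0.6)
  expect_equal(select_axis(fits5)$polarity, "reversed")
  # failed fits (NA p) disqualify the axis
  fits6 <- fits
  fits6$p[1] <- NA
  expect_equal(select_axis(fits6)$selected, "none")
  expect_error(select_axis(fits[1:5, ]), "3 axes")
})
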