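# Shared fixtures: tiny grids, images and cohort configurations built in
# code at test time.

make_geom <- function(dims = c(4, 4, 4), voxel = c(1, 1, 1)) {
  volume_geometry(dims, voxel)
}

make_image <- function(dims = c(4, 4, 4), T = 10, tr = 2, seed = 1,
                       geom = make_geom(dims)) {
  set.seed(seed)
  image4d(array(rnorm(prod(dims) * T), c(dims, T)), geom, tr)
}

zero_motion <- function(T) matrix(0, T, 6)

random_motion <- function(T, seed = 1) {
  set.seed(seed)
  matrix(rnorm(T * 6, sd = 0.05), T, 6)
}

box_mask <- function(geom, xr, yr, zr, name = "box") {
  n <- prod(geom$dims)
  ijk <- arrayInd(seq_len(n), geom$dims)
  xyz <- voxel_world_coords(geom, ijk)
  inside <- xyz[, 1] >= xr[1] & xyz[, 1] <= xr[2] &
    xyz[, 2] >= yr[1] & xyz[, 2] <= yr[2] &
    xyz[, 3] >= zr[1] & xyz[, 3] <= zr[2]
  roi_mask(array(inside, geom$dims), geom, name)
}

# independent OLS oracle: residuals via explicit normal equations
ols_resid_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

ols_fit_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  tval <- beta[2] / se
  list(slope = beta[2], intercept = beta[1],
       p = 2 * pt(-abs(tval), n - 2))
}

# small default-conditions config with a controllable seed
tiny_config <- function(seed = 1, ...) {
  cohort_config(rng_seed = seed, ...)
}

# brute-force per-voxel winner-take-all oracle for both gate semantics
wta_oracle <- function(stat, sig, gate) {
  winner <- rep(NA_integer_, ncol(stat))
  for (v in seq_len(ncol(stat))) {
    if (gate == "candidates") {
      cand <- which(sig[, v])
      if (length(cand) == 0) next
      best <- cand[which.max(stat[cand, v])]
      best <- min(cand[stat[cand, v] == stat[best, v]])  # tie: smaller label
      winner[v] <- best - 1L
    } else {
      best <- min(which(stat[, v] == max(stat[, v])))
      if (sig[best, v]) winner[v] <- best - 1L
    }
  }
  winner
}

# WTA map with prescribed winners (NA = unassigned) on a shared fake grid
make_wta <- function(winners, n_slabs = 5, geom = make_geom(c(15, 15, 2))) {
  nv <- length(winners)
  stat <- matrix(0, n_slabs, nv)
  p <- matrix(1, n_slabs, nv)
  for (v in seq_len(nv)) if (!is.na(winners[v])) {
    stat[winners[v] + 1L, v] <- 10
    p[winners[v] + 1L, v] <- 1e-9
  }
  winner_take_all(fake_stack(stat, p, alpha = 0.001, geom = geom))
}

# a minimal stat_map_stack built directly from matrices (for WTA tests)
fake_stack <- function(t, p = NULL, mean_z = NULL, alpha = 0.05,
                       geom = make_geom(c(10, 10, 2))) {
  n_slabs <- nrow(t)
  nv <- ncol(t)
  if (is.null(p)) p <- matrix(1, n_slabs, nv)
  if (is.null(mean_z)) mean_z <- t
  seedbox <- roi_mask(array(c(rep(TRUE, n_slabs), rep(FALSE,
                                                      prod(geom$dims) - n_slabs)),
                            geom$dims), geom, "seed")
  lab <- slice_mask(seedbox, "AP", 2)
  lab$n_slabs <- n_slabs
  lab$slab_center_mm <- seq_len(n_slabs) * 2
  structure(list(subject_id = "fake", axis = "AP", hemisphere = "L",
                 t = t, p = p, mean_z = mean_z,
                 significant = p < alpha,
                 voxel_idx = seq_len(nv) + n_slabs,
                 labeling = lab, df = 2L, alpha = alpha,
                 geometry = geom),
            class = "stat_map_stack")
}
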