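#' Remove linear trend and motion nuisance from a run
#'
#' Every voxel's time series is replaced by the residual of an ordinary
#' least-squares regression on an intercept, a linear trend, and the six
#' motion regressors. Rank-deficient designs (e.g. a motionless run with
#' constant columns) drop the offending columns with a warning. Residuals
#' are mean-zero by construction.
#'
#' @param run a \code{run_data}.
#' @return An \code{image4d} of residual time series.
#' @export
clean_run <- function(run) {
  stopifnot(inherits(run, "run_data"))
  img <- run$image
  T <- img$n_volumes
  if (T <= 8L) stop("need more than 8 volumes to fit the nuisance design")
  trend <- seq_len(T) - (T + 1) / 2
  X <- cbind(intercept = 1, trend = trend / max(abs(trend)), run$motion)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping rank-deficient nuisance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
  }
  Y <- matrix(aperm(img$data, c(4, 1, 2, 3)), nrow = T)  # T x voxels
  res <- qr.resid(qrX, Y)
  out <- aperm(array(res, c(T, img$geometry$dims)), c(2, 3, 4, 1))
  new_image4d(out, img$geometry, img$tr_s)
}

gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- min(n - 1L, as.integer(ceiling(4 * sigma_vox)))
  w <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- w[ok]
  }
  K / rowSums(K)  # renormalized truncation at the volume edges
}

#' Spatial Gaussian smoothing of a 4D image
#'
#' Separable 3D Gaussian applied to each volume, with the kernel width given
#' as full width at half maximum in mm (\code{sd = fwhm / (2 sqrt(2 ln 2))}).
#' \code{fwhm_mm = 0} is the identity. Edges use renormalized truncation, so
#' constant images are exactly preserved.
#'
#' @param img an \code{image4d} (or 3D array wrapped in one volume).
#' @param fwhm_mm kernel FWHM in mm (>= 0).
#' @return A smoothed \code{image4d}.
#' @export
smooth_gaussian <- function(img, fwhm_mm) {
  stopifnot(inherits(img, "image4d"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("fwhm_mm must be a single number >= 0")
  if (fwhm_mm == 0) return(img)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(img$data)
  sig_vox <- sigma_mm / img$geometry$voxel_size_mm
  a <- img$data
  # dim 1
  K <- gaussian_kernel_matrix(d[1], sig_vox[1])
  a <- array(K %*% matrix(a, d[1]), d)
  # dim 2
  K <- gaussian_kernel_matrix(d[2], sig_vox[2])
  a <- aperm(a, c(2, 1, 3, 4))
  a <- aperm(array(K %*% matrix(a, d[2]), d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # dim 3
  K <- gaussian_kernel_matrix(d[3], sig_vox[3])
  a <- aperm(a, c(3, 1, 2, 4))
  a <- aperm(array(K %*% matrix(a, d[3]), d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  new_image4d(a, img$geometry, img$tr_s)
}

#' Mean time series over one seed slab
#'
#' @param img an \code{image4d} (typically cleaned and smoothed).
#' @param labeling a \code{slab_labeling} on the same grid.
#' @param label slab index (0-based).
#' @return Numeric vector of length T: the unweighted mean over slab voxels
#'   at each time point.
#' @export
slab_seed_series <- function(img, labeling, label) {
  stopifnot(inherits(img, "image4d"))
  stop_if_grid_mismatch(img$geometry, labeling$geometry,
                        "image and slab labeling")
  vox <- slab_voxels(labeling, label)
  if (length(vox) == 0L) stop("slab ", label, " is empty")
  nvox <- prod(img$geometry$dims)
  m <- matrix(img$data, nrow = nvox)  # voxels x T
  colMeans(m[vox, , drop = FALSE])
}

#' Seed-to-cortex Pearson correlation map
#'
#' @param img_clean cleaned \code{image4d} (same preprocessing as the seed).
#' @param seed_series numeric vector of length T.
#' @param cortex an \code{roi_mask} of target voxels on the same grid.
#' @return Numeric vector of correlations, one per cortex voxel (in the
#'   order of \code{which(cortex$voxels)}); voxels with zero temporal
#'   variance are \code{NA} and are excluded downstream.
#' @export
run_correlation_map <- function(img_clean, seed_series, cortex) {
  stopifnot(inherits(img_clean, "image4d"), inherits(cortex, "roi_mask"))
  stop_if_grid_mismatch(img_clean$geometry, cortex$geometry,
                        "image and cortex mask")
  T <- img_clean$n_volumes
  if (length(seed_series) != T)
    stop("seed series length != number of volumes")
  vox <- which(cortex$voxels)
  Y <- matrix(img_clean$data, nrow = prod(img_clean$geometry$dims))[vox, ,
                                                                    drop = FALSE]
  s <- seed_series - mean(seed_series)
  ss <- sum(s^2)
  if (ss == 0) stop("seed series has zero variance")
  Yc <- Y - rowMeans(Y)
  num <- as.numeric(Yc %*% s)
  den2 <- rowSums(Yc^2) * ss
  r <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
  r
}

#' Fisher r-to-z transform
#'
#' \code{z = atanh(r) = 0.5 * log((1 + r) / (1 - r))}; odd and strictly
#' increasing on (-1, 1).
#'
#' @param r correlation(s) with \code{|r| < 1}.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stop("fisher_z requires |r| < 1")
  atanh(r)
}

#' Inverse Fisher transform
#' @param z Fisher z value(s).
#' @return Correlation(s) in (-1, 1).
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Across-run one-sample t-test on Fisher-z maps
#'
#' For each voxel, the per-run z values are tested against zero
#' (\code{t = mean(z) / (sd(z) / sqrt(n))}, two-sided p from Student's t
#' with \code{n - 1} df). A voxel whose z values are identical across runs
#' with nonzero mean is, by convention, significant with p recorded as 0;
#' identical zeros give t = 0, p = 1. Voxels with any missing z (e.g.
#' zero-variance in some run) are NA throughout and never significant.
#'
#' @param z_mat n_runs x n_voxels matrix of Fisher-z values.
#' @param alpha significance level (default 0.001, uncorrected).
#' @return List with \code{t}, \code{p}, \code{mean_z}, \code{significant}
#'   (logical), \code{df}, \code{alpha}.
#' @export
across_run_tmap <- function(z_mat, alpha = 0.001) {
  z_mat <- as.matrix(z_mat)
  n <- nrow(z_mat)
  if (n < 2L) stop("need at least 2 runs for the across-run t-test")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  m <- colMeans(z_mat)
  v <- (colSums(z_mat^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # float guard
  s <- sqrt(v)
  t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, Inf * sign(m)))
  df <- n - 1L
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df),
              0)  # degenerate zero-variance, nonzero mean
  p[!is.finite(m)] <- NA_real_
  t[!is.finite(m)] <- NA_real_
  sig <- !is.na(p) & p < alpha
  list(t = t, p = p, mean_z = m, significant = sig, df = df, alpha = alpha)
}

#' Per-subject, per-slab connectivity statistics
#'
#' Runs the slab-seeded connectivity analysis for every slab of one
#' labeling: per run, the slab's mean seed series is correlated with every
#' cortex voxel, correlations are Fisher-z transformed, and the per-run z
#' maps enter an across-run one-sample t-test thresholded at
#' \code{p < alpha} (uncorrected). Seed-mask voxels are removed from the
#' target set to avoid self-correlation.
#'
#' @param images_clean list of cleaned (and smoothed) \code{image4d}, one
#'   per run.
#' @param labeling a \code{slab_labeling} of the seed nucleus.
#' @param cortex an \code{roi_mask} of cortical target voxels.
#' @param alpha voxelwise significance level (default 0.001).
#' @param subject_id identifier carried into downstream tables.
#' @return An object of class \code{stat_map_stack}: matrices
#'   \code{t}, \code{p}, \code{mean_z}, \code{significant} of size
#'   n_slabs x n_voxels, plus \code{voxel_idx} (linear indices of the
#'   target voxels), \code{labeling}, \code{df}, \code{alpha},
#'   \code{axis}, \code{subject_id}.
#' @export
subject_stat_stack <- function(images_clean, labeling, cortex,
                               alpha = 0.001, subject_id = "subject",
                               run_matrices = NULL) {
  stopifnot(length(images_clean) >= 2L)
  for (im in images_clean)
    stop_if_grid_mismatch(im$geometry, labeling$geometry, "run and labeling")
  stop_if_grid_mismatch(cortex$geometry, labeling$geometry,
                        "cortex and labeling")
  target <- cortex$voxels & is.na(labeling$labels)
  vox <- which(target)
  if (length(vox) == 0L) stop("no cortex voxels outside the seed mask")
  n_slabs <- labeling$n_slabs
  n_runs <- length(images_clean)
  df <- n_runs - 1L
  slab_idx <- lapply(seq_len(n_slabs) - 1L,
                     function(k) slab_voxels(labeling, k))
  nvox_total <- prod(labeling$geometry$dims)
  # per run: one (voxels x T) matrix view of the data, shared by all slabs;
  # callers analysing several labelings can pass the views in once
  z_by_slab <- lapply(seq_len(n_slabs), function(k)
    matrix(NA_real_, n_runs, length(vox)))
  for (j in seq_len(n_runs)) {
    m <- if (is.null(run_matrices))
      matrix(images_clean[[j]]$data, nrow = nvox_total)
    else run_matrices[[j]]
    Y <- m[vox, , drop = FALSE]
    Yc <- Y - rowMeans(Y)
    yss <- rowSums(Yc^2)
    for (k in seq_len(n_slabs)) {
      s <- colMeans(m[slab_idx[[k]], , drop = FALSE])
      sc <- s - mean(s)
      sss <- sum(sc^2)
      if (sss == 0) stop("seed series of slab ", k - 1L,
                         " has zero variance")
      den2 <- yss * sss
      r <- ifelse(den2 > 0, as.numeric(Yc %*% sc) / sqrt(den2), NA_real_)
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      z_by_slab[[k]][j, ] <- fisher_z(r)
    }
  }
  tmat <- pmat <- zmat <- matrix(NA_real_, n_slabs, length(vox))
  sigmat <- matrix(FALSE, n_slabs, length(vox))
  for (k in seq_len(n_slabs)) {
    tt <- across_run_tmap(z_by_slab[[k]], alpha)
    tmat[k, ] <- tt$t
    pmat[k, ] <- tt$p
    zmat[k, ] <- tt$mean_z
    sigmat[k, ] <- tt$significant
  }
  structure(list(subject_id = subject_id, axis = labeling$axis,
                 hemisphere = labeling$hemisphere,
                 t = tmat, p = pmat, mean_z = zmat, significant = sigmat,
                 voxel_idx = vox, labeling = labeling, df = df,
                 alpha = alpha, geometry = cortex$geometry),
            class = "stat_map_stack")
}

#' Write a stat-map stack as per-slab NIfTI volumes
#'
#' For each slab, writes the across-run t map, the p map and the mean
#' Fisher-z map over the target voxels (0 elsewhere), named
#' \code{<prefix>_slab<k>_<t|p|meanz>.nii.gz}.
#'
#' @param stack a \code{stat_map_stack}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default combines subject and axis).
#' @return The written file paths, invisibly.
#' @export
write_stat_map_stack <- function(stack, dir,
                                 prefix = paste(stack$subject_id,
                                                stack$axis,
                                                stack$hemisphere,
                                                sep = "_")) {
  stopifnot(inherits(stack, "stat_map_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- stack$geometry$dims
  paths <- character(0)
  layers <- list(t = stack$t, p = stack$p, meanz = stack$mean_z)
  for (k in seq_len(nrow(stack$t))) {
    for (nm in names(layers)) {
      vol <- array(0, d)
      val <- layers[[nm]][k, ]
      vol[stack$voxel_idx] <- ifelse(is.na(val), 0, val)
      f <- file.path(dir, sprintf("%s_slab%d_%s.nii.gz",
                                  prefix, k - 1L, nm))
      RNifti::writeNifti(as_nifti_with_geometry(vol, stack$geometry), f)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}

#' @export
print.stat_map_stack <- function(x, ...) {
  cat("stat_map_stack:", x$subject_id, "axis", x$axis, "-",
      nrow(x$t), "slabs x", ncol(x$t), "voxels, df", x$df, "\n")
  invisible(x)
}
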