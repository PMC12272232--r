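#' Configuration for a synthetic resting-state cohort
#'
#' Describes a multi-subject, multi-run 4D BOLD cohort with planted
#' pulvino-cortical topography: an ellipsoidal seed nucleus per hemisphere
#' whose fixed-thickness slabs each share a latent AR(1) signal with one
#' segment of a cortical band, so that every downstream stage (slab
#' connectivity, winner-take-all assignment, consensus, gradient
#' regression) has a known ground truth. Defaults emulate an awake
#' resting-state acquisition at desk scale: iron-oxide-contrast-like runs
#' of a few hundred volumes at TR 2 s on a 1-mm grid, temporally
#' autocorrelated noise, and a motion-coupled global nuisance.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param runs_per_subject runs per subject (>= 2 for the across-run test).
#' @param volumes_per_run volumes per run (>= 50).
#' @param tr_s repetition time in seconds.
#' @param grid_dims,voxel_size_mm grid (default 24^3 at 1 mm, centred on
#'   the origin).
#' @param nucleus_center_mm centre of the right-hemisphere nucleus in mm
#'   (the left one is its mirror image across x = 0).
#' @param nucleus_radii_mm ellipsoid radii in mm.
#' @param slab_axis axis along which the nucleus is sliced and cortical
#'   band segments are planted (\code{"LM"}, \code{"AP"}, \code{"VD"}).
#' @param slab_thickness_mm slab thickness (default 2 mm).
#' @param bands data frame with columns \code{sulcus}, \code{position_axis}
#'   (\code{"AP"} or \code{"VD"}), \code{polarity} (\code{"direct"} or
#'   \code{"reversed"}); at most two bands (one dorsal, one ventral strip).
#' @param signal_sd latent signal scale (shared within a slab/band pair).
#' @param noise_sd marginal sd of the independent voxel noise (> 0).
#' @param ar1_phi lag-1 autocorrelation of latents and noise, in [0, 1).
#' @param motion_leak coefficient coupling the first motion regressor into
#'   every voxel (>= 0).
#' @param subject_jitter_sd per-subject jitter (mm) of band-segment
#'   boundaries along the band's position axis.
#' @param shared_topography when \code{FALSE}, each subject's band-to-slab
#'   assignment is independently permuted, destroying the common
#'   topography while keeping within-subject structure (the null used for
#'   consistency comparisons).
#' @param rng_seed base seed; together with the subject index it fully
#'   determines every subject's data.
#' @return A list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_subjects = 4L,
                          runs_per_subject = 2L,
                          volumes_per_run = 200L,
                          tr_s = 2,
                          grid_dims = c(24L, 24L, 24L),
                          voxel_size_mm = c(1, 1, 1),
                          nucleus_center_mm = c(6, -2, 0),
                          nucleus_radii_mm = c(2.5, 5, 5),
                          slab_axis = "AP",
                          slab_thickness_mm = 2,
                          bands = data.frame(
                            sulcus = c("IPS", "ACC"),
                            position_axis = c("AP", "AP"),
                            polarity = c("direct", "reversed"),
                            stringsAsFactors = FALSE),
                          signal_sd = 1,
                          noise_sd = 1,
                          ar1_phi = 0.3,
                          motion_leak = 0.1,
                          subject_jitter_sd = 0.5,
                          shared_topography = TRUE,
                          rng_seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              runs_per_subject = as.integer(runs_per_subject),
              volumes_per_run = as.integer(volumes_per_run),
              tr_s = tr_s, grid_dims = as.integer(grid_dims),
              voxel_size_mm = voxel_size_mm,
              nucleus_center_mm = nucleus_center_mm,
              nucleus_radii_mm = nucleus_radii_mm,
              slab_axis = match.arg(slab_axis, c("LM", "AP", "VD")),
              slab_thickness_mm = slab_thickness_mm,
              bands = bands, signal_sd = signal_sd, noise_sd = noise_sd,
              ar1_phi = ar1_phi, motion_leak = motion_leak,
              subject_jitter_sd = subject_jitter_sd,
              shared_topography = isTRUE(shared_topography),
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$n_subjects >= 1L, cfg$runs_per_subject >= 2L,
            cfg$volumes_per_run >= 50L, cfg$tr_s > 0,
            cfg$noise_sd > 0, cfg$signal_sd >= 0,
            cfg$ar1_phi >= 0, cfg$ar1_phi < 1, cfg$motion_leak >= 0,
            cfg$subject_jitter_sd >= 0, cfg$slab_thickness_mm > 0)
  if (nrow(cfg$bands) > 2L)
    stop("at most two cortical bands are supported (dorsal + ventral strip)")
  if (!all(cfg$bands$position_axis %in% c("AP", "VD")))
    stop("band position_axis must be AP or VD")
  if (!all(cfg$bands$polarity %in% c("direct", "reversed")))
    stop("band polarity must be 'direct' or 'reversed'")
  class(cfg) <- "cohort_config"
  cfg
}

# deterministic per-subject seed below 2^31
derive_seed <- function(rng_seed, subject_index, salt = 0L) {
  as.integer((abs(rng_seed) * 2654435.0 + subject_index * 97003.0 +
                salt * 131.0) %% 2147483629)
}

cohort_geometry <- function(config) {
  volume_geometry(config$grid_dims, config$voxel_size_mm)
}

# logical array from a predicate on world coordinates (n x 3 matrix -> logical)
mask_from_world <- function(geometry, predicate, name, allow_empty = FALSE) {
  n <- prod(geometry$dims)
  ijk <- arrayInd(seq_len(n), geometry$dims)
  xyz <- voxel_world_coords(geometry, ijk)
  roi_mask(array(predicate(xyz), geometry$dims), geometry, name,
           allow_empty = allow_empty)
}

nucleus_mask <- function(config, hemisphere) {
  ctr <- config$nucleus_center_mm
  if (hemisphere == "L") ctr[1] <- -ctr[1]
  rad <- config$nucleus_radii_mm
  mask_from_world(cohort_geometry(config), function(xyz) {
    rowSums(sweep(sweep(xyz, 2, ctr), 2, rad, "/")^2) <= 1
  }, paste0("pulvinar_", hemisphere))
}

# cortical band strips: lateral shell 4-8 mm from the midline, long axis
# along the band's position axis, confined to a dorsal (slot 1) or ventral
# (slot 2) slot so bands never touch the nucleus
band_mask <- function(config, band_row, slot, hemisphere) {
  zr <- if (slot == 1L) c(6, 10) else c(-10, -6)
  sgn <- if (hemisphere == "L") -1 else 1
  mask_from_world(cohort_geometry(config), function(xyz) {
    x <- sgn * xyz[, 1]
    long <- if (band_row$position_axis == "AP") xyz[, 2] else xyz[, 3]
    slotc <- if (band_row$position_axis == "AP") xyz[, 3] else xyz[, 2]
    x >= 4 & x <= 8 & long >= -9 & long <= 9 & slotc >= zr[1] & slotc <= zr[2]
  }, paste0(band_row$sulcus, "_", hemisphere))
}

neutral_mask <- function(config, hemisphere) {
  sgn <- if (hemisphere == "L") -1 else 1
  mask_from_world(cohort_geometry(config), function(xyz) {
    x <- sgn * xyz[, 1]
    x >= 9 & x <= 11 & abs(xyz[, 2]) <= 9 & abs(xyz[, 3]) <= 2
  }, paste0("neutral_", hemisphere))
}

# unit-variance AR(1) series
ar1_series <- function(T, phi, n = 1L) {
  innov_sd <- sqrt(1 - phi^2)
  e <- matrix(stats::rnorm(T * n), T, n)
  x <- e
  if (phi > 0) for (t in 2:T) x[t, ] <- phi * x[t - 1L, ] + innov_sd * e[t, ]
  x
}

#' Generate one synthetic subject
#'
#' Nucleus voxels in slab \code{k} and the cortical band voxels assigned
#' to slab \code{k} share a latent unit-variance AR(1) series scaled by
#' \code{signal_sd}; every voxel additionally carries independent AR(1)
#' noise of marginal sd \code{noise_sd}, and \code{motion_leak} times the
#' first motion regressor is added globally. Band-segment boundaries are
#' jittered per subject. Fully deterministic given
#' \code{(rng_seed, subject_index)}.
#'
#' @param config a \code{cohort_config}.
#' @param subject_index 1-based subject number.
#' @return A list: \code{subject_id}; \code{runs} (list of
#'   \code{run_data}); \code{seed}, \code{cortex} (lists with \code{L} and
#'   \code{R} \code{roi_mask}s, cortex = bands + a neutral strip);
#'   \code{sulci} (per band x hemisphere: name, hemisphere, mask,
#'   position_axis, polarity); \code{labeling} (per-hemisphere
#'   \code{slab_labeling} along the planted axis); \code{ground_truth}
#'   (data frame: voxel index, hemisphere, sulcus, planted slab,
#'   position) plus \code{latents} per run.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"),
            subject_index >= 1, subject_index <= config$n_subjects)
  geom <- cohort_geometry(config)
  T <- config$volumes_per_run
  nvox <- prod(geom$dims)

  seed_m <- list(L = nucleus_mask(config, "L"), R = nucleus_mask(config, "R"))
  labeling <- lapply(c(L = "L", R = "R"), function(h)
    slice_mask(seed_m[[h]], config$slab_axis, config$slab_thickness_mm, h))
  ext <- vapply(c(L = "L", R = "R"), function(h) {
    idx <- which(seed_m[[h]]$voxels)
    diff(range(axis_coordinate(geom, arrayInd(idx, geom$dims),
                               config$slab_axis, h)))
  }, 0)
  if (min(ext) < config$slab_thickness_mm)
    stop("nucleus extent along ", config$slab_axis, " (", min(ext),
         " mm) is smaller than one slab thickness")
  n_lat <- max(vapply(labeling, function(l) l$n_slabs, 0L))

  bands <- config$bands
  sulci <- list()
  for (b in seq_len(nrow(bands))) for (h in c("L", "R")) {
    m <- band_mask(config, bands[b, ], b, h)
    if (any(m$voxels & seed_m[[h]]$voxels))
      stop("band ", bands$sulcus[b], " overlaps the nucleus")
    sulci[[paste0(bands$sulcus[b], "_", h)]] <-
      list(name = bands$sulcus[b], hemisphere = h, mask = m,
           position_axis = bands$position_axis[b],
           polarity = bands$polarity[b])
  }
  cortex <- lapply(c(L = "L", R = "R"), function(h) {
    v <- neutral_mask(config, h)$voxels
    for (s in sulci) if (s$hemisphere == h) v <- v | s$mask$voxels
    roi_mask(v, geom, paste0("cortex_", h))
  })

  set.seed(derive_seed(config$rng_seed, subject_index))

  # planted band-to-slab assignment (jittered per subject)
  perm <- if (config$shared_topography) seq_len(n_lat) else sample(n_lat)
  gt <- list()
  for (s in sulci) {
    nk <- labeling[[s$hemisphere]]$n_slabs
    idx <- which(s$mask$voxels)
    ijk <- arrayInd(idx, geom$dims)
    cc <- axis_coordinate(geom, ijk, s$position_axis, s$hemisphere)
    jit <- stats::rnorm(1, 0, config$subject_jitter_sd)
    p <- (cc + jit - min(cc)) / (max(cc) - min(cc))
    p <- pmin(pmax(p, 0), 1 - 1e-9)
    slab <- as.integer(floor(p * nk))
    if (s$polarity == "reversed") slab <- nk - 1L - slab
    slab <- perm[slab + 1L] - 1L
    slab <- pmin(slab, nk - 1L)  # permutation can exceed a smaller hemisphere
    gt[[paste0(s$name, "_", s$hemisphere)]] <-
      data.frame(voxel = idx, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                 hemisphere = s$hemisphere, sulcus = s$name,
                 slab = slab, position = (cc - min(cc)) / (max(cc) - min(cc)),
                 polarity = s$polarity, stringsAsFactors = FALSE)
  }
  ground_truth <- do.call(rbind, c(gt, list(make.row.names = FALSE)))

  runs <- vector("list", config$runs_per_subject)
  latents <- vector("list", config$runs_per_subject)
  for (rr in seq_len(config$runs_per_subject)) {
    motion <- vapply(c(0.02, 0.02, 0.02, 0.002, 0.002, 0.002),
                     function(sd) cumsum(stats::rnorm(T, 0, sd)),
                     numeric(T))
    L <- ar1_series(T, config$ar1_phi, n_lat)          # T x n_lat, unit var
    M <- matrix(stats::rnorm(nvox * T), nvox, T)        # innovations
    if (config$ar1_phi > 0) {
      isd <- sqrt(1 - config$ar1_phi^2)
      for (t in 2:T) M[, t] <- config$ar1_phi * M[, t - 1L] + isd * M[, t]
    }
    if (config$noise_sd != 1) M <- M * config$noise_sd
    add_latent <- function(vox, k) {
      # recycle L over rows: column t of M[vox, ] gets L[t, k]
      M[vox, ] <<- M[vox, ] +
        config$signal_sd * rep(L[, k + 1L], each = length(vox))
    }
    for (h in c("L", "R")) {
      lab <- labeling[[h]]
      for (k in seq_len(lab$n_slabs) - 1L)
        add_latent(slab_voxels(lab, k), k)
    }
    for (nm in names(gt)) {
      g <- gt[[nm]]
      for (k in unique(g$slab)) add_latent(g$voxel[g$slab == k], k)
    }
    if (config$motion_leak > 0)
      M <- M + config$motion_leak * rep(motion[, 1], each = nvox)
    img <- new_image4d(array(M, c(geom$dims, T)), geom, config$tr_s)
    run_id <- sprintf("sub-%02d_run-%02d", subject_index, rr)
    runs[[rr]] <- run_data(img, motion, run_id)
    latents[[rr]] <- L
  }

  list(subject_id = sprintf("sub-%02d", subject_index), runs = runs,
       seed = seed_m, cortex = cortex, sulci = sulci,
       labeling = labeling, ground_truth = ground_truth,
       latents = latents, planted_axis = config$slab_axis)
}

#' Generate an entire cohort and write it to disk
#'
#' Writes per-subject run volumes (NIfTI-1, gzipped), motion tables
#' (plain text, 6 columns), the shared masks, per-subject ground-truth
#' CSVs, and a YAML manifest tying everything together.
#'
#' @param config a \code{cohort_config}.
#' @param out_dir writable output directory (created if needed).
#' @return Path of the cohort manifest (\code{manifest.yaml}), invisibly;
#'   the manifest lists every written file relative to \code{out_dir}.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mask_dir <- file.path(out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)
  manifest <- list(n_subjects = config$n_subjects,
                   tr_s = config$tr_s,
                   slab_axis = config$slab_axis,
                   slab_thickness_mm = config$slab_thickness_mm,
                   rng_seed = config$rng_seed,
                   subjects = list(), masks = list(), sulci = list())
  subjects <- list()
  for (i in seq_len(config$n_subjects)) {
    sub <- generate_subject(config, i)
    sdir <- file.path(out_dir, sub$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    run_files <- motion_files <- character(0)
    for (rr in seq_along(sub$runs)) {
      rd <- sub$runs[[rr]]
      rf <- file.path(sub$subject_id, paste0(rd$run_id, "_bold.nii.gz"))
      mf <- file.path(sub$subject_id, paste0(rd$run_id, "_motion.txt"))
      write_image4d(rd$image, file.path(out_dir, rf))
      utils::write.table(format(rd$motion, digits = 10),
                         file.path(out_dir, mf),
                         row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
      run_files <- c(run_files, rf)
      motion_files <- c(motion_files, mf)
    }
    gt_file <- file.path(sub$subject_id, "ground_truth.csv")
    utils::write.csv(sub$ground_truth, file.path(out_dir, gt_file),
                     row.names = FALSE)
    manifest$subjects[[sub$subject_id]] <-
      list(runs = as.list(run_files), motion = as.list(motion_files),
           ground_truth = gt_file)
    if (i == 1L) {
      for (h in c("L", "R")) {
        sf <- file.path("masks", paste0("pulvinar_", h, ".nii.gz"))
        cf <- file.path("masks", paste0("cortex_", h, ".nii.gz"))
        write_mask(sub$seed[[h]], file.path(out_dir, sf))
        write_mask(sub$cortex[[h]], file.path(out_dir, cf))
        manifest$masks[[paste0("seed_", h)]] <- sf
        manifest$masks[[paste0("cortex_", h)]] <- cf
      }
      for (nm in names(sub$sulci)) {
        s <- sub$sulci[[nm]]
        f <- file.path("masks", paste0("sulcus_", nm, ".nii.gz"))
        write_mask(s$mask, file.path(out_dir, f))
        manifest$sulci[[nm]] <- list(file = f, name = s$name,
                                     hemisphere = s$hemisphere,
                                     position_axis = s$position_axis,
                                     polarity = s$polarity)
      }
    }
    subjects[[i]] <- sub$subject_id
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Load a cohort previously written by \code{generate_cohort}
#'
#' @param manifest_path path to \code{manifest.yaml}.
#' @return List with \code{config} fields from the manifest and
#'   \code{subjects}: per subject the runs (\code{run_data}), plus the
#'   shared \code{seed}/\code{cortex} masks, \code{sulci} descriptors,
#'   and ground-truth data frames.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- yaml::read_yaml(manifest_path)
  root <- dirname(manifest_path)
  seed <- list(L = load_mask(file.path(root, man$masks$seed_L), "pulvinar_L"),
               R = load_mask(file.path(root, man$masks$seed_R), "pulvinar_R"))
  cortex <- list(L = load_mask(file.path(root, man$masks$cortex_L), "cortex_L"),
                 R = load_mask(file.path(root, man$masks$cortex_R), "cortex_R"))
  sulci <- lapply(man$sulci, function(s) {
    list(name = s$name, hemisphere = s$hemisphere,
         mask = load_mask(file.path(root, s$file), s$name),
         position_axis = s$position_axis, polarity = s$polarity)
  })
  subjects <- lapply(names(man$subjects), function(id) {
    entry <- man$subjects[[id]]
    runs <- lapply(seq_along(entry$runs), function(rr) {
      img <- load_image4d(file.path(root, entry$runs[[rr]]))
      mot <- load_motion(file.path(root, entry$motion[[rr]]),
                         n_volumes = img$n_volumes)
      run_data(img, mot, sub("_bold\\.nii\\.gz$", "",
                             basename(entry$runs[[rr]])))
    })
    gt <- utils::read.csv(file.path(root, entry$ground_truth),
                          stringsAsFactors = FALSE)
    list(subject_id = id, runs = runs, seed = seed, cortex = cortex,
         sulci = sulci, ground_truth = gt)
  })
  list(manifest = man, subjects = subjects, seed = seed, cortex = cortex,
       sulci = sulci, slab_axis = man$slab_axis,
       slab_thickness_mm = man$slab_thickness_mm)
}
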