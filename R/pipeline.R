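#' Total scanning time of a session specification
#'
#' Sums \code{n_runs x run_length_pulses x tr_s / 60} over run groups, the
#' accounting used to report per-subject scan durations in minutes.
#'
#' @param n_runs integer vector of run counts, one per run group.
#' @param run_length_pulses run length in pulses (volumes) per group
#'   (recycled against \code{n_runs}).
#' @param tr_s repetition time in seconds.
#' @return Total minutes (numeric scalar).
#' @examples
#' session_minutes(13, 300, 2)          # 130
#' session_minutes(c(21, 9), 300, 2)    # 300
#' @export
session_minutes <- function(n_runs, run_length_pulses, tr_s) {
  if (length(n_runs) == 0L || any(n_runs <= 0))
    stop("n_runs must be positive")
  if (any(run_length_pulses <= 0)) stop("run_length_pulses must be positive")
  if (length(tr_s) != 1L || tr_s <= 0) stop("tr_s must be a positive scalar")
  sum(n_runs * run_length_pulses) * tr_s / 60
}

preprocess_runs <- function(runs, fwhm_mm) {
  lapply(runs, function(rd) {
    sm <- smooth_gaussian(rd$image, fwhm_mm)
    clean_run(run_data(sm, rd$motion, rd$run_id))
  })
}

#' Run the full topography analysis on an in-memory cohort
#'
#' Per subject and hemisphere: smooth, remove nuisance, slice the seed
#' nucleus along each requested axis, compute slab connectivity
#' statistics, and build winner-take-all maps. Then: group consensus maps,
#' inter-subject Spearman consistency with the Friedman axis comparison
#' (blocks = subject pair x hemisphere), and per-sulcus gradient
#' regressions with axis selection and polarity. When ground truth is
#' present, planted-slab recovery is evaluated on the planted axis.
#'
#' @param subjects list of subjects as returned by
#'   \code{\link{generate_subject}} (or \code{\link{load_cohort}}).
#' @param axes axes to analyze (default all three).
#' @param alpha voxelwise significance level for the across-run t-test
#'   (default 0.001, uncorrected).
#' @param fwhm_mm spatial smoothing kernel FWHM (default 2 mm).
#' @param slab_thickness_mm slab thickness (default 2 mm).
#' @param gradient_alpha significance level for gradient polarity and
#'   axis selection (default 0.05).
#' @param wta_stat,wta_gate comparison statistic and significance-gate
#'   mode for the winner-take-all step, passed to
#'   \code{\link{winner_take_all}}.
#' @param planted_axis axis carrying planted topography, for recovery
#'   scoring (default: taken from the first subject if present).
#' @return A list of class \code{cohort_analysis}: \code{wta} (nested
#'   [[axis]][[hemisphere]] lists of per-subject \code{wta_map}),
#'   \code{consensus}, \code{consistency} (tables + \code{comparison}),
#'   \code{gradients} (pooled fits data frame), \code{axis_selection}
#'   (per sulcus), \code{recovery} (per hemisphere planted-slab recovery),
#'   \code{params}.
#' @export
analyze_cohort <- function(subjects, axes = c("LM", "AP", "VD"),
                           alpha = 0.001, fwhm_mm = 2,
                           slab_thickness_mm = 2, gradient_alpha = 0.05,
                           wta_stat = c("mean_z", "t"),
                           wta_gate = c("winner", "candidates"),
                           planted_axis = NULL) {
  wta_stat <- match.arg(wta_stat)
  wta_gate <- match.arg(wta_gate)
  stopifnot(length(subjects) >= 1L)
  axes <- match.arg(axes, c("LM", "AP", "VD"), several.ok = TRUE)
  hemis <- c("L", "R")
  if (is.null(planted_axis)) planted_axis <- subjects[[1]]$planted_axis

  wta <- stats::setNames(vector("list", length(axes)), axes)
  for (ax in axes) wta[[ax]] <- list(L = list(), R = list())

  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    cleaned <- preprocess_runs(sub$runs, fwhm_mm)
    nvox <- prod(cleaned[[1]]$geometry$dims)
    mats <- lapply(cleaned, function(im) matrix(im$data, nrow = nvox))
    for (h in hemis) {
      for (ax in axes) {
        lab <- slice_mask(sub$seed[[h]], ax, slab_thickness_mm, h)
        stack <- subject_stat_stack(cleaned, lab, sub$cortex[[h]],
                                    alpha = alpha,
                                    subject_id = sub$subject_id,
                                    run_matrices = mats)
        wta[[ax]][[h]][[sub$subject_id]] <-
          winner_take_all(stack, stat = wta_stat, gate = wta_gate)
      }
    }
  }

  consensus <- lapply(wta, function(byh)
    lapply(byh, function(maps) if (length(maps) >= 1L)
      group_consensus(unname(maps)) else NULL))

  consistency <- NULL
  comparison <- NULL
  if (length(subjects) >= 2L) {
    consistency <- lapply(wta, function(byh) {
      tl <- consistency_table(unname(byh$L))
      tr <- consistency_table(unname(byh$R))
      out <- rbind(tl, tr)
      attr(out, "mean_rho") <- mean(out$rho, na.rm = TRUE)
      out
    })
    if (length(axes) == 3L && nrow(consistency[[1]]) >= 3L) {
      comparison <- tryCatch(compare_axes(consistency[axes]),
                             error = function(e) NULL)
    }
  }

  gradients <- list()
  axis_selection <- list()
  if (!is.null(subjects[[1]]$sulci)) {
    sulcus_names <- unique(vapply(subjects[[1]]$sulci,
                                  function(s) s$name, ""))
    for (sn in sulcus_names) {
      fits <- list()
      for (h in hemis) for (ax in axes) {
        sdef <- Find(function(s) s$name == sn && s$hemisphere == h,
                     subjects[[1]]$sulci)
        path <- parameterize_sulcus(sdef$mask, sdef$position_axis, h)
        path$name <- sn
        fit <- tryCatch(
          fit_gradient(unname(wta[[ax]][[h]]), path,
                       alpha = gradient_alpha),
          error = function(e)
            data.frame(sulcus = sn, hemisphere = h, pulvinar_axis = ax,
                       slope = NA_real_, intercept = NA_real_,
                       r = NA_real_, p = NA_real_, n_points = 0L,
                       polarity = "none", nonmonotone = NA,
                       stringsAsFactors = FALSE))
        fits[[paste(ax, h)]] <- fit
      }
      fdf <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
      gradients[[sn]] <- fdf
      axis_selection[[sn]] <- if (length(axes) == 3L)
        select_axis(fdf, alpha = gradient_alpha)
      else list(selected = NA_character_, polarity = NA_character_)
    }
  }

  recovery <- NULL
  if (!is.null(subjects[[1]]$ground_truth) && !is.null(planted_axis) &&
      planted_axis %in% axes) {
    rec <- lapply(hemis, function(h) {
      n_ok <- n_assigned <- 0L
      for (sub in subjects) {
        m <- wta[[planted_axis]][[h]][[sub$subject_id]]
        gt <- sub$ground_truth
        gt <- gt[gt$hemisphere == h, ]
        j <- match(gt$voxel, m$voxel_idx)
        w <- m$winner[j]
        ok <- !is.na(w)
        n_assigned <- n_assigned + sum(ok)
        n_ok <- n_ok + sum(w[ok] == gt$slab[ok])
      }
      c(assigned = n_assigned, correct = n_ok)
    })
    names(rec) <- hemis
    tot <- Reduce(`+`, rec)
    recovery <- list(per_hemisphere = rec,
                     assigned = unname(tot["assigned"]),
                     correct = unname(tot["correct"]),
                     rate = unname(tot["correct"] / max(tot["assigned"], 1)))
  }

  structure(list(wta = wta, consensus = consensus,
                 consistency = consistency, comparison = comparison,
                 gradients = gradients, axis_selection = axis_selection,
                 recovery = recovery,
                 params = list(axes = axes, alpha = alpha,
                               fwhm_mm = fwhm_mm,
                               slab_thickness_mm = slab_thickness_mm,
                               gradient_alpha = gradient_alpha,
                               planted_axis = planted_axis,
                               n_subjects = length(subjects))),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("cohort_analysis:", x$params$n_subjects, "subjects, axes",
      paste(x$params$axes, collapse = "/"), "\n")
  if (!is.null(x$recovery))
    cat(sprintf("  planted-slab recovery: %.1f%% of %d assigned voxels\n",
                100 * x$recovery$rate, x$recovery$assigned))
  for (sn in names(x$axis_selection))
    cat("  ", sn, ": axis ", x$axis_selection[[sn]]$selected, ", polarity ",
        x$axis_selection[[sn]]$polarity, "\n", sep = "")
  invisible(x)
}

#' Run the pipeline end to end on a cohort directory
#'
#' Loads a cohort written by \code{\link{generate_cohort}}, runs
#' \code{\link{analyze_cohort}}, and writes winner-take-all and consensus
#' NIfTI volumes, consistency and gradient CSV tables, and a
#' machine-readable \code{results.json} (plus the resolved parameters)
#' under \code{out_dir}. Deterministic for a fixed cohort.
#'
#' @param cohort_dir directory containing \code{manifest.yaml}.
#' @param out_dir output directory (created if needed).
#' @param ... parameters passed to \code{\link{analyze_cohort}}.
#' @return The \code{cohort_analysis}, invisibly; outputs on disk.
#' @export
run_pipeline <- function(cohort_dir, out_dir, ...) {
  cohort <- load_cohort(file.path(cohort_dir, "manifest.yaml"))
  subjects <- lapply(cohort$subjects, function(s) {
    s$planted_axis <- cohort$slab_axis
    s
  })
  res <- analyze_cohort(subjects,
                        slab_thickness_mm = cohort$slab_thickness_mm, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (ax in names(res$wta)) for (h in c("L", "R")) {
    for (id in names(res$wta[[ax]][[h]]))
      write_wta_map(res$wta[[ax]][[h]][[id]],
                    file.path(out_dir,
                              sprintf("wta_%s_%s_%s.nii.gz", id, ax, h)))
    g <- res$consensus[[ax]][[h]]
    if (!is.null(g)) {
      vol <- array(0, g$geometry$dims)
      vol[g$voxel_idx] <- ifelse(is.na(g$mean_position), 0, g$mean_position)
      sup <- array(0, g$geometry$dims)
      sup[g$voxel_idx] <- g$support
      RNifti::writeNifti(as_nifti_with_geometry(vol, g$geometry),
                         file.path(out_dir,
                                   sprintf("consensus_%s_%s.nii.gz", ax, h)))
      RNifti::writeNifti(as_nifti_with_geometry(sup, g$geometry),
                         file.path(out_dir,
                                   sprintf("support_%s_%s.nii.gz", ax, h)))
    }
  }
  if (!is.null(res$consistency)) {
    ct <- do.call(rbind, c(lapply(res$consistency, as.data.frame),
                           list(make.row.names = FALSE)))
    utils::write.csv(ct, file.path(out_dir, "consistency.csv"),
                     row.names = FALSE)
  }
  if (length(res$gradients) > 0L)
    utils::write.csv(do.call(rbind, c(unname(res$gradients),
                                      list(make.row.names = FALSE))),
                     file.path(out_dir, "gradients.csv"), row.names = FALSE)
  summary_json <- list(
    params = res$params,
    mean_rho = if (!is.null(res$consistency))
      lapply(res$consistency, function(tb) {
        r <- attr(tb, "mean_rho")
        if (is.finite(r)) r else NULL  # undefined -> null, not "NaN"
      }),
    friedman = if (!is.null(res$comparison))
      list(chi2 = res$comparison$chi2, df = res$comparison$df,
           p = res$comparison$p),
    axis_selection = lapply(res$axis_selection, function(s)
      list(selected = s$selected, polarity = s$polarity)),
    recovery = if (!is.null(res$recovery))
      list(rate = res$recovery$rate, assigned = res$recovery$assigned))
  jsonlite::write_json(summary_json, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}

#' Replicate cohort analyses to measure recovery rates
#'
#' Generates \code{n_replicates} independent cohorts (seeds
#' \code{seed + 1 .. seed + n}) and records, per replicate: the
#' planted-slab recovery rate, and per sulcus the selected pulvinar axis
#' and detected polarity.
#'
#' @param config a \code{cohort_config} (its \code{rng_seed} is replaced
#'   per replicate).
#' @param n_replicates number of cohorts.
#' @param seed base seed.
#' @param axes,alpha,fwhm_mm passed to \code{\link{analyze_cohort}}.
#' @return Data frame with one row per replicate x sulcus: columns
#'   \code{replicate}, \code{sulcus}, \code{planted_axis},
#'   \code{planted_polarity}, \code{selected_axis}, \code{polarity},
#'   \code{recovery_rate}, \code{n_assigned}.
#' @export
cohort_replication_study <- function(config, n_replicates, seed = 1L,
                                     axes = c("LM", "AP", "VD"),
                                     alpha = 0.001, fwhm_mm = 2) {
  rows <- list()
  for (rep in seq_len(n_replicates)) {
    cfg <- config
    cfg$rng_seed <- as.integer((seed + rep * 7919) %% 2147483629)
    subjects <- lapply(seq_len(cfg$n_subjects),
                       function(i) generate_subject(cfg, i))
    res <- analyze_cohort(subjects, axes = axes, alpha = alpha,
                          fwhm_mm = fwhm_mm,
                          slab_thickness_mm = cfg$slab_thickness_mm)
    for (b in seq_len(nrow(cfg$bands))) {
      sn <- cfg$bands$sulcus[b]
      sel <- res$axis_selection[[sn]]
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep, sulcus = sn,
        planted_axis = cfg$slab_axis,
        planted_polarity = cfg$bands$polarity[b],
        selected_axis = sel$selected, polarity = sel$polarity,
        recovery_rate = if (!is.null(res$recovery)) res$recovery$rate
                        else NA_real_,
        n_assigned = if (!is.null(res$recovery)) res$recovery$assigned
                     else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
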