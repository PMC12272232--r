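#' Spearman spatial correlation between two WTA maps
#'
#' Rank correlation of the normalized winning-slab positions over the
#' voxels assigned in \emph{both} maps (the intersection domain).
#'
#' @param a,b \code{wta_map} objects for the same axis and grid.
#' @param min_overlap smallest admissible number of jointly assigned
#'   voxels (default 10); below it the correlation is undefined and an
#'   error is raised.
#' @return Spearman's rho.
#' @export
wta_spearman <- function(a, b, min_overlap = 10L) {
  stopifnot(inherits(a, "wta_map"), inherits(b, "wta_map"))
  if (a$axis != b$axis) stop("maps are for different axes")
  stop_if_grid_mismatch(a$geometry, b$geometry, "WTA maps")
  if (!identical(a$voxel_idx, b$voxel_idx))
    stop("maps cover different voxel sets")
  pa <- wta_positions(a)
  pb <- wta_positions(b)
  both <- !is.na(pa) & !is.na(pb)
  if (sum(both) < min_overlap)
    stop("only ", sum(both), " jointly assigned voxels (need >= ",
         min_overlap, ")")
  stats::cor(pa[both], pb[both], method = "spearman")
}

#' Inter-subject consistency table for one axis
#'
#' Spearman rho for every unordered subject pair.
#'
#' @param maps list of \code{wta_map} (one per subject, same axis/grid).
#' @param min_overlap passed to \code{\link{wta_spearman}}; pairs with
#'   insufficient overlap are recorded as \code{NA}.
#' @return A data frame of class \code{consistency_table} with columns
#'   \code{axis}, \code{hemisphere}, \code{subject_a}, \code{subject_b},
#'   \code{rho}; attribute \code{mean_rho}.
#' @export
consistency_table <- function(maps, min_overlap = 10L) {
  n <- length(maps)
  if (n < 2L) stop("need at least 2 subjects")
  pairs <- utils::combn(n, 2)
  rho <- apply(pairs, 2, function(ij) {
    tryCatch(wta_spearman(maps[[ij[1]]], maps[[ij[2]]], min_overlap),
             error = function(e) NA_real_)
  })
  out <- data.frame(
    axis = maps[[1]]$axis,
    hemisphere = maps[[1]]$hemisphere,
    subject_a = vapply(pairs[1, ], function(i) maps[[i]]$subject_id, ""),
    subject_b = vapply(pairs[2, ], function(i) maps[[i]]$subject_id, ""),
    rho = rho,
    stringsAsFactors = FALSE)
  attr(out, "mean_rho") <- mean(rho, na.rm = TRUE)
  class(out) <- c("consistency_table", class(out))
  out
}

#' Compare inter-subject consistency across the three anatomical axes
#'
#' Friedman rank-sum test over blocks (subject pair x hemisphere) with the
#' three axes as conditions (df = 2), followed by post-hoc paired
#' two-sided Wilcoxon signed-rank tests per axis pair with Bonferroni
#' adjustment. Fully tied blocks throughout (identical columns) are the
#' degenerate no-evidence case and return chi-squared 0, p = 1.
#'
#' @param tables named list of three \code{consistency_table}s (or a
#'   blocks x 3 numeric matrix of rho values with axis column names);
#'   tables must cover the same blocks in the same order.
#' @return An object of class \code{axis_comparison}: \code{chi2},
#'   \code{df}, \code{p}, \code{n_blocks}, \code{posthoc} (data frame of
#'   pairwise Bonferroni-adjusted p-values), \code{rho_matrix}.
#' @export
compare_axes <- function(tables) {
  if (is.matrix(tables)) {
    m <- tables
    if (is.null(colnames(m))) colnames(m) <- c("LM", "AP", "VD")
  } else {
    if (length(tables) != 3L) stop("need consistency tables for 3 axes")
    axes <- vapply(tables, function(tb) tb$axis[1], "")
    rows <- lapply(tables, function(tb)
      paste(tb$hemisphere, tb$subject_a, tb$subject_b, sep = ":"))
    for (i in 2:3)
      if (!identical(rows[[i]], rows[[1]]))
        stop("tables cover different blocks; same pairs and hemispheres ",
             "are required for all axes")
    m <- vapply(tables, function(tb) tb$rho, numeric(nrow(tables[[1]])))
    m <- matrix(m, ncol = 3, dimnames = list(rows[[1]], axes))
  }
  if (nrow(m) < 3L) stop("need at least 3 blocks for the Friedman test")
  if (anyNA(m)) stop("missing consistency values; all blocks must be ",
                     "complete across axes")
  all_tied <- all(apply(m, 1, function(r) max(r) == min(r)))
  if (all_tied) {
    chi2 <- 0; p <- 1
  } else {
    ft <- stats::friedman.test(m)
    chi2 <- unname(ft$statistic); p <- ft$p.value
  }
  cmb <- utils::combn(3, 2)
  posthoc <- data.frame(
    axis_a = colnames(m)[cmb[1, ]],
    axis_b = colnames(m)[cmb[2, ]],
    p_raw = apply(cmb, 2, function(ij) {
      d <- m[, ij[1]] - m[, ij[2]]
      if (all(d == 0)) return(1)
      suppressWarnings(stats::wilcox.test(m[, ij[1]], m[, ij[2]],
                                          paired = TRUE)$p.value)
    }),
    stringsAsFactors = FALSE)
  posthoc$p_adj <- pmin(1, posthoc$p_raw * nrow(posthoc))
  structure(list(chi2 = chi2, df = 2L, p = p, n_blocks = nrow(m),
                 posthoc = posthoc, rho_matrix = m),
            class = "axis_comparison")
}

#' @export
print.axis_comparison <- function(x, ...) {
  cat(sprintf("Friedman chi2(%d) = %.3f, p = %.4g over %d blocks\n",
              x$df, x$chi2, x$p, x$n_blocks))
  print(x$posthoc)
  invisible(x)
}
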