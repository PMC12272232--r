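#' Winner-take-all cortical assignment map
#'
#' For each cortical voxel, among the slabs significant at the stack's
#' alpha (across-run t-test), the winner is the slab with the maximal
#' connectivity statistic; exact ties break toward the smaller slab label.
#' Voxels where no slab reaches significance stay unassigned. The default
#' comparison statistic is the mean Fisher-z correlation (the strength of
#' functional connectivity itself, with the t-test acting only as the
#' significance gate); \code{stat = "t"} compares the across-run t
#' instead.
#'
#' @param stack a \code{stat_map_stack}.
#' @param stat comparison statistic for the argmax: \code{"mean_z"}
#'   (default) or \code{"t"}.
#' @param gate where the significance threshold acts. \code{"winner"}
#'   (default): the argmax is taken over all slabs and the voxel is
#'   assigned only if that winning slab is significant there.
#'   \code{"candidates"}: the argmax is restricted to the slabs
#'   significant at the voxel. The two agree whenever the winning slab is
#'   significant; they differ for voxels where a non-maximal slab alone
#'   reaches significance, which \code{"winner"} leaves unassigned.
#' @return An object of class \code{wta_map}: \code{winner} (integer slab
#'   label, 0-based, \code{NA} = unassigned), \code{winner_stat} (the
#'   winning statistic), \code{voxel_idx}, \code{labeling}, \code{axis},
#'   \code{hemisphere}, \code{subject_id}, \code{n_slabs}.
#' @export
winner_take_all <- function(stack, stat = c("mean_z", "t"),
                            gate = c("winner", "candidates")) {
  stopifnot(inherits(stack, "stat_map_stack"))
  stat <- match.arg(stat)
  gate <- match.arg(gate)
  tt <- if (stat == "mean_z") stack$mean_z else stack$t
  tt[is.na(tt)] <- -Inf
  winner <- rep(NA_integer_, ncol(tt))
  wstat <- rep(NA_real_, ncol(tt))
  if (gate == "candidates") {
    tt[!stack$significant] <- -Inf
    any_sig <- colSums(stack$significant) > 0
    if (any(any_sig)) {
      sub <- tt[, any_sig, drop = FALSE]
      w <- apply(sub, 2, which.max)  # first max = smallest label on ties
      winner[any_sig] <- as.integer(w) - 1L
      wstat[any_sig] <- sub[cbind(w, seq_len(ncol(sub)))]
    }
  } else {
    w <- apply(tt, 2, which.max)
    ok <- stack$significant[cbind(w, seq_len(ncol(tt)))] &
      is.finite(tt[cbind(w, seq_len(ncol(tt)))])
    winner[ok] <- as.integer(w[ok]) - 1L
    wstat[ok] <- tt[cbind(w, seq_len(ncol(tt)))][ok]
  }
  structure(list(subject_id = stack$subject_id, axis = stack$axis,
                 hemisphere = stack$hemisphere,
                 winner = winner, winner_stat = wstat,
                 voxel_idx = stack$voxel_idx, labeling = stack$labeling,
                 n_slabs = stack$labeling$n_slabs,
                 geometry = stack$geometry),
            class = "wta_map")
}

#' @export
print.wta_map <- function(x, ...) {
  cat("wta_map:", x$subject_id, "axis", x$axis, "-",
      sum(!is.na(x$winner)), "of", length(x$winner), "voxels assigned\n")
  invisible(x)
}

#' Normalized winning-slab positions of a WTA map
#'
#' @param map a \code{wta_map}.
#' @return Numeric vector over the map's voxels: \code{slab_position} of the
#'   winner, \code{NA} where unassigned.
#' @export
wta_positions <- function(map) {
  stopifnot(inherits(map, "wta_map"))
  pos <- rep(NA_real_, length(map$winner))
  ok <- !is.na(map$winner)
  if (any(ok)) pos[ok] <- slab_position(map$labeling, map$winner[ok])
  pos
}

#' Group consensus map over subjects
#'
#' Per cortical voxel, the mean of the normalized winning-slab positions
#' over the subjects in which the voxel is assigned (significant
#' connectivity), together with the support count. Voxels supported by
#' fewer than half the subjects (\code{support < ceiling(n/2)}) are
#' removed. Averaging on normalized positions keeps subjects with
#' different slab counts commensurable.
#'
#' @param maps list of \code{wta_map}, one per subject, same axis and grid.
#' @return An object of class \code{group_wta_map}: \code{mean_position}
#'   (NA where not retained), \code{support}, \code{retained} (logical),
#'   \code{voxel_idx}, \code{n_subjects}, \code{axis}, \code{hemisphere}.
#' @export
group_consensus <- function(maps) {
  if (length(maps) == 0L) stop("empty map list")
  ax <- maps[[1]]$axis
  vox <- maps[[1]]$voxel_idx
  for (m in maps) {
    stopifnot(inherits(m, "wta_map"))
    if (m$axis != ax) stop("maps mix axes (", ax, " vs ", m$axis, ")")
    stop_if_grid_mismatch(m$geometry, maps[[1]]$geometry, "WTA maps")
    if (!identical(m$voxel_idx, vox))
      stop("maps cover different voxel sets")
  }
  n <- length(maps)
  pos <- vapply(maps, wta_positions, numeric(length(vox)))
  pos <- matrix(pos, ncol = n)
  support <- rowSums(!is.na(pos))
  mean_pos <- ifelse(support > 0, rowMeans(pos, na.rm = TRUE), NA_real_)
  retained <- support >= ceiling(n / 2)
  mean_pos[!retained] <- NA_real_
  structure(list(axis = ax, hemisphere = maps[[1]]$hemisphere,
                 mean_position = mean_pos,
                 support = as.integer(support), retained = retained,
                 voxel_idx = vox, n_subjects = n,
                 geometry = maps[[1]]$geometry),
            class = "group_wta_map")
}

#' @export
print.group_wta_map <- function(x, ...) {
  cat("group_wta_map: axis", x$axis, "-", sum(x$retained), "of",
      length(x$retained), "voxels retained (n =", x$n_subjects, ")\n")
  invisible(x)
}

#' Write a WTA map as NIfTI-1 volumes
#'
#' The winner volume stores 0 for unassigned and \code{k + 1} for slab
#' \code{k}; the statistic volume stores the winning t (0 where
#' unassigned).
#'
#' @param map a \code{wta_map}.
#' @param winner_path output path for the integer winner volume.
#' @param stat_path optional output path for the winning-statistic volume.
#' @return \code{winner_path}, invisibly.
#' @export
write_wta_map <- function(map, winner_path, stat_path = NULL) {
  d <- map$geometry$dims
  vol <- array(0, d)
  vol[map$voxel_idx] <- ifelse(is.na(map$winner), 0L, map$winner + 1L)
  RNifti::writeNifti(as_nifti_with_geometry(vol, map$geometry),
                     winner_path, datatype = "int16")
  if (!is.null(stat_path)) {
    sv <- array(0, d)
    sv[map$voxel_idx] <- ifelse(is.na(map$winner_stat), 0,
                                map$winner_stat)
    RNifti::writeNifti(as_nifti_with_geometry(sv, map$geometry),
                       stat_path, datatype = "double")
  }
  invisible(winner_path)
}
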