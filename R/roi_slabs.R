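#' Subdivide a seed mask into fixed-thickness slabs along an anatomical axis
#'
#' Each mask voxel is binned by its centre's world coordinate along the
#' chosen axis into half-open 2-mm (by default) bins anchored at the mask's
#' own minimum coordinate: label \code{k} covers
#' \code{[c_min + k*t, c_min + (k+1)*t)}. Axis direction follows the
#' anatomical conventions: LM runs lateral to medial within the given
#' hemisphere, AP posterior to anterior, VD ventral to dorsal, so labels
#' increase along those directions. Bins left empty by a non-axis-connected
#' mask are dropped and labels re-compacted to a contiguous
#' \code{0..n_slabs-1}.
#'
#' @param mask an \code{roi_mask} (non-empty).
#' @param axis one of \code{"LM"}, \code{"AP"}, \code{"VD"}.
#' @param thickness_mm slab thickness in mm (> 0); default 2.
#' @param hemisphere \code{"L"} or \code{"R"}; only consulted for the LM
#'   axis, where the lateral end differs between hemispheres.
#' @return An object of class \code{slab_labeling} with fields \code{axis},
#'   \code{hemisphere}, \code{thickness_mm}, \code{labels} (integer 3D array,
#'   \code{NA} outside the mask, slab index 0-based inside), \code{n_slabs},
#'   and \code{slab_center_mm} (world coordinate of each slab's bin midpoint
#'   along the axis, strictly increasing).
#' @export
slice_mask <- function(mask, axis = c("LM", "AP", "VD"), thickness_mm = 2,
                       hemisphere = c("L", "R")) {
  stopifnot(inherits(mask, "roi_mask"))
  axis <- match.arg(axis)
  hemisphere <- match.arg(hemisphere)
  if (!is.numeric(thickness_mm) || thickness_mm <= 0)
    stop("thickness_mm must be > 0")
  idx <- which(mask$voxels)
  if (length(idx) == 0L) stop("cannot slice an empty mask")
  ijk <- arrayInd(idx, dim(mask$voxels))
  cc <- axis_coordinate(mask$geometry, ijk, axis, hemisphere)
  c_min <- min(cc)
  # small tolerance so coordinates that are exact bin multiples up to float
  # error land in the intended bin
  bin <- as.integer(floor((cc - c_min) / thickness_mm + 1e-9))
  kept <- sort(unique(bin))
  lab <- match(bin, kept) - 1L  # compact empty bins
  labels <- array(NA_integer_, dim(mask$voxels))
  labels[idx] <- lab
  structure(list(axis = axis, hemisphere = hemisphere,
                 thickness_mm = thickness_mm,
                 geometry = mask$geometry,
                 labels = labels,
                 n_slabs = length(kept),
                 slab_center_mm = c_min + (kept + 0.5) * thickness_mm),
            class = "slab_labeling")
}

#' @export
print.slab_labeling <- function(x, ...) {
  cat("slab_labeling:", x$n_slabs, "slabs of", x$thickness_mm, "mm along",
      x$axis, paste0("(", x$hemisphere, ")"), "\n")
  invisible(x)
}

#' Linear indices of the voxels in one slab
#' @param labeling a \code{slab_labeling}.
#' @param label slab index in \code{0..n_slabs-1}.
#' @return Integer vector of linear voxel indices.
#' @export
slab_voxels <- function(labeling, label) {
  check_slab_label(labeling, label)
  which(!is.na(labeling$labels) & labeling$labels == label)
}

check_slab_label <- function(labeling, label) {
  stopifnot(inherits(labeling, "slab_labeling"))
  if (length(label) != 1L || is.na(label) || label < 0 ||
      label >= labeling$n_slabs)
    stop("slab label ", label, " out of range [0, ",
         labeling$n_slabs - 1, "]")
  invisible(TRUE)
}

#' Normalized position of a slab along its axis
#'
#' Maps slab centres linearly to \code{[0, 1]}; with a single slab the
#' position is defined as 0.5.
#'
#' @param labeling a \code{slab_labeling}.
#' @param label slab index (0-based); vectorized.
#' @return Numeric in \code{[0, 1]}.
#' @export
slab_position <- function(labeling, label) {
  stopifnot(inherits(labeling, "slab_labeling"))
  if (any(is.na(label)) || any(label < 0) || any(label >= labeling$n_slabs))
    stop("slab label out of range [0, ", labeling$n_slabs - 1, "]")
  if (labeling$n_slabs == 1L) return(rep(0.5, length(label)))
  ctr <- labeling$slab_center_mm
  (ctr[label + 1L] - ctr[1L]) / (ctr[labeling$n_slabs] - ctr[1L])
}

#' Serialize a slab labeling as an integer NIfTI volume
#'
#' Voxels outside the mask are 0; slab \code{k} is stored as \code{k + 1}.
#' Slab centres go to a companion CSV when \code{centers_csv} is given.
#'
#' @param labeling a \code{slab_labeling}.
#' @param path output NIfTI path.
#' @param centers_csv optional CSV path for the slab-centre table.
#' @return \code{path}, invisibly.
#' @export
write_slab_labeling <- function(labeling, path, centers_csv = NULL) {
  vol <- labeling$labels + 1L
  vol[is.na(vol)] <- 0L
  nii <- as_nifti_with_geometry(array(as.double(vol), dim(vol)),
                                labeling$geometry)
  RNifti::writeNifti(nii, path, datatype = "int16")
  if (!is.null(centers_csv))
    utils::write.csv(data.frame(slab = seq_len(labeling$n_slabs) - 1L,
                                center_mm = labeling$slab_center_mm),
                     centers_csv, row.names = FALSE)
  invisible(path)
}
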