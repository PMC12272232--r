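#' Construct a volume geometry
#'
#' A \code{volume_geometry} holds the voxel grid shared by all volumes in an
#' analysis: array dimensions, voxel size, and the 4x4 affine mapping 0-based
#' voxel indices to world millimetres in the RAS+ convention (+x right,
#' +y anterior, +z superior). All slab and sulcus logic operates in world mm
#' through this affine, never in array-index space.
#'
#' @param dims integer vector of length 3, voxels per axis.
#' @param voxel_size_mm positive numeric vector of length 3.
#' @param affine 4x4 numeric matrix (voxel index, 0-based, to world mm). If
#'   \code{NULL}, a diagonal affine with the grid centred on the origin is
#'   built from \code{voxel_size_mm}.
#' @return An object of class \code{volume_geometry}.
#' @export
volume_geometry <- function(dims, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size_mm
    # centre the grid: voxel (i) centre at (i - (n-1)/2) * size
    affine[1:3, 4] <- -(dims - 1) / 2 * voxel_size_mm
  }
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps)
    stop("affine matrix is singular")
  colnorm <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(colnorm - voxel_size_mm) > 1e-6))
    stop("voxel_size_mm inconsistent with affine column norms")
  structure(list(dims = dims, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("volume_geometry:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_size_mm, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Test whether two geometries describe the same grid
#'
#' @param a,b \code{volume_geometry} objects.
#' @param tol_mm per-element tolerance on the affines, in mm.
#' @return \code{TRUE} iff dims are equal and affines agree within
#'   \code{tol_mm} per element.
#' @export
check_same_grid <- function(a, b, tol_mm = 1e-4) {
  stopifnot(inherits(a, "volume_geometry"), inherits(b, "volume_geometry"))
  identical(a$dims, b$dims) && all(abs(a$affine - b$affine) <= tol_mm)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!check_same_grid(a, b))
    stop("grid mismatch between ", what,
         " (dims or affine differ); all volumes must share one grid")
  invisible(TRUE)
}

geometry_of <- function(x) {
  if (inherits(x, "volume_geometry")) return(x)
  if (!is.null(x$geometry)) return(x$geometry)
  stop("cannot extract a volume_geometry from object of class ",
       paste(class(x), collapse = "/"))
}

#' World-mm coordinates of voxel centres
#'
#' @param geometry a \code{volume_geometry}.
#' @param ijk n x 3 matrix of 1-based array indices.
#' @return n x 3 matrix of world coordinates (mm, RAS+).
#' @export
voxel_world_coords <- function(geometry, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz1 <- cbind(ijk - 1, 1) %*% t(geometry$affine)  # 0-based indices
  xyz1[, 1:3, drop = FALSE]
}

# Signed world coordinate along an anatomical axis, increasing in the
# direction labels/positions grow: LM lateral -> medial (hemisphere-aware),
# AP posterior -> anterior (+y), VD ventral -> dorsal (+z).
axis_coordinate <- function(geometry, ijk, axis, hemisphere = "L") {
  axis <- match.arg(axis, c("LM", "AP", "VD"))
  xyz <- voxel_world_coords(geometry, ijk)
  switch(axis,
         AP = xyz[, 2],
         VD = xyz[, 3],
         LM = {
           hemisphere <- match.arg(hemisphere, c("L", "R"))
           if (hemisphere == "L") xyz[, 1] else -xyz[, 1]
         })
}

#' Construct a 4D image
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param geometry a \code{volume_geometry} matching \code{dim(data)[1:3]}.
#' @param tr_s repetition time in seconds (> 0).
#' @return An object of class \code{image4d}.
#' @export
image4d <- function(data, geometry, tr_s) {
  stopifnot(length(dim(data)) == 4L)
  if (!identical(as.integer(dim(data)[1:3]), geometry$dims))
    stop("data dimensions do not match geometry")
  if (dim(data)[4] < 2L) stop("an image4d needs at least 2 volumes")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a single positive number")
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at voxel (%d, %d, %d), volume %d",
                 bad[1], bad[2], bad[3], bad[4]))
  }
  structure(list(geometry = geometry, data = data, tr_s = tr_s,
                 n_volumes = dim(data)[4]),
            class = "image4d")
}

# internal constructor for data produced by the package itself (already
# finite by construction); skips the full-array validation scan
new_image4d <- function(data, geometry, tr_s) {
  structure(list(geometry = geometry, data = data, tr_s = tr_s,
                 n_volumes = dim(data)[4]),
            class = "image4d")
}

#' @export
print.image4d <- function(x, ...) {
  cat("image4d:", paste(dim(x$data), collapse = " x "),
      sprintf("(TR %.3g s)\n", x$tr_s))
  invisible(x)
}

geometry_from_nifti <- function(img) {
  dims <- dim(img)
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  volume_geometry(dims[1:3], voxel_size_mm = sqrt(colSums(aff[1:3, 1:3]^2)),
                  affine = aff)
}

#' Read a 4D NIfTI-1 time series
#'
#' The repetition time is taken from the header (\code{pixdim[4]}) unless
#' overridden; data are held in native array order with world positions
#' resolved through the sform/qform affine (RAS+).
#'
#' @param path path to a \code{.nii}/\code{.nii.gz} file.
#' @param tr_s optional TR override in seconds (e.g. from a sidecar config);
#'   when supplied it replaces the header value and a message is emitted.
#' @return An \code{image4d}.
#' @export
load_image4d <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D image, got ", length(dim(img)), "D: ", path)
  hdr_tr <- RNifti::pixdim(img)[4]
  if (!is.null(tr_s)) {
    message("TR override: using ", tr_s, " s instead of header value ", hdr_tr)
  } else {
    tr_s <- hdr_tr
  }
  if (!is.finite(tr_s) || tr_s <= 0)
    stop("non-positive TR (", tr_s, ") in ", path,
         "; supply tr_s explicitly")
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  if (anyNA(dat) || any(!is.finite(dat))) {
    bad <- which(!is.finite(dat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite voxel at (%d, %d, %d), volume %d in %s",
                 bad[1], bad[2], bad[3], bad[4], path))
  }
  image4d(dat, geometry_from_nifti(img), tr_s)
}

as_nifti_with_geometry <- function(data, geometry, tr_s = NULL) {
  img <- RNifti::asNifti(data)
  pd <- c(geometry$voxel_size_mm, if (!is.null(tr_s)) tr_s)
  RNifti::pixdim(img) <- c(pd, rep(1, length(dim(data)) - length(pd)))
  RNifti::`qform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
}

#' Write a 4D image as NIfTI-1
#'
#' @param img an \code{image4d}.
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return \code{path}, invisibly.
#' @export
write_image4d <- function(img, path) {
  stopifnot(inherits(img, "image4d"))
  nii <- as_nifti_with_geometry(img$data, img$geometry, img$tr_s)
  RNifti::writeNifti(nii, path, datatype = "double")
  invisible(path)
}

#' Construct a binary region-of-interest mask
#'
#' @param voxels logical 3D array over the grid.
#' @param geometry a \code{volume_geometry}.
#' @param name label for the region.
#' @param allow_empty permit a mask with no voxels (default \code{FALSE}).
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(voxels, geometry, name = "roi", allow_empty = FALSE) {
  stopifnot(is.logical(voxels), length(dim(voxels)) == 3L)
  if (!identical(as.integer(dim(voxels)), geometry$dims))
    stop("mask dimensions do not match geometry")
  if (!allow_empty && !any(voxels))
    stop("mask '", name, "' is empty")
  structure(list(geometry = geometry, voxels = voxels, name = name),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask '", x$name, "': ", sum(x$voxels), " voxels\n", sep = "")
  invisible(x)
}

#' Read a binary mask from NIfTI-1
#'
#' Values must be exactly 0 or 1.
#'
#' @param path file path.
#' @param name label for the region (defaults to the file base name).
#' @return An \code{roi_mask}.
#' @export
load_mask <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("mask must be 3D: ", path)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  if (!all(dat %in% c(0, 1)))
    stop("mask values must be 0/1: ", path)
  roi_mask(array(dat > 0.5, dim(dat)), geometry_from_nifti(img),
           name = if (is.null(name)) sub("\\.nii(\\.gz)?$", "", basename(path))
                  else name)
}

#' Write a binary mask as NIfTI-1
#' @param mask an \code{roi_mask}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  nii <- as_nifti_with_geometry(array(as.double(mask$voxels),
                                      dim(mask$voxels)), mask$geometry)
  RNifti::writeNifti(nii, path, datatype = "uint8")
  invisible(path)
}

#' Read a motion-regressor table
#'
#' Whitespace-delimited text, one row per volume, exactly six columns
#' (three translations in mm, three rotations in rad). A different column
#' count is an error: format drift fails loudly.
#'
#' @param path file path.
#' @param n_volumes if given, the required row count.
#' @return A numeric matrix with 6 columns.
#' @export
load_motion <- function(path, n_volumes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L)
    stop("motion table must have exactly 6 columns, found ", ncol(m),
         ": ", path)
  if (anyNA(m)) stop("non-numeric or missing entries in motion table: ", path)
  if (!is.null(n_volumes) && nrow(m) != n_volumes)
    stop("motion table has ", nrow(m), " rows but the run has ",
         n_volumes, " volumes: ", path)
  dimnames(m) <- list(NULL, c("tx_mm", "ty_mm", "tz_mm",
                              "rx_rad", "ry_rad", "rz_rad"))
  m
}

#' Bundle one run's image and motion regressors
#'
#' @param image an \code{image4d}.
#' @param motion T x 6 numeric matrix; row count must equal the number of
#'   volumes.
#' @param run_id identifier string.
#' @return An object of class \code{run_data}.
#' @export
run_data <- function(image, motion, run_id = "run") {
  stopifnot(inherits(image, "image4d"))
  motion <- as.matrix(motion)
  if (nrow(motion) != image$n_volumes)
    stop("motion rows (", nrow(motion), ") != image volumes (",
         image$n_volumes, ") for ", run_id)
  if (ncol(motion) != 6L) stop("motion must have 6 columns")
  structure(list(image = image, motion = motion, run_id = run_id),
            class = "run_data")
}
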