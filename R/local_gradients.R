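#' Parameterize a sulcus mask along an anatomical axis
#'
#' Each sulcus voxel receives a normalized position in [0, 1] from its
#' centre's world coordinate along the declared axis:
#' \code{(c - c_min) / (c_max - c_min)}. Low positions are posterior (AP),
#' ventral (VD) or lateral (LM, hemisphere-aware), matching the slab
#' conventions.
#'
#' @param mask an \code{roi_mask} with at least 2 voxels and nonzero
#'   extent along the axis.
#' @param position_axis \code{"AP"}, \code{"VD"} or \code{"LM"}.
#' @param hemisphere \code{"L"} or \code{"R"} (consulted for LM).
#' @return An object of class \code{sulcus_path}: \code{name},
#'   \code{hemisphere}, \code{position_axis}, \code{voxel_idx} (linear
#'   indices), \code{position} (numeric per voxel), \code{geometry}.
#' @export
parameterize_sulcus <- function(mask, position_axis = c("AP", "VD", "LM"),
                                hemisphere = c("L", "R")) {
  stopifnot(inherits(mask, "roi_mask"))
  position_axis <- match.arg(position_axis)
  hemisphere <- match.arg(hemisphere)
  idx <- which(mask$voxels)
  if (length(idx) < 2L) stop("sulcus mask needs at least 2 voxels")
  ijk <- arrayInd(idx, dim(mask$voxels))
  cc <- axis_coordinate(mask$geometry, ijk, position_axis, hemisphere)
  ext <- max(cc) - min(cc)
  if (ext <= 0) stop("sulcus '", mask$name, "' has zero extent along ",
                     position_axis)
  structure(list(name = mask$name, hemisphere = hemisphere,
                 position_axis = position_axis, voxel_idx = idx,
                 position = (cc - min(cc)) / ext,
                 geometry = mask$geometry),
            class = "sulcus_path")
}

#' Regress winning-slab position on sulcus position
#'
#' Pools, over all subjects' WTA maps for one pulvinar axis, the assigned
#' voxels inside the sulcus mask as points (x = normalized sulcus position,
#' y = normalized winning-slab position) and fits an ordinary
#' least-squares line. Polarity is \code{"direct"} for a significantly
#' positive slope, \code{"reversed"} for a significantly negative slope
#' (two-sided p of the slope below \code{alpha}), otherwise \code{"none"}.
#'
#' @param maps list of \code{wta_map} (one per subject) for one pulvinar
#'   axis and one hemisphere.
#' @param path a \code{sulcus_path} on the same grid and hemisphere.
#' @param alpha significance level for polarity (default 0.05).
#' @return A one-row data frame of class \code{gradient_fit}: columns
#'   \code{sulcus}, \code{hemisphere}, \code{pulvinar_axis}, \code{slope},
#'   \code{intercept}, \code{r}, \code{p}, \code{n_points},
#'   \code{polarity}, and \code{nonmonotone} — \code{TRUE} when a
#'   two-segment piecewise fit improves BIC over the single line,
#'   flagging a possible dual gradient (detection only).
#' @export
fit_gradient <- function(maps, path, alpha = 0.05) {
  stopifnot(inherits(path, "sulcus_path"), length(maps) >= 1L)
  ax <- maps[[1]]$axis
  xs <- ys <- list()
  for (m in maps) {
    stopifnot(inherits(m, "wta_map"))
    if (m$axis != ax) stop("maps mix pulvinar axes")
    stop_if_grid_mismatch(m$geometry, path$geometry, "map and sulcus")
    pos <- wta_positions(m)
    j <- match(path$voxel_idx, m$voxel_idx)
    covered <- !is.na(j)
    assigned <- covered
    assigned[covered] <- !is.na(pos[j[covered]])
    xs[[length(xs) + 1L]] <- path$position[assigned]
    ys[[length(ys) + 1L]] <- pos[j[assigned]]
  }
  x <- unlist(xs); y <- unlist(ys)
  if (length(x) < 10L)
    stop("only ", length(x), " pooled (position, winner) points for ",
         path$name, " ", path$hemisphere, "/", ax, " (need >= 10)")
  if (stats::var(x) == 0) stop("zero variance in sulcus positions")
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  if (stats::var(y) == 0) {          # flat winners: no gradient
    r <- 0; p <- 1
  } else {
    r <- stats::cor(x, y)
    # two-sided p of the slope; identical to the correlation t-test with
    # n - 2 df (and well defined at |r| = 1, where p -> 0)
    tval <- r * sqrt((n - 2) / max(1 - r^2, 0))
    p <- if (is.finite(tval)) 2 * stats::pt(-abs(tval), n - 2) else 0
  }
  polarity <- if (p < alpha && slope > 0) "direct"
              else if (p < alpha && slope < 0) "reversed" else "none"
  out <- data.frame(sulcus = path$name, hemisphere = path$hemisphere,
                    pulvinar_axis = ax, slope = slope,
                    intercept = intercept,
                    r = r, p = p, n_points = n,
                    polarity = polarity,
                    nonmonotone = detect_nonmonotone(x, y),
                    stringsAsFactors = FALSE)
  class(out) <- c("gradient_fit", class(out))
  out
}

# residual sum of squares of a one-segment OLS line
segment_rss <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(sum((y - mean(y))^2))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  sum((y - mean(y) - b * (x - mean(x)))^2)
}

# flag profiles where a two-segment piecewise line beats the single line
# by BIC (dual-gradient detection only; no segment inference is reported)
detect_nonmonotone <- function(x, y, min_segment = 8L) {
  n <- length(x)
  if (n < 2L * min_segment || stats::var(y) == 0) return(FALSE)
  rss_line <- segment_rss(x, y)
  bic_line <- n * log(max(rss_line, 1e-12) / n) + 3 * log(n)
  bic_best <- Inf
  for (q in seq(0.3, 0.7, by = 0.1)) {
    s <- stats::quantile(x, q, names = FALSE)
    left <- x <= s
    if (sum(left) < min_segment || sum(!left) < min_segment) next
    rss <- segment_rss(x[left], y[left]) + segment_rss(x[!left], y[!left])
    bic_best <- min(bic_best, n * log(max(rss, 1e-12) / n) + 6 * log(n))
  }
  is.finite(bic_best) && bic_best < bic_line
}

#' Select the pulvinar axis best explaining one sulcus's topography
#'
#' An axis qualifies when its regression is significant
#' (\code{p < alpha}) in \emph{both} hemispheres with slope signs agreeing
#' across hemispheres. Among qualifying axes, the one with the larger
#' \code{min(|r_L|, |r_R|)} is selected; \code{"none"} if no axis
#' qualifies.
#'
#' @param fits data frame of \code{\link{fit_gradient}} rows covering all
#'   three pulvinar axes in both hemispheres for one sulcus (six rows;
#'   failed fits may be encoded with \code{p = NA}, which disqualifies
#'   the axis).
#' @param alpha significance level (default 0.05).
#' @return List \code{selected} (axis name or \code{"none"}),
#'   \code{polarity} (of the selected axis, from the hemisphere-agreeing
#'   slope sign), \code{table} (per-axis qualification summary).
#' @export
select_axis <- function(fits, alpha = 0.05) {
  need <- c("hemisphere", "pulvinar_axis", "slope", "r", "p")
  stopifnot(all(need %in% names(fits)))
  if (length(unique(fits$sulcus)) > 1L)
    stop("select_axis expects fits for a single sulcus")
  axes <- unique(fits$pulvinar_axis)
  if (length(axes) != 3L ||
      !all(table(fits$pulvinar_axis, fits$hemisphere) == 1L))
    stop("need exactly one fit per pulvinar axis and hemisphere ",
         "(3 axes x 2 hemispheres)")
  summ <- do.call(rbind, lapply(axes, function(ax) {
    fl <- fits[fits$pulvinar_axis == ax & fits$hemisphere == "L", ]
    fr <- fits[fits$pulvinar_axis == ax & fits$hemisphere == "R", ]
    qual <- !is.na(fl$p) && !is.na(fr$p) && fl$p < alpha && fr$p < alpha &&
      sign(fl$slope) == sign(fr$slope) && fl$slope != 0
    data.frame(pulvinar_axis = ax, qualifies = qual,
               min_abs_r = min(abs(fl$r), abs(fr$r)),
               slope_sign = ifelse(sign(fl$slope) == sign(fr$slope),
                                   sign(fl$slope), NA_real_),
               stringsAsFactors = FALSE)
  }))
  q <- summ[summ$qualifies, , drop = FALSE]
  if (nrow(q) == 0L)
    return(list(selected = "none", polarity = "none", table = summ))
  best <- q[which.max(q$min_abs_r), ]
  list(selected = best$pulvinar_axis,
       polarity = if (best$slope_sign > 0) "direct" else "reversed",
       table = summ)
}
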