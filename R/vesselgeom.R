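#' Segment vessels from an intensity channel
#'
#' Global thresholding (Otsu or fixed) followed by removal of small
#' connected components.
#'
#' @param volume an [lsfm_volume()].
#' @param channel channel name (default `"vessels"`).
#' @param method `"otsu"` or `"fixed_threshold"`.
#' @param threshold numeric threshold for `fixed_threshold` (mask = intensity
#'   strictly above it).
#' @param min_size_um3 drop components smaller than this volume.
#' @param frame frame index for 4D data.
#' @return `vessel_mask`: list with logical `mask`, `spacing`, and
#'   `provenance` (threshold and cleanup used).
#' @export
segment_vessels <- function(volume, channel = "vessels",
                            method = c("otsu", "fixed_threshold"),
                            threshold = NULL, min_size_um3 = 20, frame = NULL) {
  method <- match.arg(method)
  arr <- vol_channel(volume, channel, frame)
  sp <- volume$spacing
  if (all(arr == 0)) lsfm_stop("no vessels found: channel is empty")
  th <- if (method == "otsu") otsu_threshold(arr) else {
    if (is.null(threshold)) lsfm_stop("fixed_threshold requires a threshold")
    threshold
  }
  mask <- arr > th
  if (any(mask) && min_size_um3 > 0) {
    lab <- label_components(mask, 26)
    sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n_components"))
    keep <- which(sizes * prod(sp) >= min_size_um3)
    mask <- array(lab %in% keep, dim = dim(mask))
  }
  if (!any(mask)) lsfm_stop("no vessels found after cleanup")
  structure(list(mask = mask, spacing = sp,
                 provenance = list(method = method, threshold = th,
                                   min_size_um3 = min_size_um3)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d foreground voxels (%.0f um3), threshold %.4g (%s)\n",
              sum(x$mask), sum(x$mask) * prod(x$spacing),
              x$provenance$threshold, x$provenance$method))
  invisible(x)
}

#' Fit the local plexus plane at a measurement site
#'
#' The orientation of the vascular plexus surrounding a vessel segment is
#' used as the reference surface for width/depth measurements. The plane is
#' fit to all skeleton points within `fit_radius` of the site: it passes
#' through their centroid and its normal is the direction of least variance
#' (smallest principal component) of the neighbourhood.
#'
#' @param skeleton a [skeletonize_mask()] result.
#' @param site `(x, y, z)` µm measurement point.
#' @param fit_radius neighbourhood radius, µm.
#' @param exclude optional logical array (same shape as the mask): skeleton
#'   voxels marked `TRUE` (e.g. tuft voxels) are excluded from the fit.
#' @param orient reference direction (vitreous side); the normal is flipped
#'   to have a positive dot product with it.
#' @return `plexus_plane`: list with `anchor` (µm), unit `normal`,
#'   `fit_radius`, `fit_residual` (RMS µm) and `n_points`.
#' @export
fit_plexus_plane <- function(skeleton, site, fit_radius = 30, exclude = NULL,
                             orient = c(0, 0, 1)) {
  pts <- skeleton$points
  if (!is.null(exclude)) {
    ex <- exclude[skeleton$voxels]
    pts <- pts[!ex, , drop = FALSE]
  }
  d2 <- rowSums((pts - matrix(site, nrow(pts), 3, byrow = TRUE))^2)
  near <- pts[d2 <= fit_radius^2, , drop = FALSE]
  if (nrow(near) < 10)
    lsfm_stop(sprintf("plexus neighborhood too sparse: %d skeleton points within %.0f um (need >= 10)",
                      nrow(near), fit_radius))
  ctr <- colMeans(near)
  sv <- svd(sweep(near, 2, ctr))
  normal <- sv$v[, 3]
  if (sum(normal * orient) < 0) normal <- -normal
  resid <- sqrt(mean((sweep(near, 2, ctr) %*% normal)^2))
  structure(list(anchor = ctr, normal = as.numeric(normal), fit_radius = fit_radius,
                 fit_residual = resid, n_points = nrow(near)),
            class = "plexus_plane")
}

#' @export
print.plexus_plane <- function(x, ...) {
  cat(sprintf("<plexus_plane> anchor (%.1f, %.1f, %.1f) um, normal (%.3f, %.3f, %.3f), RMS residual %.2f um (%d pts)\n",
              x$anchor[1], x$anchor[2], x$anchor[3],
              x$normal[1], x$normal[2], x$normal[3], x$fit_residual, x$n_points))
  invisible(x)
}

#' Chord of a binary mask through a point along a direction
#'
#' Bidirectional ray casting with trilinear interpolation of the mask and
#' linear sub-voxel localisation of the 0.5 crossing.
#' @noRd
mask_chord <- function(arr, spacing, site, dir, step = 0.25, max_len = 120) {
  dir <- normalize3(dir)
  half <- function(sgn) {
    ts <- seq(0, max_len, by = step)
    pts <- matrix(site, length(ts), 3, byrow = TRUE) + outer(ts, sgn * dir)
    v <- trilinear_sample(arr, spacing, pts, outside = 0)
    below <- which(v < 0.5)
    if (length(below) == 0) return(max_len)
    i <- below[1]
    if (i == 1) return(0)
    ts[i - 1] + step * (v[i - 1] - 0.5) / (v[i - 1] - v[i])
  }
  half(1) + half(-1)
}

#' Local vessel axis from the skeleton near a site
#' @noRd
local_vessel_axis <- function(skeleton, site, radius = 6) {
  pts <- skeleton$points
  d2 <- rowSums((pts - matrix(site, nrow(pts), 3, byrow = TRUE))^2)
  i0 <- which.min(d2)
  near <- pts[d2 <= max(radius, sqrt(d2[i0]) + 2)^2, , drop = FALSE]
  if (nrow(near) < 2) lsfm_stop("cannot determine local vessel axis near site")
  sv <- svd(sweep(near, 2, colMeans(near)))
  as.numeric(sv$v[, 1])
}

#' Measure plexus-plane-referenced vessel diameters at a site
#'
#' Realises the width/depth convention of correlative distortion analysis:
#' depth `D` is the chord of the vessel mask through the site along the
#' plexus-plane normal (the flat-mount z-axis equivalent), and width `W` the
#' chord along the in-plane direction perpendicular to the local vessel axis
#' (the XY-diameter equivalent). Chords use bidirectional ray casting with
#' sub-voxel 0.5-crossing localisation.
#'
#' @param mask a `vessel_mask` (or logical array plus `spacing`).
#' @param site `(x, y, z)` µm point inside the vessel.
#' @param plane a [fit_plexus_plane()] result (or any object with unit
#'   `normal`).
#' @param skeleton a [skeletonize_mask()] result for the local vessel axis.
#' @param spacing voxel spacing when `mask` is a bare array.
#' @param modality label stored with the measurement (`"lsfm"` or
#'   `"confocal"`).
#' @param width_mode `"perp_axis"` (default: in-plane chord perpendicular to
#'   the vessel axis) or `"max_inplane"` (maximal in-plane chord).
#' @param min_axis_angle_deg reject sites whose vessel axis is within this
#'   angle of the plane normal (width direction ill-defined).
#' @param step ray-casting step, µm.
#' @return one-row data frame (`diameter_measurement`): site coordinates,
#'   `width_um`, `depth_um`, `aspect` (W/D), `modality`.
#' @export
measure_diameters <- function(mask, site, plane, skeleton, spacing = NULL,
                              modality = "lsfm",
                              width_mode = c("perp_axis", "max_inplane"),
                              min_axis_angle_deg = 15, step = 0.25) {
  width_mode <- match.arg(width_mode)
  if (inherits(mask, "vessel_mask")) { spacing <- mask$spacing; mask <- mask$mask }
  if (is.null(spacing)) lsfm_stop("spacing required with a bare mask array")
  arr <- mask * 1.0
  if (trilinear_sample(arr, spacing, rbind(site)) < 0.5)
    lsfm_stop("site is outside the vessel mask")
  nrm <- normalize3(plane$normal)
  axis <- local_vessel_axis(skeleton, site)
  axis_from_normal <- acos(pmin(1, abs(sum(axis * nrm)))) * 180 / pi
  if (axis_from_normal < min_axis_angle_deg)
    lsfm_stop("segment not measurable against this plane: vessel axis within 15 deg of the normal")
  depth <- mask_chord(arr, spacing, site, nrm, step = step)
  if (width_mode == "perp_axis") {
    wdir <- normalize3(cross3(nrm, axis))
    width <- mask_chord(arr, spacing, site, wdir, step = step)
  } else {
    u <- normalize3(cross3(nrm, axis))
    v <- cross3(nrm, u)
    width <- max(vapply(seq(0, 175, by = 5) * pi / 180, function(th)
      mask_chord(arr, spacing, site, cos(th) * u + sin(th) * v, step = step), numeric(1)))
  }
  if (width <= 0 || depth <= 0) lsfm_stop("degenerate chord at site")
  structure(data.frame(x_um = site[1], y_um = site[2], z_um = site[3],
                       width_um = width, depth_um = depth, aspect = width / depth,
                       modality = modality),
            class = c("diameter_measurement", "data.frame"))
}

#' Two-sample t-test tolerant of degenerate (zero-variance) groups
#' @noRd
safe_t_test <- function(x, y, var.equal = TRUE) {
  degenerate <- sd(x) == 0 && sd(y) == 0
  if (degenerate) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, df = length(x) + length(y) - 2, p.value = 1,
                  degenerate = TRUE))
    return(list(statistic = Inf, df = length(x) + length(y) - 2, p.value = 0,
                degenerate = TRUE))
  }
  tt <- t.test(x, y, var.equal = var.equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, degenerate = FALSE)
}

#' Compare LSFM and confocal diameter measurements (distortion report)
#'
#' Summarises the two groups (mean width, depth and aspect ratio) and runs
#' unpaired two-sample t-tests (Student and Welch) on depth and on the
#' aspect ratio, quantifying whether flat-mounted vessels are wider and
#' shallower than their in-toto counterparts.
#'
#' @param lsfm,confocal data frames of [measure_diameters()] rows (>= 2 each).
#' @return `distortion_report`: list with `groups` (summary data frame) and
#'   `tests` (statistic, df, two-sided p for each metric and variant).
#' @export
compare_distortion <- function(lsfm, confocal) {
  if (nrow(lsfm) < 2 || nrow(confocal) < 2)
    lsfm_stop("need at least 2 measurements per group")
  summarise <- function(df, label) data.frame(
    modality = label, n = nrow(df),
    mean_width_um = mean(df$width_um), mean_depth_um = mean(df$depth_um),
    mean_aspect = mean(df$aspect))
  groups <- rbind(summarise(lsfm, "lsfm"), summarise(confocal, "confocal"))
  tests <- list()
  for (metric in c("depth_um", "aspect")) {
    x <- lsfm[[metric]]; y <- confocal[[metric]]
    tests[[metric]] <- list(student = safe_t_test(x, y, var.equal = TRUE),
                            welch = safe_t_test(x, y, var.equal = FALSE))
  }
  structure(list(groups = groups, tests = tests), class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat("<distortion_report>\n")
  print(x$groups, row.names = FALSE)
  for (m in names(x$tests)) {
    s <- x$tests[[m]]$student
    cat(sprintf("  %s: Student t = %.3f, df = %.1f, p = %.3g%s\n", m,
                s$statistic, s$df, s$p.value,
                if (isTRUE(s$degenerate)) " (degenerate)" else ""))
  }
  invisible(x)
}
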