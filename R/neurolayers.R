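#' Region of interest delimiting a nuclear layer in one slice
#'
#' @param slice 1-based z-slice index.
#' @param polygon n x 2 matrix of `(x, y)` µm vertices of a simple polygon.
#' @return `layer_roi` with the polygon and its shoelace area (µm²).
#' @export
layer_roi <- function(slice, polygon) {
  polygon <- rbind(polygon)
  if (nrow(polygon) < 3) lsfm_stop("ROI polygon needs at least 3 vertices")
  x <- polygon[, 1]; y <- polygon[, 2]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (area <= 0) lsfm_stop("ROI polygon has zero area")
  structure(list(slice = as.integer(slice), polygon = polygon, area_um2 = area),
            class = "layer_roi")
}

#' Outer-nuclear-layer nuclei density by per-slice particle analysis
#'
#' For each ROI: threshold the nuclear channel inside the polygon on that
#' z-slice, count 2D connected particles at least `min_particle_um2` in
#' area, and divide by the polygon area. Slices are whatever the supplied
#' ROIs sample (the source procedure increments z by a fixed stride, ~50
#' slices, over ~8 areas per condition); the mean across ROIs is reported.
#'
#' @param volume an [lsfm_volume()] with the nuclear channel.
#' @param rois list of [layer_roi()]s.
#' @param channel channel name.
#' @param threshold `"otsu"` (per ROI) or numeric.
#' @param min_particle_um2 particle-size filter (µm² in-slice).
#' @param projection when `TRUE` (default) the nuclear channel is
#'   max-projected across z inside the ROI before particle analysis, so the
#'   count estimates the areal density of the whole layer; `FALSE` analyses
#'   the single ROI slice only (nuclei cut by that optical section).
#' @return `layer_measurement` list: `per_slice` data frame (slice, n
#'   particles, area, density per µm²) and `mean_density_per_um2`.
#' @export
onl_density <- function(volume, rois, channel = "nuclei", threshold = "otsu",
                        min_particle_um2 = 5, projection = TRUE) {
  arr3 <- vol_channel(volume, channel)
  sp <- volume$spacing
  rows <- list()
  for (roi in rois) {
    if (roi$slice < 1 || roi$slice > dim(arr3)[1]) {
      warning(sprintf("ROI slice %d outside the stack: skipped", roi$slice))
      next
    }
    sl <- if (projection) apply(arr3, c(2, 3), max) else arr3[roi$slice, , ] # (y, x)
    ny <- nrow(sl); nx <- ncol(sl)
    gx <- rep((seq_len(nx) - 1) * sp[3], each = ny)
    gy <- rep((seq_len(ny) - 1) * sp[2], times = nx)
    inside <- matrix(mgcv::in.out(rbind(roi$polygon, roi$polygon[1, ]),
                                  cbind(gx, gy)), ny, nx)
    vals <- sl[inside]
    if (length(vals) == 0) { warning("empty ROI: skipped"); next }
    th <- if (identical(threshold, "otsu")) {
      if (diff(range(vals)) <= 0) Inf else otsu_threshold(array(vals, dim = c(length(vals), 1, 1)))
    } else threshold
    bin <- sl > th & inside
    n_particles <- 0L
    if (any(bin)) {
      lab <- EBImage::bwlabel(bin * 1)
      sizes <- tabulate(lab[lab > 0])
      n_particles <- sum(sizes * sp[2] * sp[3] >= min_particle_um2)
    }
    rows[[length(rows) + 1]] <- data.frame(slice = roi$slice, n_particles = n_particles,
                                           area_um2 = roi$area_um2,
                                           density_per_um2 = n_particles / roi$area_um2)
  }
  if (!length(rows)) lsfm_stop("no usable ROIs")
  per_slice <- do.call(rbind, rows)
  structure(list(per_slice = per_slice,
                 mean_density_per_um2 = mean(per_slice$density_per_um2)),
            class = "layer_measurement")
}

#' Outer-nuclear-layer thickness from sampled line measurements
#'
#' Per sampled slice, measures the layer extent along z at `n_lines`
#' equally spaced lateral positions (sub-voxel 0.5-crossing of the layer
#' mask) and averages them; the overall mean across slices estimates the
#' layer thickness. Line lengths may also be supplied directly.
#'
#' @param layer_mask logical array `(z, y, x)` of the layer (e.g. a
#'   thresholded nuclear-density band), or `NULL` when `lines_um` is given.
#' @param spacing voxel spacing, µm.
#' @param stride sample every `stride`-th slice along x (the source
#'   procedure used 50).
#' @param n_lines lines per slice (default 3).
#' @param lines_um optional list of numeric vectors of manual line lengths
#'   per slice, bypassing the mask.
#' @return `layer_measurement` list with `per_slice` (slice, thickness µm)
#'   and `mean_thickness_um`.
#' @export
onl_thickness <- function(layer_mask = NULL, spacing = c(1, 1, 1), stride = 50,
                          n_lines = 3, lines_um = NULL) {
  if (!is.null(lines_um)) {
    per_slice <- data.frame(slice = seq_along(lines_um),
                            thickness_um = vapply(lines_um, mean, numeric(1)))
    return(structure(list(per_slice = per_slice,
                          mean_thickness_um = mean(per_slice$thickness_um)),
                     class = "layer_measurement"))
  }
  if (is.null(layer_mask)) lsfm_stop("either a layer mask or line lengths are required")
  d <- dim(layer_mask)
  slices <- seq(1, d[3], by = stride)
  if (length(slices) == 1 && d[3] > 1)
    warning("stride larger than the stack: single-slice estimate")
  rows <- list()
  for (ix in slices) {
    ys <- round(seq(1, d[2], length.out = n_lines + 2))[2:(n_lines + 1)]
    lens <- vapply(ys, function(iy) {
      prof <- layer_mask[, iy, ix]
      if (!any(prof)) return(NA_real_)
      zi <- which(prof)
      lo <- min(zi); hi <- max(zi)
      # half-voxel extension on each side (0.5-crossing of the binary profile)
      (hi - lo + 1) * spacing[1]
    }, numeric(1))
    lens <- lens[!is.na(lens)]
    if (!length(lens)) next
    rows[[length(rows) + 1]] <- data.frame(slice = ix, thickness_um = mean(lens))
  }
  if (!length(rows)) lsfm_stop("layer mask empty on all sampled slices")
  per_slice <- do.call(rbind, rows)
  structure(list(per_slice = per_slice,
                 mean_thickness_um = mean(per_slice$thickness_um)),
            class = "layer_measurement")
}

#' @export
print.layer_measurement <- function(x, ...) {
  if (!is.null(x$mean_density_per_um2))
    cat(sprintf("<layer_measurement> mean density %.4g nuclei/um2 over %d ROIs\n",
                x$mean_density_per_um2, nrow(x$per_slice)))
  else
    cat(sprintf("<layer_measurement> mean thickness %.2f um over %d slices\n",
                x$mean_thickness_um, nrow(x$per_slice)))
  invisible(x)
}
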