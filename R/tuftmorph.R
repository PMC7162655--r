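#' Detect neovascular tufts protruding above the plexus
#'
#' A tuft is a connected component (26-connectivity) of vessel voxels whose
#' signed height above the plexus reference exceeds `min_height_um`, kept if
#' its volume reaches `min_volume_um3`.
#'
#' @param mask a `vessel_mask` from [segment_vessels()] (or logical array
#'   plus `spacing`).
#' @param plexus an `lsfm_surface` or fitted `plexus_plane` reference.
#' @param min_height_um protrusion cutoff above the plexus mid-surface
#'   (default 10).
#' @param min_volume_um3 minimum component volume.
#' @param spacing required when `mask` is a bare array.
#' @return `tuft_set`: list with integer `labels` array (0 background),
#'   `records` data frame (tuft_id, n_voxels, volume_um3, centroid, max
#'   height), the `heights` array, and the parameters used.
#' @export
detect_tufts <- function(mask, plexus, min_height_um = 10, min_volume_um3 = 200,
                         spacing = NULL) {
  if (is.null(plexus)) lsfm_stop("no plexus model supplied")
  if (inherits(mask, "vessel_mask")) { spacing <- mask$spacing; mask <- mask$mask }
  if (is.null(spacing)) lsfm_stop("spacing required with a bare mask array")
  d <- dim(mask)
  co <- voxel_coords(d, spacing)
  h <- array(surface_height(plexus, cbind(as.numeric(co$X), as.numeric(co$Y),
                                          as.numeric(co$Z))), dim = d)
  above <- mask & h > min_height_um
  if (!any(above)) {
    return(structure(list(labels = array(0L, dim = d),
                          records = data.frame(tuft_id = integer(0), n_voxels = integer(0),
                                               volume_um3 = numeric(0), x_um = numeric(0),
                                               y_um = numeric(0), z_um = numeric(0),
                                               max_height_um = numeric(0)),
                          heights = h, plexus = plexus, spacing = spacing,
                          min_height_um = min_height_um),
                     class = "tuft_set"))
  }
  lab <- label_components(above, 26)
  ncomp <- attr(lab, "n_components")
  voxvol <- prod(spacing)
  sizes <- tabulate(lab[lab > 0], nbins = ncomp)
  keep <- which(sizes * voxvol >= min_volume_um3)
  out <- array(0L, dim = d)
  recs <- list()
  for (j in seq_along(keep)) {
    sel <- lab == keep[j]
    out[sel] <- j
    idx <- which(sel)
    pts <- mask_points_um(sel, spacing)
    recs[[j]] <- data.frame(tuft_id = j, n_voxels = length(idx),
                            volume_um3 = length(idx) * voxvol,
                            x_um = mean(pts[, 1]), y_um = mean(pts[, 2]),
                            z_um = mean(pts[, 3]),
                            max_height_um = max(h[idx]))
  }
  structure(list(labels = out,
                 records = if (length(recs)) do.call(rbind, recs) else
                   data.frame(tuft_id = integer(0)),
                 heights = h, plexus = plexus, spacing = spacing,
                 min_height_um = min_height_um),
            class = "tuft_set")
}

#' @export
print.tuft_set <- function(x, ...) {
  cat(sprintf("<tuft_set> %d tufts above %.0f um\n", nrow(x$records), x$min_height_um))
  if (nrow(x$records)) print(x$records, row.names = FALSE)
  invisible(x)
}

#' Tuft volume by voxel integration
#'
#' @param tufts a `tuft_set` (or integer label array).
#' @param tuft_id which label.
#' @param spacing voxel spacing when a bare array is given.
#' @return volume in µm³ (voxel count x voxel volume).
#' @export
tuft_volume <- function(tufts, tuft_id, spacing = NULL) {
  if (inherits(tufts, "tuft_set")) { spacing <- tufts$spacing; labels <- tufts$labels }
  else labels <- tufts
  if (is.null(spacing)) lsfm_stop("spacing required with a bare label array")
  n <- sum(labels == tuft_id)
  if (n == 0) lsfm_stop(sprintf("tuft label %d is empty", tuft_id))
  n * prod(spacing)
}

#' Depth of a tuft perpendicular to the plexus plane
#'
#' The tuft length oriented along the plexus normal: the maximum signed
#' height of the tuft's voxels above the plexus mid-surface.
#'
#' @inheritParams tuft_volume
#' @return depth, µm.
#' @export
tuft_depth <- function(tufts, tuft_id) {
  stopifnot(inherits(tufts, "tuft_set"))
  idx <- which(tufts$labels == tuft_id)
  if (length(idx) == 0) lsfm_stop(sprintf("tuft label %d is empty", tuft_id))
  max(tufts$heights[idx])
}

#' Tuft size class from the nuclear count
#'
#' Small tufts have fewer than 4 nuclei (the smallest observable has 2),
#' medium tufts 4 to 20, large tufts over 20.
#'
#' @param n_nuclei positive integer vector.
#' @return factor with levels small, medium, large.
#' @export
classify_tuft <- function(n_nuclei) {
  if (any(n_nuclei < 1)) lsfm_stop("n_nuclei must be >= 1")
  cls <- ifelse(n_nuclei < 4, "small", ifelse(n_nuclei <= 20, "medium", "large"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Count vessel connections between a tuft and the plexus
#'
#' Counts the distinct skeleton crossings of the iso-height surface
#' `h = min_height_um` that join the tuft's component to the network below:
#' adjacent skeleton-voxel pairs straddling the threshold whose upper voxel
#' is 26-connected (within the above-threshold skeleton) to the tuft label,
#' clustered so that one stalk yields one crossing.
#'
#' @param skeleton a [skeletonize_mask()] of the full vessel mask.
#' @param tufts a `tuft_set`.
#' @param tuft_id which tuft.
#' @param min_height_um crossing height (defaults to the tuft set's cutoff).
#' @param cluster_um crossings closer than this merge into one connection.
#' @return integer count (0 with a warning for a detached tuft).
#' @export
count_connections <- function(skeleton, tufts, tuft_id,
                              min_height_um = tufts$min_height_um,
                              cluster_um = 5) {
  stopifnot(inherits(tufts, "tuft_set"))
  pts <- skeleton$points
  h <- surface_height(tufts$plexus, pts)
  vox <- skeleton$voxels
  n <- nrow(pts)
  lab_at <- tufts$labels[vox]
  # adjacency among skeleton voxels (26)
  d <- skeleton$dim
  key <- array(0L, dim = d); key[vox] <- seq_len(n)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  pairs <- list()
  for (k in seq_len(nrow(offs))) {
    zz <- vox[, 1] + offs[k, 1]; yy <- vox[, 2] + offs[k, 2]; xx <- vox[, 3] + offs[k, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    nb <- rep(0L, n); nb[ok] <- key[cbind(zz[ok], yy[ok], xx[ok])]
    hit <- which(nb > 0 & seq_len(n) < nb)
    if (length(hit)) pairs[[length(pairs) + 1]] <- cbind(hit, nb[hit])
  }
  if (length(pairs) == 0) return(0L)
  pairs <- do.call(rbind, pairs)
  # connected components of the above-threshold skeleton subgraph
  above <- h > min_height_um
  sub <- pairs[above[pairs[, 1]] & above[pairs[, 2]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(sub, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  tuft_comps <- unique(comp[above & lab_at == tuft_id])
  if (length(tuft_comps) == 0) {
    warning("tuft has no skeleton voxels above the crossing height")
    return(0L)
  }
  straddle <- xor(above[pairs[, 1]], above[pairs[, 2]])
  upper <- ifelse(above[pairs[, 1]], pairs[, 1], pairs[, 2])
  cross_idx <- which(straddle & comp[upper] %in% tuft_comps)
  if (length(cross_idx) == 0) {
    warning(sprintf("tuft %d appears detached from the plexus (0 crossings)", tuft_id))
    return(0L)
  }
  mids <- (pts[pairs[cross_idx, 1], , drop = FALSE] + pts[pairs[cross_idx, 2], , drop = FALSE]) / 2
  if (nrow(mids) == 1) return(1L)
  cl <- stats::cutree(stats::hclust(stats::dist(mids), method = "single"), h = cluster_um)
  length(unique(cl))
}

#' Tuft tunnel count (first Betti number of the label mask)
#'
#' @param tufts a `tuft_set` or logical mask array.
#' @param tuft_id which label (ignored for a bare mask).
#' @param largest_component clean the mask to its largest 26-component first.
#' @return number of independent tunnels through the tuft.
#' @export
tuft_topology <- function(tufts, tuft_id = NULL, largest_component = TRUE) {
  mask <- if (inherits(tufts, "tuft_set")) tufts$labels == tuft_id else tufts
  if (!any(mask)) lsfm_stop("empty tuft mask")
  if (largest_component) {
    lab <- label_components(mask, 26)
    sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n_components"))
    mask <- array(lab == which.max(sizes), dim = dim(mask))
  }
  unname(betti_numbers(mask)["b1"])
}

# ---- nuclei ----------------------------------------------------------------

#' Detect nuclei in the nuclear channel, with principal-curve shape metrics
#'
#' Thresholds the channel (Otsu by default), optionally restricts to one
#' tuft's voxels, labels 26-connected blobs, splits touching blobs with a
#' marker-based watershed on the interior distance transform, and extracts a
#' principal curve per nucleus by medial-axis thinning. Arc length (curve
#' length), chord (end-to-end distance), their ratio and the maximum turning
#' angle along the curve feed the curvature classification.
#'
#' @param volume an [lsfm_volume()] with a nuclear channel.
#' @param channel channel name (default `"nuclei"`).
#' @param within optional logical array restricting detection (e.g. a tuft
#'   label, dilated by `within_dilate_um`).
#' @param within_dilate_um tolerance around `within` (µm).
#' @param threshold `"otsu"` or a numeric value.
#' @param min_volume_um3 discard blobs smaller than this.
#' @param split split touching blobs by watershed.
#' @return data frame of `NucleusRecord`s: centroid, volume, arc length,
#'   chord, `bend_ratio`, `max_turning_deg`, `degenerate` flag. Zero rows
#'   (with a warning) when the channel holds no nuclei.
#' @export
detect_nuclei <- function(volume, channel = "nuclei", within = NULL,
                          within_dilate_um = 2, threshold = "otsu",
                          min_volume_um3 = 10, split = TRUE) {
  arr <- vol_channel(volume, channel)
  sp <- volume$spacing
  offset_um <- c(0, 0, 0) # (x, y, z) of crop origin
  if (!is.null(within)) {
    # crop to the region of interest: all morphology then runs on a small box
    idx <- which(within, arr.ind = TRUE)
    if (nrow(idx) == 0) { warning("empty 'within' region"); return(nucleus_record_frame()) }
    pad <- ceiling(within_dilate_um / min(sp)) + 4
    d <- dim(arr)
    zr <- max(1, min(idx[, 1]) - pad):min(d[1], max(idx[, 1]) + pad)
    yr <- max(1, min(idx[, 2]) - pad):min(d[2], max(idx[, 2]) + pad)
    xr <- max(1, min(idx[, 3]) - pad):min(d[3], max(idx[, 3]) + pad)
    arr <- arr[zr, yr, xr, drop = FALSE]
    within <- within[zr, yr, xr, drop = FALSE]
    offset_um <- c((xr[1] - 1) * sp[3], (yr[1] - 1) * sp[2], (zr[1] - 1) * sp[1])
  }
  th <- if (identical(threshold, "otsu")) {
    if (diff(range(arr)) <= 0) NA_real_ else otsu_threshold(arr)
  } else threshold
  mask <- if (is.na(th)) array(FALSE, dim = dim(arr)) else arr > th
  if (!is.null(within)) {
    if (within_dilate_um > 0) {
      dt <- distance_transform(!within, sp)
      within <- within | (dt <= within_dilate_um)
    }
    mask <- mask & within
  }
  if (!any(mask)) {
    warning("no nuclei detected in channel")
    return(nucleus_record_frame())
  }
  lab <- label_components(mask, 26)
  ncomp <- attr(lab, "n_components")
  voxvol <- prod(sp)
  recs <- list()
  nid <- 0
  for (j in seq_len(ncomp)) {
    comp <- lab == j
    if (sum(comp) * voxvol < min_volume_um3) next
    parts <- if (split) split_touching_blobs(comp, sp, intensity = arr) else list(comp)
    for (p in parts) {
      nid <- nid + 1
      recs[[nid]] <- nucleus_shape_metrics(p, sp, nid)
    }
  }
  if (nid == 0) {
    warning("no nuclei detected above the size filter")
    return(nucleus_record_frame())
  }
  out <- do.call(rbind, recs)
  out$x_um <- out$x_um + offset_um[1]
  out$y_um <- out$y_um + offset_um[2]
  out$z_um <- out$z_um + offset_um[3]
  out
}

#' @noRd
nucleus_record_frame <- function() {
  data.frame(nucleus_id = integer(0), x_um = numeric(0), y_um = numeric(0),
             z_um = numeric(0), volume_um3 = numeric(0), arc_length_um = numeric(0),
             chord_um = numeric(0), bend_ratio = numeric(0),
             max_turning_deg = numeric(0), degenerate = logical(0))
}

#' Marker-based watershed split of touching blobs
#'
#' Markers are the connected plateaus of the interior distance transform
#' within 1 µm of the component maximum; voxels are assigned to the nearest
#' marker by geodesic flooding inside the component.
#' @noRd
split_touching_blobs <- function(comp, spacing, intensity = NULL) {
  # height function: rendered intensity when available (touching nuclei show
  # a dim valley at the contact, a single bent nucleus stays bright along
  # its body); interior distance for binary phantoms
  hmap <- if (!is.null(intensity) && diff(range(intensity[comp])) > 0.05) {
    h <- intensity
    h[!comp] <- 0
    h
  } else distance_transform(comp, spacing)
  mx <- max(hmap[comp])
  seed_mask <- comp & hmap >= 0.9 * mx
  seeds <- label_components(seed_mask, 26)
  nseed <- attr(seeds, "n_components")
  if (nseed <= 1) return(list(comp))
  lab <- geodesic_flood(comp, seeds, spacing)
  # keep a split only when the interface between two parts is a genuine
  # valley, not a shallow dip along a uniform ridge
  merged <- TRUE
  while (merged && length(unique(lab[lab > 0])) > 1) {
    merged <- FALSE
    ids <- sort(unique(lab[lab > 0]))
    peaks <- vapply(ids, function(k) max(hmap[lab == k]), numeric(1))
    for (a_i in seq_along(ids)) {
      for (b_i in seq_along(ids)) {
        if (b_i <= a_i) next
        a <- ids[a_i]; b <- ids[b_i]
        inter <- (lab == a) & dilate_mask_1(lab == b)
        if (!any(inter)) next
        if (max(hmap[inter]) >= 0.8 * min(peaks[c(a_i, b_i)])) {
          lab[lab == b] <- a
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) <= 1) return(list(comp))
  lapply(ids, function(k) array(lab == k, dim = dim(comp)))
}

#' One-voxel 26-dilation of a small logical array
#' @noRd
dilate_mask_1 <- function(m) {
  d <- dim(m)
  out <- m
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    zs <- max(1, 1 + dz):min(d[1], d[1] + dz)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    xs <- max(1, 1 + dx):min(d[3], d[3] + dx)
    out[zs - dz, ys - dy, xs - dx] <- out[zs - dz, ys - dy, xs - dx] | m[zs, ys, xs]
  }
  out
}

#' Multi-source BFS flooding of a mask from labelled seeds
#' @noRd
geodesic_flood <- function(comp, seeds, spacing) {
  d <- dim(comp)
  lab <- array(0L, dim = d)
  lab[seeds > 0] <- seeds[seeds > 0]
  frontier <- which(lab > 0)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ar <- arrayInd(frontier, d)
  while (length(frontier)) {
    nxt <- integer(0); nxt_lab <- integer(0)
    for (k in seq_len(nrow(offs))) {
      zz <- ar[, 1] + offs[k, 1]; yy <- ar[, 2] + offs[k, 2]; xx <- ar[, 3] + offs[k, 3]
      ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
      if (!any(ok)) next
      j <- cbind(zz[ok], yy[ok], xx[ok])
      ji <- j[, 1] + d[1] * (j[, 2] - 1) + d[1] * d[2] * (j[, 3] - 1)
      new <- comp[ji] & lab[ji] == 0L
      if (any(new)) {
        nxt <- c(nxt, ji[new]); nxt_lab <- c(nxt_lab, lab[frontier[ok]][new])
      }
    }
    if (!length(nxt)) break
    first <- !duplicated(nxt)
    lab[nxt[first]] <- nxt_lab[first]
    frontier <- unique(nxt[first])
    ar <- arrayInd(frontier, d)
  }
  lab
}

#' Shape metrics of one nucleus blob via its medial principal curve
#' @noRd
nucleus_shape_metrics <- function(blob, spacing, nid) {
  voxvol <- prod(spacing)
  pts <- mask_points_um(blob, spacing)
  ctr <- colMeans(pts)
  vol <- nrow(pts) * voxvol
  skel <- .thin_3d(as.logical(blob), as.integer(dim(blob)))
  sk_pts <- mask_points_um(skel, spacing)
  if (nrow(sk_pts) < 3) {
    return(data.frame(nucleus_id = nid, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
                      volume_um3 = vol, arc_length_um = 0, chord_um = 0,
                      bend_ratio = 1, max_turning_deg = 0, degenerate = TRUE))
  }
  path <- longest_skeleton_path(skel, spacing)
  # smooth the voxel staircase before measuring: resample densely, then a
  # short moving average, so straight-but-tilted capsules read as straight
  path <- smooth_polyline(resample_polyline(path, 1), window = 3)
  arc <- sum(sqrt(rowSums(diff(path)^2)))
  chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  if (arc < 2 * max(spacing) || chord == 0) {
    return(data.frame(nucleus_id = nid, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
                      volume_um3 = vol, arc_length_um = arc, chord_um = chord,
                      bend_ratio = 1, max_turning_deg = 0, degenerate = TRUE))
  }
  # turning = angle between the mean tangent of the first and last thirds
  # of the curve: robust both to staircase noise (which inflates per-step
  # turns) and to end erosion of the medial axis (which shrinks arc/chord)
  turning <- 0
  if (nrow(path) >= 3) {
    v <- diff(path)
    keep <- rowSums(v^2) > 0
    v <- v[keep, , drop = FALSE]
    v <- v / sqrt(rowSums(v^2))
    if (nrow(v) >= 2) {
      k <- max(1, floor(nrow(v) / 3))
      t1 <- colMeans(v[seq_len(k), , drop = FALSE])
      t2 <- colMeans(v[(nrow(v) - k + 1):nrow(v), , drop = FALSE])
      t1 <- t1 / sqrt(sum(t1^2)); t2 <- t2 / sqrt(sum(t2^2))
      turning <- acos(pmin(1, pmax(-1, sum(t1 * t2)))) * 180 / pi
    }
  }
  data.frame(nucleus_id = nid, x_um = ctr[1], y_um = ctr[2], z_um = ctr[3],
             volume_um3 = vol, arc_length_um = arc, chord_um = chord,
             bend_ratio = max(1, arc / chord), max_turning_deg = turning,
             degenerate = FALSE)
}

#' Longest geodesic path through a skeleton (double BFS), as a polyline
#' @noRd
longest_skeleton_path <- function(skel, spacing) {
  g <- skeleton_to_graph(skel, spacing)
  pts <- g$points
  n <- nrow(pts)
  d <- g$dim
  key <- array(0L, dim = d); key[g$voxels] <- seq_len(n)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  el <- list()
  for (k in seq_len(nrow(offs))) {
    zz <- g$voxels[, 1] + offs[k, 1]; yy <- g$voxels[, 2] + offs[k, 2]; xx <- g$voxels[, 3] + offs[k, 3]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    nb <- rep(0L, n); nb[ok] <- key[cbind(zz[ok], yy[ok], xx[ok])]
    hit <- which(nb > 0 & seq_len(n) < nb)
    if (length(hit)) {
      w <- sqrt(rowSums((pts[hit, , drop = FALSE] - pts[nb[hit], , drop = FALSE])^2))
      el[[length(el) + 1]] <- cbind(hit, nb[hit], w)
    }
  }
  if (!length(el)) return(pts[1, , drop = FALSE])
  el <- do.call(rbind, el)
  gg <- igraph::graph_from_edgelist(el[, 1:2, drop = FALSE], directed = FALSE)
  if (igraph::vcount(gg) < n) gg <- igraph::add_vertices(gg, n - igraph::vcount(gg))
  igraph::E(gg)$weight <- el[, 3]
  d1 <- igraph::distances(gg, v = 1)
  a <- which.max(ifelse(is.finite(d1), d1, -1))
  da <- igraph::distances(gg, v = a)
  b <- which.max(ifelse(is.finite(da), da, -1))
  path <- igraph::shortest_paths(gg, from = a, to = b)$vpath[[1]]
  pts[as.integer(path), , drop = FALSE]
}

#' @noRd
smooth_polyline <- function(path, window = 3) {
  n <- nrow(path)
  if (n <= window) return(path)
  half <- window %/% 2
  sm <- path
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    sm[i, ] <- colMeans(path[j, , drop = FALSE])
  }
  sm
}

#' @noRd
resample_polyline <- function(path, step) {
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= step) return(path[c(1, nrow(path)), , drop = FALSE])
  ts <- seq(0, total, by = step)
  if (ts[length(ts)] < total) ts <- c(ts, total)
  t(vapply(ts, function(t0) {
    i <- findInterval(t0, s, rightmost.closed = TRUE)
    i <- min(i, nrow(path) - 1)
    w <- if (seg[i] == 0) 0 else (t0 - s[i]) / seg[i]
    path[i, ] * (1 - w) + path[i + 1, ] * w
  }, numeric(3)))
}

#' Classify a nucleus as curved or flat
#'
#' A nucleus counts as curved when its principal-curve bend ratio
#' (arc/chord) exceeds `bend_threshold` or its maximum turning angle exceeds
#' `angle_threshold_deg`. Degenerate (sub-resolution) nuclei are flat.
#'
#' @param records data frame from [detect_nuclei()].
#' @param bend_threshold default 1.2.
#' @param angle_threshold_deg default 60.
#' @return logical vector (`TRUE` = curved).
#' @export
classify_nucleus_curvature <- function(records, bend_threshold = 1.2,
                                       angle_threshold_deg = 60) {
  !records$degenerate &
    (records$bend_ratio > bend_threshold | records$max_turning_deg > angle_threshold_deg)
}

# ---- regressions and polarity ---------------------------------------------

#' Ordinary least squares between two tuft morphometrics
#'
#' @param records data frame with the tuft table (>= 3 rows).
#' @param x,y column names.
#' @return `RegressionResult` list: slope, intercept, `r_squared`, n.
#' @export
regress_morphometrics <- function(records, x, y) {
  if (nrow(records) < 3) lsfm_stop("need at least 3 records for a regression")
  fit <- lm(records[[y]] ~ records[[x]])
  yv <- records[[y]]
  ss_tot <- sum((yv - mean(yv))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = nrow(records))
}

#' Fold change of a morphometric across the large-tuft boundary
#'
#' Ratio of the mean of `field` in large tufts (more nuclei than `boundary`)
#' to its mean in medium tufts (4 to `boundary` nuclei), the sharp
#' transition signature at the 20-nucleus boundary.
#'
#' @param records tuft table with `n_nuclei` and `field` columns.
#' @param field column to compare.
#' @param boundary nuclei boundary (default 20).
#' @return fold change (numeric).
#' @export
class_fold_change <- function(records, field, boundary = 20) {
  large <- records[[field]][records$n_nuclei > boundary]
  medium <- records[[field]][records$n_nuclei >= 4 & records$n_nuclei <= boundary]
  if (length(large) == 0) lsfm_stop("no tufts above the boundary")
  if (length(medium) == 0) lsfm_stop("no medium tufts at or below the boundary")
  mean(large) / mean(medium)
}

#' Nucleus-Golgi polarity vectors
#'
#' Pairs every nucleus with its nearest Golgi body (Euclidean distance; a
#' Golgi body may serve several nuclei) and reports the unit polarity vector
#' and its angle against a reference direction (e.g. the flow direction).
#'
#' @param nuclei n x 3 matrix of nucleus centroids (µm).
#' @param golgi m x 3 matrix of Golgi centroids (µm).
#' @param reference reference direction (need not be unit length).
#' @return data frame: nucleus/golgi coordinates, pairing distance, unit
#'   vector components, `angle_deg` in `[0, 180]`.
#' @export
nucleus_golgi_polarity <- function(nuclei, golgi, reference) {
  nuclei <- rbind(nuclei); golgi <- rbind(golgi)
  if (nrow(nuclei) < 1 || nrow(golgi) < 1) lsfm_stop("need at least one nucleus and one golgi")
  ref <- normalize3(as.numeric(reference))
  out <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    dd <- sqrt(rowSums((golgi - matrix(nuclei[i, ], nrow(golgi), 3, byrow = TRUE))^2))
    j <- which.min(dd)
    v <- golgi[j, ] - nuclei[i, ]
    nv <- sqrt(sum(v^2))
    u <- if (nv == 0) c(NA_real_, NA_real_, NA_real_) else v / nv
    ang <- if (nv == 0) NA_real_ else acos(pmin(1, pmax(-1, sum(u * ref)))) * 180 / pi
    out[[i]] <- data.frame(nucleus_id = i, golgi_id = j,
                           nx_um = nuclei[i, 1], ny_um = nuclei[i, 2], nz_um = nuclei[i, 3],
                           gx_um = golgi[j, 1], gy_um = golgi[j, 2], gz_um = golgi[j, 3],
                           distance_um = nv, ux = u[1], uy = u[2], uz = u[3],
                           angle_deg = ang)
  }
  do.call(rbind, out)
}
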