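#' Multi-channel voxel volume
#'
#' Container for LSFM-like image data. Channels are numeric arrays with
#' `dim = c(nz, ny, nx)` (one time point) or `c(nt, nz, ny, nx)` (time lapse),
#' all sharing one physical voxel spacing in micrometres. Voxel indices are
#' 0-based in physical terms: the centre of voxel `[iz, iy, ix]` (1-based R
#' indices) sits at `((ix - 1) sx, (iy - 1) sy, (iz - 1) sz)` µm, and all
#' user-facing point coordinates are `(x, y, z)` µm.
#'
#' @param channels named list of numeric arrays (3D `z,y,x` or 4D `t,z,y,x`).
#' @param spacing numeric length-3 voxel spacing `(z, y, x)` in µm, all > 0.
#' @param dt_min frame interval in minutes for 4D data (`NA` for static).
#' @return an object of class `lsfm_volume`.
#' @export
lsfm_volume <- function(channels, spacing = c(1, 1, 1), dt_min = NA_real_) {
  if (!is.list(channels) || length(channels) == 0 || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    lsfm_stop("channels must be a non-empty named list of arrays")
  nd <- vapply(channels, function(a) length(dim(a)), integer(1))
  if (any(!nd %in% c(3L, 4L)))
    lsfm_stop("channel arrays must be 3D (z,y,x) or 4D (t,z,y,x); got a lower-dimensional array (not a volume)")
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1)
    lsfm_stop("all channels must share the same dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    lsfm_stop("spacing must be 3 positive numbers (z, y, x) in um")
  structure(list(channels = channels, spacing = setNames(spacing, c("z", "y", "x")),
                 dt_min = dt_min),
            class = "lsfm_volume")
}

#' @export
print.lsfm_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  kind <- if (length(d) == 4) sprintf("4D (%d frames)", d[1]) else "3D"
  cat(sprintf("<lsfm_volume> %s, %s voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              kind, paste(utils::tail(d, 3), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel array (optionally one frame of a time lapse)
#' @param vol an `lsfm_volume`.
#' @param channel channel name.
#' @param frame frame index for 4D data (1-based).
#' @return numeric 3D array `(z, y, x)`.
#' @export
vol_channel <- function(vol, channel, frame = NULL) {
  if (!channel %in% names(vol$channels))
    lsfm_stop(sprintf("no channel '%s' (have: %s)", channel,
                      paste(names(vol$channels), collapse = ", ")))
  a <- vol$channels[[channel]]
  if (length(dim(a)) == 4) {
    if (is.null(frame)) lsfm_stop("4D channel: a frame index is required")
    a <- array(a[frame, , , ], dim = dim(a)[-1])
  }
  a
}

vol_dim <- function(vol) utils::tail(dim(vol$channels[[1]]), 3)

#' Physical coordinate grids for a volume
#'
#' Returns arrays `X`, `Y`, `Z` of the same shape as a channel giving each
#' voxel centre's physical coordinate in µm.
#' @noRd
voxel_coords <- function(dimzyx, spacing) {
  nz <- dimzyx[1]; ny <- dimzyx[2]; nx <- dimzyx[3]
  z <- (seq_len(nz) - 1) * spacing[1]
  y <- (seq_len(ny) - 1) * spacing[2]
  x <- (seq_len(nx) - 1) * spacing[3]
  list(Z = array(rep(z, times = ny * nx), dim = dimzyx),
       Y = array(rep(rep(y, each = nz), times = nx), dim = dimzyx),
       X = array(rep(x, each = nz * ny), dim = dimzyx))
}

#' Voxel-centre coordinates (x,y,z µm) of TRUE voxels in a mask
#' @noRd
mask_points_um <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE) # iz, iy, ix
  cbind(x = (idx[, 3] - 1) * spacing[3],
        y = (idx[, 2] - 1) * spacing[2],
        z = (idx[, 1] - 1) * spacing[1])
}

#' Trilinear interpolation of a 3D array at physical points
#'
#' Out-of-bounds points evaluate to `outside`.
#' @noRd
trilinear_sample <- function(arr, spacing, pts, outside = 0) {
  d <- dim(arr)
  # continuous voxel index (1-based)
  fz <- pts[, 3] / spacing[1] + 1
  fy <- pts[, 2] / spacing[2] + 1
  fx <- pts[, 1] / spacing[3] + 1
  z0 <- floor(fz); y0 <- floor(fy); x0 <- floor(fx)
  wz <- fz - z0; wy <- fy - y0; wx <- fx - x0
  val <- rep(outside, nrow(pts))
  ok <- z0 >= 1 & y0 >= 1 & x0 >= 1 & z0 <= d[1] - 1 & y0 <= d[2] - 1 & x0 <= d[3] - 1
  # clamp exact upper-boundary points into the last cell
  hi <- fz <= d[1] & fy <= d[2] & fx <= d[3] & (z0 == d[1] | y0 == d[2] | x0 == d[3]) &
    z0 >= 1 & y0 >= 1 & x0 >= 1
  if (any(hi)) {
    z0[hi] <- pmin(z0[hi], d[1] - 1); y0[hi] <- pmin(y0[hi], d[2] - 1); x0[hi] <- pmin(x0[hi], d[3] - 1)
    wz[hi] <- fz[hi] - z0[hi]; wy[hi] <- fy[hi] - y0[hi]; wx[hi] <- fx[hi] - x0[hi]
    ok <- ok | hi
  }
  if (any(ok)) {
    iz <- z0[ok]; iy <- y0[ok]; ix <- x0[ok]
    az <- wz[ok]; ay <- wy[ok]; ax <- wx[ok]
    at <- function(dz, dy, dx) arr[cbind(iz + dz, iy + dy, ix + dx)]
    val[ok] <-
      at(0, 0, 0) * (1 - az) * (1 - ay) * (1 - ax) +
      at(1, 0, 0) * az * (1 - ay) * (1 - ax) +
      at(0, 1, 0) * (1 - az) * ay * (1 - ax) +
      at(0, 0, 1) * (1 - az) * (1 - ay) * ax +
      at(1, 1, 0) * az * ay * (1 - ax) +
      at(1, 0, 1) * az * (1 - ay) * ax +
      at(0, 1, 1) * (1 - az) * ay * ax +
      at(1, 1, 1) * az * ay * ax
  }
  val
}

#' Separable Gaussian blur of a 3D array, sigma in µm per axis
#' @noRd
gaussian_blur_3d <- function(arr, sigma_um, spacing) {
  sigma_um <- rep_len(sigma_um, 3)
  d <- dim(arr)
  blur_axis <- function(a, axis) {
    s <- sigma_um[axis] / spacing[axis]
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2)); k <- k / sum(k)
    n <- d[axis]
    # band matrix with renormalised truncated rows (replicate-free edge handling)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      keep <- j >= 1 & j <= n
      K[i, j[keep]] <- k[keep] / sum(k[keep])
    }
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(arr, perm)
    m <- matrix(ap, nrow = d[axis])
    ap <- array(K %*% m, dim = d[perm])
    aperm(ap, order(perm))
  }
  arr <- blur_axis(arr, 1); arr <- blur_axis(arr, 2); arr <- blur_axis(arr, 3)
  arr
}

#' Otsu threshold of a numeric array (values scaled into [0,1] internally)
#' @noRd
otsu_threshold <- function(arr) {
  rng <- range(arr, finite = TRUE)
  if (diff(rng) <= 0) lsfm_stop("cannot threshold a constant image")
  m <- matrix((arr - rng[1]) / diff(rng), nrow = dim(arr)[1])
  th <- EBImage::otsu(m, range = c(0, 1))
  th * diff(rng) + rng[1]
}

# ---- reference surfaces ----------------------------------------------------

#' Reference surface models for the superficial plexus
#'
#' Two parametric models of the retinal surface carrying the superficial
#' vascular plexus: a flat plane at height `z0`, and a spherical cap (mouse-eye
#' scale curvature) whose apex sits at `apex_z` above the lateral centre
#' `centre_xy`. Signed height is measured along the outward surface normal
#' (towards the vitreous, i.e. increasing z at the apex).
#'
#' @param z0 plane height, µm.
#' @param centre_xy lateral position `(x, y)` of the cap apex, µm.
#' @param radius_um sphere radius, µm (default 1700, mouse-eye scale).
#' @param apex_z apex height, µm.
#' @return a surface model object of class `lsfm_surface`.
#' @export
surface_plane <- function(z0) {
  structure(list(type = "plane", z0 = z0), class = "lsfm_surface")
}

#' @rdname surface_plane
#' @export
surface_cap <- function(centre_xy, radius_um = 1700, apex_z = 0) {
  structure(list(type = "spherical_cap",
                 centre = c(centre_xy[1], centre_xy[2], apex_z - radius_um),
                 radius = radius_um),
            class = "lsfm_surface")
}

#' Signed height of points above a reference surface
#' @param surface an `lsfm_surface` (or fitted plexus plane, see
#'   [fit_plexus_plane()]).
#' @param pts n x 3 matrix of `(x, y, z)` µm points.
#' @return numeric vector of signed heights, µm (positive towards vitreous).
#' @export
surface_height <- function(surface, pts) {
  pts <- rbind(pts)
  if (inherits(surface, "plexus_plane"))
    return(as.numeric((pts - matrix(surface$anchor, nrow(pts), 3, byrow = TRUE)) %*% surface$normal))
  switch(surface$type,
         plane = pts[, 3] - surface$z0,
         spherical_cap = sqrt(rowSums((pts - matrix(surface$centre, nrow(pts), 3, byrow = TRUE))^2)) - surface$radius,
         lsfm_stop("unknown surface type"))
}

#' Surface z-elevation at lateral positions
#' @noRd
surface_elevation <- function(surface, x, y) {
  if (inherits(surface, "plexus_plane")) {
    n <- surface$normal; a <- surface$anchor
    if (abs(n[3]) < 1e-8) lsfm_stop("plane is vertical; no single elevation")
    return(a[3] - ((x - a[1]) * n[1] + (y - a[2]) * n[2]) / n[3])
  }
  switch(surface$type,
         plane = rep(surface$z0, length(x)),
         spherical_cap = {
           c0 <- surface$centre; r2 <- surface$radius^2
           d2 <- (x - c0[1])^2 + (y - c0[2])^2
           if (any(d2 > r2)) lsfm_stop("lateral position outside the spherical cap")
           c0[3] + sqrt(r2 - d2)
         },
         lsfm_stop("unknown surface type"))
}

#' Unit outward normal of the surface at points
#' @noRd
surface_normal_at <- function(surface, pts) {
  pts <- rbind(pts)
  if (inherits(surface, "plexus_plane"))
    return(matrix(surface$normal, nrow(pts), 3, byrow = TRUE))
  switch(surface$type,
         plane = matrix(c(0, 0, 1), nrow(pts), 3, byrow = TRUE),
         spherical_cap = {
           v <- pts - matrix(surface$centre, nrow(pts), 3, byrow = TRUE)
           v / sqrt(rowSums(v^2))
         },
         lsfm_stop("unknown surface type"))
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) lsfm_stop("zero vector cannot be normalised")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
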