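#' Scene specification for synthetic LSFM volumes
#'
#' Describes a synthetic retina scene: a reference surface (flat or
#' spherical-cap, emulating the natural curvature of the dissected eye cup),
#' tubular vessels lying on the surface, optional protruding neovascular
#' tufts, and an imaging noise model (Gaussian PSF-like blur plus additive
#' Gaussian noise on a constant background). All geometry is in µm.
#'
#' @param seed integer; drives every stochastic draw of the generators.
#' @param volume_shape voxels per axis `(z, y, x)`.
#' @param spacing µm per axis `(z, y, x)`, all > 0.
#' @param surface an [surface_plane()] or [surface_cap()] model.
#' @param vessels list of vessels, each `list(points = n x 3 (x,y,z µm)
#'   centreline control points, radius = µm > 0)`.
#' @param tufts list of [tuft_spec()] objects.
#' @param noise list: `background` level, additive Gaussian `sigma`, and
#'   `blur_um` PSF-like Gaussian sigma per axis (z,y,x; >= 0).
#' @return `scene_spec` object.
#' @export
scene_spec <- function(seed, volume_shape = c(48, 96, 96), spacing = c(1, 1, 1),
                       surface = surface_plane(z0 = 12),
                       vessels = list(), tufts = list(),
                       noise = list(background = 0.05, sigma = 0.02,
                                    blur_um = c(0.8, 0.8, 0.8))) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) lsfm_stop("spacing must be > 0 per axis")
  if (any(rep_len(noise$blur_um, 3) < 0)) lsfm_stop("blur sigma must be >= 0")
  for (v in vessels) {
    if (is.null(v$radius) || v$radius <= 0) lsfm_stop("all vessel radii must be > 0")
    if (is.null(v$points)) lsfm_stop("each vessel needs centreline control points")
  }
  for (tf in tufts) if (!inherits(tf, "tuft_spec")) lsfm_stop("tufts must be tuft_spec objects")
  structure(list(seed = as.integer(seed), volume_shape = as.integer(volume_shape),
                 spacing = spacing, surface = surface, vessels = vessels,
                 tufts = tufts, noise = noise),
            class = "scene_spec")
}

#' Specification of one synthetic neovascular tuft
#'
#' @param anchor_xy lateral `(x, y)` µm position on the surface.
#' @param n_nuclei number of endothelial nuclei (>= 1).
#' @param n_connections number of stalk vessels to the plexus (>= 1).
#' @param n_tunnels first Betti number of the tuft body: 0 = ball-like,
#'   1 = torus-like, 2 = figure-eight (two fused tori). Larger values are
#'   unsupported.
#' @param curved_nuclei_fraction fraction of nuclei rendered as bent capsules
#'   in `[0, 1]`.
#' @param target_volume_um3 approximate tuft body volume, µm³.
#' @param protrusion_height_um height of the tuft top above the plexus
#'   surface, µm.
#' @param ring_factor ring-to-tube radius ratio for torus-shaped tufts
#'   (default 2; larger values spread the ring to host more nuclei).
#' @return `tuft_spec` object.
#' @export
tuft_spec <- function(anchor_xy, n_nuclei, n_connections = 1, n_tunnels = 0,
                      curved_nuclei_fraction = 0, target_volume_um3 = 8000,
                      protrusion_height_um = 35, ring_factor = 2) {
  if (n_nuclei < 1) lsfm_stop("n_nuclei must be >= 1")
  if (n_connections < 1) lsfm_stop("n_connections must be >= 1")
  if (n_tunnels < 0 || n_tunnels > 2) lsfm_stop("n_tunnels must be 0, 1 or 2 (more is unsupported)")
  if (curved_nuclei_fraction < 0 || curved_nuclei_fraction > 1)
    lsfm_stop("curved_nuclei_fraction must be in [0, 1]")
  structure(list(anchor_xy = as.numeric(anchor_xy), n_nuclei = as.integer(n_nuclei),
                 n_connections = as.integer(n_connections), n_tunnels = as.integer(n_tunnels),
                 curved_nuclei_fraction = curved_nuclei_fraction,
                 target_volume_um3 = target_volume_um3,
                 protrusion_height_um = protrusion_height_um,
                 ring_factor = ring_factor),
            class = "tuft_spec")
}

# ---- rasterization ---------------------------------------------------------

#' Rasterize a tube around a polyline into a logical array
#' @noRd
raster_tube <- function(mask, spacing, pts, radius) {
  d <- dim(mask)
  pts <- rbind(pts)
  segs <- if (nrow(pts) == 1) list(rbind(pts[1, ], pts[1, ])) else
    lapply(seq_len(nrow(pts) - 1), function(i) pts[i:(i + 1), , drop = FALSE])
  for (s in segs) {
    a <- s[1, ]; b <- s[2, ]
    lo <- pmin(a, b) - radius - spacing[c(3, 2, 1)]
    hi <- pmax(a, b) + radius + spacing[c(3, 2, 1)]
    iz <- max(1, floor(lo[3] / spacing[1]) + 1):min(d[1], ceiling(hi[3] / spacing[1]) + 1)
    iy <- max(1, floor(lo[2] / spacing[2]) + 1):min(d[2], ceiling(hi[2] / spacing[2]) + 1)
    ix <- max(1, floor(lo[1] / spacing[3]) + 1):min(d[3], ceiling(hi[1] / spacing[3]) + 1)
    if (lo[3] > (d[1] - 1) * spacing[1] || hi[3] < 0 ||
        lo[2] > (d[2] - 1) * spacing[2] || hi[2] < 0 ||
        lo[1] > (d[3] - 1) * spacing[3] || hi[1] < 0) next
    g <- expand.grid(z = (iz - 1) * spacing[1], y = (iy - 1) * spacing[2],
                     x = (ix - 1) * spacing[3])
    ab <- b - a
    len2 <- sum(ab^2)
    px <- g$x - a[1]; py <- g$y - a[2]; pz <- g$z - a[3]
    tt <- if (len2 == 0) rep(0, nrow(g)) else
      pmin(1, pmax(0, (px * ab[1] + py * ab[2] + pz * ab[3]) / len2))
    dx <- px - tt * ab[1]; dy <- py - tt * ab[2]; dz <- pz - tt * ab[3]
    inside <- dx^2 + dy^2 + dz^2 <= radius^2
    if (any(inside)) {
      sub <- array(mask[iz, iy, ix], dim = c(length(iz), length(iy), length(ix)))
      sub[inside] <- TRUE
      mask[iz, iy, ix] <- sub
    }
  }
  mask
}

#' Rasterize a solid torus (ring in a tilted plane) into a logical array
#'
#' Core circle of radius `ring_r` centred at `centre`, lying in the plane
#' with unit normal `axis`; tube radius `tube_r`.
#' @noRd
raster_torus <- function(mask, spacing, centre, axis, ring_r, tube_r) {
  n <- max(24, ceiling(2 * pi * ring_r / (tube_r / 2)))
  axis <- normalize3(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize3(cross3(axis, ref)); e2 <- cross3(axis, e1)
  th <- seq(0, 2 * pi, length.out = n + 1)
  pts <- t(vapply(th, function(t) centre + ring_r * (cos(t) * e1 + sin(t) * e2), numeric(3)))
  raster_tube(mask, spacing, pts, tube_r)
}

#' Rasterize a flat solid cylinder (disc) of given radius and height
#' @noRd
raster_cylinder <- function(mask, spacing, centre, axis, radius, height) {
  d <- dim(mask)
  axis <- normalize3(axis)
  ext <- radius + height / 2 + 1
  lo <- centre - ext; hi <- centre + ext
  iz <- max(1, floor(lo[3] / spacing[1]) + 1):min(d[1], ceiling(hi[3] / spacing[1]) + 1)
  iy <- max(1, floor(lo[2] / spacing[2]) + 1):min(d[2], ceiling(hi[2] / spacing[2]) + 1)
  ix <- max(1, floor(lo[1] / spacing[3]) + 1):min(d[3], ceiling(hi[1] / spacing[3]) + 1)
  g <- expand.grid(z = (iz - 1) * spacing[1], y = (iy - 1) * spacing[2],
                   x = (ix - 1) * spacing[3])
  px <- g$x - centre[1]; py <- g$y - centre[2]; pz <- g$z - centre[3]
  ax <- px * axis[1] + py * axis[2] + pz * axis[3]
  lat2 <- px^2 + py^2 + pz^2 - ax^2
  inside <- abs(ax) <= height / 2 & lat2 <= radius^2
  if (any(inside)) {
    sub <- array(mask[iz, iy, ix], dim = c(length(iz), length(iy), length(ix)))
    sub[inside] <- TRUE
    mask[iz, iy, ix] <- sub
  }
  mask
}

#' Rasterize a (possibly bent) capsule nucleus; returns the polyline used
#' @noRd
nucleus_polyline <- function(centre, direction, bend_normal, length_um, bend_deg) {
  direction <- normalize3(direction)
  if (bend_deg <= 1) {
    half <- direction * length_um / 2
    return(rbind(centre - half, centre, centre + half))
  }
  theta <- bend_deg * pi / 180
  rho <- length_um / theta
  e2 <- normalize3(bend_normal - sum(bend_normal * direction) * direction)
  phi <- seq(-theta / 2, theta / 2, length.out = 9)
  t(vapply(phi, function(p) centre + rho * sin(p) * direction + rho * (1 - cos(p)) * e2,
           numeric(3)))
}

# ---- imaging model ---------------------------------------------------------

#' Render a clean binary mask into a noisy intensity channel
#' @noRd
render_channel <- function(mask, spacing, noise) {
  arr <- gaussian_blur_3d(mask * 1.0, rep_len(noise$blur_um, 3), spacing)
  arr <- noise$background + (1 - noise$background) * arr
  if (noise$sigma > 0) arr <- arr + rnorm(length(arr), 0, noise$sigma)
  array(pmin(1, pmax(0, arr)), dim = dim(mask))
}

# ---- plexus scenes ---------------------------------------------------------

#' Generate a synthetic plexus volume with tubular vessels on a surface
#'
#' Rasterizes every vessel of the scene as a circular-cross-section tube
#' around its centreline, then applies the imaging model (Gaussian blur +
#' background + additive noise). Ground truth records each vessel's radius,
#' its voxel count in the clean mask, and the local outward surface normal at
#' every control point.
#'
#' @param spec a [scene_spec()].
#' @return list with `volume` (an [lsfm_volume()] with channel `vessels`) and
#'   `truth` (class `lsfm_truth`; includes the clean binary mask).
#' @export
make_plexus_volume <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  d <- spec$volume_shape; sp <- spec$spacing
  min_r <- 2 * max(sp)
  for (v in spec$vessels)
    if (v$radius < min_r)
      lsfm_stop(sprintf("vessel radius %.2f um < 2 x max spacing (%.2f um): unresolvable", v$radius, min_r))
  mask <- array(FALSE, dim = d)
  vtruth <- list()
  for (i in seq_along(spec$vessels)) {
    v <- spec$vessels[[i]]
    before <- sum(mask)
    only <- raster_tube(array(FALSE, dim = d), sp, v$points, v$radius)
    mask <- mask | only
    normals <- surface_normal_at(spec$surface, v$points)
    vtruth[[i]] <- list(id = i, radius_um = v$radius, points = v$points,
                        normals = normals, n_voxels = sum(only),
                        expected_width_um = 2 * v$radius,
                        expected_depth_um = 2 * v$radius)
  }
  vol <- lsfm_volume(list(vessels = render_channel(mask, sp, spec$noise)), spacing = sp)
  truth <- structure(list(kind = "plexus", surface = spec$surface, spacing = sp, dim = d,
                          vessels = vtruth, clean_mask = mask, distortion = list(),
                          seed = spec$seed),
                     class = "lsfm_truth")
  list(volume = vol, truth = truth)
}

#' Apply a flat-mounting distortion to a synthetic volume
#'
#' Emulates what confocal flat-mounting does to the tissue: optionally maps
#' the curved reference surface to a flat plane (`unbend`), then compresses
#' all distances to the surface along z by `compression`. Ground truth is
#' updated: expected vessel depths and tuft protrusion heights scale by
#' `compression`; expected widths are unchanged.
#'
#' @param volume an [lsfm_volume()].
#' @param truth the matching `lsfm_truth`.
#' @param compression factor in (0, 1]; 1 plus `unbend = FALSE` is the
#'   identity.
#' @param unbend flatten the curved surface before compressing.
#' @return list `(volume, truth)` after distortion.
#' @export
apply_flatmount_distortion <- function(volume, truth, compression, unbend = FALSE) {
  if (compression <= 0 || compression > 1) lsfm_stop("compression must be in (0, 1]")
  if (compression == 1 && !unbend) return(list(volume = volume, truth = truth))
  d <- vol_dim(volume); sp <- volume$spacing
  surf <- truth$surface
  ctr_xy <- c((d[3] - 1) * sp[3] / 2, (d[2] - 1) * sp[2] / 2)
  z_ref <- surface_elevation(surf, ctr_xy[1], ctr_xy[2])
  co <- voxel_coords(d, sp)
  zs <- array(surface_elevation(surf,
                                as.numeric(co$X),
                                as.numeric(co$Y)), dim = d)
  flat_ref <- if (unbend) z_ref else zs
  src_z <- zs + (co$Z - flat_ref) / compression
  pts <- cbind(as.numeric(co$X), as.numeric(co$Y), as.numeric(src_z))
  channels <- lapply(volume$channels, function(a) {
    array(trilinear_sample(a, sp, pts, outside = 0), dim = d)
  })
  out_vol <- lsfm_volume(channels, spacing = sp, dt_min = volume$dt_min)
  # ground truth updates
  remap_pts <- function(p) {
    p <- rbind(p)
    z_s <- surface_elevation(surf, p[, 1], p[, 2])
    ref <- if (unbend) z_ref else z_s
    cbind(p[, 1], p[, 2], ref + compression * (p[, 3] - z_s))
  }
  truth$vessels <- lapply(truth$vessels, function(v) {
    v$expected_depth_um <- v$expected_depth_um * compression
    v$points <- remap_pts(v$points)
    v
  })
  if (!is.null(truth$tufts)) {
    truth$tufts <- lapply(truth$tufts, function(tf) {
      tf$protrusion_height_um <- tf$protrusion_height_um * compression
      if (!is.null(tf$nuclei_centroids)) tf$nuclei_centroids <- remap_pts(tf$nuclei_centroids)
      tf
    })
  }
  if (!is.null(truth$clean_mask)) {
    mvals <- trilinear_sample(truth$clean_mask * 1.0, sp, pts, outside = 0)
    truth$clean_mask <- array(mvals >= 0.5, dim = d)
  }
  if (unbend) truth$surface <- surface_plane(z_ref)
  truth$distortion <- c(truth$distortion,
                        list(list(compression = compression, unbend = unbend)))
  list(volume = out_vol, truth = truth)
}

# ---- tuft scenes -----------------------------------------------------------

#' @noRd
tuft_geometry <- function(tf, surf) {
  a_xy <- tf$anchor_xy
  z0 <- surface_elevation(surf, a_xy[1], a_xy[2])
  base <- c(a_xy, z0)
  nrm <- as.numeric(surface_normal_at(surf, rbind(base)))
  V <- tf$target_volume_um3
  if (tf$n_tunnels == 0) {
    r <- (3 * V / (4 * pi))^(1 / 3)
    if (2 * r <= tf$protrusion_height_um - 13) {
      centre <- base + nrm * (tf$protrusion_height_um - r)
      return(list(type = "ball", centre = centre, r = r, normal = nrm, base = base,
                  lateral_extent = r))
    }
    # too squat for a ball within the height budget: cup (ring sealed by a
    # top plate; still no tunnels) - the morphology of many real tufts
    rf <- if (is.null(tf$ring_factor)) 2 else tf$ring_factor
    plate <- 3.5
    rt <- ((V * 0.8) / (2 * pi^2 * rf))^(1 / 3)
    rr <- rf * rt
    centre <- base + nrm * (tf$protrusion_height_um - plate - rt)
    return(list(type = "cup", centre = centre, ring_r = rr, tube_r = rt,
                plate_um = plate, normal = nrm, base = base,
                lateral_extent = rr + rt))
  }
  if (tf$n_tunnels == 1) {
    rf <- if (is.null(tf$ring_factor)) 2 else tf$ring_factor
    rt <- (V / (2 * pi^2 * rf))^(1 / 3) # solid torus, ring radius = rf * tube radius
    rr <- rf * rt
    centre <- base + nrm * (tf$protrusion_height_um - rt)
    list(type = "torus", centre = centre, ring_r = rr, tube_r = rt, normal = nrm,
         base = base, lateral_extent = rr + rt)
  } else {
    rf <- if (is.null(tf$ring_factor)) 2 else tf$ring_factor
    rt <- (V / (4 * pi^2 * rf))^(1 / 3) # two fused tori, each half the volume
    rr <- rf * rt
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- normalize3(cross3(nrm, ref))
    # cores exactly tangent: the tubes fuse in one contractible junction,
    # so the union is a genus-2 handlebody (two clear holes)
    off <- rr
    centre <- base + nrm * (tf$protrusion_height_um - rt)
    list(type = "double_torus", centres = list(centre - off * e1, centre + off * e1),
         ring_r = rr, tube_r = rt, normal = nrm, base = base,
         lateral_extent = off + rr + rt)
  }
}

#' @noRd
raster_tuft_body <- function(mask, spacing, geo) {
  if (geo$type == "ball") {
    raster_tube(mask, spacing, rbind(geo$centre), geo$r)
  } else if (geo$type == "cup") {
    mask <- raster_torus(mask, spacing, geo$centre, geo$normal, geo$ring_r, geo$tube_r)
    ctr <- geo$centre + geo$normal * (geo$tube_r - 0.5 + geo$plate_um / 2)
    raster_cylinder(mask, spacing, ctr, geo$normal,
                    geo$ring_r + 0.6 * geo$tube_r, geo$plate_um)
  } else if (geo$type == "torus") {
    raster_torus(mask, spacing, geo$centre, geo$normal, geo$ring_r, geo$tube_r)
  } else {
    mask <- raster_torus(mask, spacing, geo$centres[[1]], geo$normal, geo$ring_r, geo$tube_r)
    raster_torus(mask, spacing, geo$centres[[2]], geo$normal, geo$ring_r, geo$tube_r)
  }
}

#' Sample nucleus centres and axes inside a tuft body
#'
#' Nuclei stand along the tuft normal (cells growing up into the vitreous),
#' side by side: in a ball they occupy a lateral disc around the centre, in
#' a torus they line up along the ring core. A minimum lateral gap keeps the
#' rendered blobs from merging.
#' @noRd
sample_tuft_nuclei <- function(geo, n, min_gap = 6) {
  nrm <- geo$normal
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- normalize3(cross3(nrm, ref)); e2 <- cross3(nrm, e1)
  ring_points <- function(c0, R, n_pts, skip_rad = 0) {
    # n_pts evenly spaced on the circle, avoiding an angular zone of half
    # width skip_rad around angle 0 (the fusion side of a double torus)
    span <- 2 * pi - 2 * skip_rad
    phase <- if (skip_rad > 0) skip_rad else runif(1, 0, 2 * pi)
    th <- phase + (seq_len(n_pts) - 0.5) / n_pts * span
    chord <- 2 * R * sin(span / n_pts / 2)
    if (n_pts > 1 && chord < min_gap)
      lsfm_stop(sprintf("could not place %d nuclei with %.1f um separation in this tuft; increase target_volume_um3 or ring_factor", n, min_gap))
    t(vapply(th, function(a) c0 + R * (cos(a) * e1 + sin(a) * e2) +
               nrm * runif(1, -0.6, 0.6), numeric(3)))
  }
  centres <- if (geo$type == "ball") {
    lat_max <- geo$r - 6
    if (n == 1) rbind(geo$centre + nrm * runif(1, -0.6, 0.6))
    else {
      rho <- min_gap / (2 * sin(pi / n))
      if (rho > lat_max)
        lsfm_stop(sprintf("could not place %d nuclei with %.1f um separation in this tuft; increase target_volume_um3", n, min_gap))
      ring_points(geo$centre, rho, n)
    }
  } else if (geo$type %in% c("torus", "cup")) {
    ring_points(geo$centre, geo$ring_r, n)
  } else {
    n1 <- ceiling(n / 2); n2 <- n - n1
    skip <- 2.5 * min_gap / geo$ring_r # stay clear of the fusion zone
    p1 <- ring_points(geo$centres[[1]], geo$ring_r, n1, skip_rad = skip)
    # ring 1 fuses towards +e1 (angle 0), ring 2 towards -e1 (angle pi):
    # rotate ring 2 points by pi so its skip zone faces ring 1
    p2 <- if (n2 > 0) {
      raw <- ring_points(geo$centres[[2]], geo$ring_r, n2, skip_rad = skip)
      sweep(-(sweep(raw, 2, geo$centres[[2]])), 2, geo$centres[[2]], FUN = "+")
    } else matrix(numeric(0), 0, 3)
    rbind(p1, p2)
  }
  # axes along the normal, tilted slightly outward; curved nuclei bow
  # radially outward so neighbouring cells along the ring never collide
  radial_of <- function(p) {
    ref_c <- if (geo$type == "double_torus") {
      dc <- vapply(geo$centres, function(c0) sum((p - c0)^2), numeric(1))
      geo$centres[[which.min(dc)]]
    } else geo$centre
    v <- p - ref_c
    v <- v - sum(v * nrm) * nrm
    if (sqrt(sum(v^2)) < 1e-6) e1 else normalize3(v)
  }
  bends <- t(apply(centres, 1, radial_of))
  dirs <- t(vapply(seq_len(n), function(i)
    normalize3(nrm + 0.07 * bends[i, ]), numeric(3)))
  list(centres = centres, dirs = dirs, bends = bends)
}

#' Generate a synthetic tuft scene with vessels, tufts and nuclei channels
#'
#' Renders the scene's plexus vessels plus, for each [tuft_spec()], a
#' protruding body whose first Betti number equals `n_tunnels` (ball, torus
#' or two fused tori), exactly `n_connections` stalk tubes joining the body
#' to the plexus surface, and exactly `n_nuclei` nuclei (bent capsules for
#' curved nuclei, straight capsules otherwise) inside the body, rendered in a
#' second channel.
#'
#' @param spec a [scene_spec()] with at least one tuft.
#' @param stalk_radius_um radius of connection stalks (µm).
#' @param nucleus_length_um,nucleus_radius_um capsule dimensions (µm).
#' @param curved_length_um arc length of curved nuclei (longer than flat
#'   ones, as strongly bent nuclei are stretched around the strain).
#' @param curved_bend_deg total turning angle of a curved nucleus (degrees);
#'   the default 200 gives a pronounced C shape (arc/chord about 1.8).
#' @return list `(volume, truth)`; the volume has channels `vessels` and
#'   `nuclei`, truth records per-tuft realized values and per-tuft voxel
#'   index sets.
#' @export
make_tuft_volume <- function(spec, stalk_radius_um = 2.5,
                             nucleus_length_um = 9, nucleus_radius_um = 1.7,
                             curved_length_um = 12, curved_bend_deg = 200) {
  stopifnot(inherits(spec, "scene_spec"))
  if (length(spec$tufts) == 0) lsfm_stop("scene has no tufts")
  for (tf in spec$tufts) if (tf$n_nuclei < 1) lsfm_stop("n_nuclei must be >= 1")
  set.seed(spec$seed)
  d <- spec$volume_shape; sp <- spec$spacing
  vmask <- array(FALSE, dim = d)
  for (v in spec$vessels) vmask <- raster_tube(vmask, sp, v$points, v$radius)
  plexus_mask <- vmask
  nmask <- array(FALSE, dim = d)
  ttruth <- list()
  for (i in seq_along(spec$tufts)) {
    tf <- spec$tufts[[i]]
    geo <- tuft_geometry(tf, spec$surface)
    tmask <- raster_tuft_body(array(FALSE, dim = d), sp, geo)
    # stalks: attachment points spread around the body, avoiding the fusion
    # zone of a double torus; each stalk drops to the plexus surface
    nrm <- geo$normal
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- normalize3(cross3(nrm, ref)); e2 <- cross3(nrm, e1)
    kcon <- tf$n_connections
    tops <- if (geo$type == "double_torus") {
      k1 <- ceiling(kcon / 2); k2 <- kcon - k1
      ang <- function(ki) (seq_len(ki) - (ki + 1) / 2) * (2 * pi - 2.4) / max(ki, 1)
      rbind(
        t(vapply(ang(k1) + pi, function(a) # ring 1 far side (fusion at angle 0)
          geo$centres[[1]] + geo$ring_r * (cos(a) * e1 + sin(a) * e2), numeric(3))),
        if (k2 > 0) t(vapply(ang(k2), function(a) # ring 2 far side
          geo$centres[[2]] + geo$ring_r * (cos(a) * e1 + sin(a) * e2), numeric(3)))
        else matrix(numeric(0), 0, 3))
    } else {
      az <- runif(1, 0, 2 * pi) + (seq_len(kcon) - 1) * 2 * pi / max(kcon, 1)
      lat <- if (geo$type == "ball") 0.5 * geo$r else geo$ring_r
      drop_um <- if (geo$type == "ball") geo$r * 0.6 else 0
      t(vapply(az, function(a)
        geo$centre + lat * (cos(a) * e1 + sin(a) * e2) - nrm * drop_um, numeric(3)))
    }
    for (k in seq_len(kcon)) {
      top <- tops[k, ]
      lat_vec <- (top - geo$base) - sum((top - geo$base) * nrm) * nrm
      bottom <- geo$base + 0.6 * lat_vec - nrm * 2
      tmask <- raster_tube(tmask, sp, rbind(bottom, top), stalk_radius_um)
    }
    # nuclei
    n_curved <- round(tf$curved_nuclei_fraction * tf$n_nuclei)
    placed <- sample_tuft_nuclei(geo, tf$n_nuclei)
    centres <- placed$centres
    curved <- rep(FALSE, tf$n_nuclei)
    if (n_curved > 0) curved[seq_len(n_curved)] <- TRUE
    for (j in seq_len(tf$n_nuclei)) {
      poly <- nucleus_polyline(centres[j, ], placed$dirs[j, ], placed$bends[j, ],
                               if (curved[j]) curved_length_um else nucleus_length_um,
                               if (curved[j]) curved_bend_deg else 0)
      nmask <- raster_tube(nmask, sp, poly, nucleus_radius_um)
    }
    vmask <- vmask | tmask
    ttruth[[i]] <- list(id = i, spec = tf, geometry_type = geo$type,
                        anchor = geo$base, normal = nrm,
                        n_nuclei = tf$n_nuclei, n_curved_nuclei = sum(curved),
                        n_connections = kcon, n_tunnels = tf$n_tunnels,
                        protrusion_height_um = tf$protrusion_height_um,
                        nuclei_centroids = centres, nuclei_curved = curved,
                        mask_idx = which(tmask))
  }
  channels <- list(vessels = render_channel(vmask, sp, spec$noise),
                   nuclei = render_channel(nmask, sp, spec$noise))
  vol <- lsfm_volume(channels, spacing = sp)
  truth <- structure(list(kind = "tufts", surface = spec$surface, spacing = sp, dim = d,
                          vessels = lapply(seq_along(spec$vessels), function(i) {
                            v <- spec$vessels[[i]]
                            list(id = i, radius_um = v$radius, points = v$points,
                                 expected_width_um = 2 * v$radius,
                                 expected_depth_um = 2 * v$radius)
                          }),
                          tufts = ttruth, clean_mask = vmask,
                          clean_nuclei_mask = nmask, plexus_mask = plexus_mask,
                          distortion = list(), seed = spec$seed),
                     class = "lsfm_truth")
  list(volume = vol, truth = truth)
}

# ---- time lapse ------------------------------------------------------------

#' Generate a scripted 4D time lapse with filopodia and moving actin bundles
#'
#' Each filopodium is scripted as a base point, a unit growth direction and a
#' per-frame length series; each actin bundle as a per-frame position. The
#' function renders a 4D intensity stack, emits the exact track table (tip
#' positions for filopodia, centroids for bundles), and computes the
#' ground-truth kinematics from the script in closed form (appearance =
#' first frame with length above `eps_um`, disappearance = first later frame
#' at or below it, half-open alive interval).
#'
#' @param filopodia list of `list(base, dir, lengths)` scripts (µm).
#' @param bundles list of `list(positions)` scripts (n_frames x 3 µm).
#' @param dt_min constant frame interval, minutes.
#' @param seed integer seed (rendering noise).
#' @param volume_shape,spacing voxel grid of the rendered stack.
#' @param eps_um filopodium presence threshold used for the scripted truth.
#' @param noise imaging model as in [scene_spec()].
#' @param render if `FALSE`, skip rasterization (tracks + truth only).
#' @return list `(volume, tracks, truth)`; `tracks` is a data frame with
#'   columns `track_id, frame, x_um, y_um, z_um` (frames 0-based).
#' @export
make_timelapse <- function(filopodia = list(), bundles = list(), dt_min = 1,
                           seed = 1, volume_shape = c(24, 64, 64),
                           spacing = c(1, 1, 1), eps_um = 0.5,
                           noise = list(background = 0.05, sigma = 0.02,
                                        blur_um = c(0.8, 0.8, 0.8)),
                           render = TRUE) {
  if (length(dt_min) != 1 || !is.finite(dt_min) || dt_min <= 0)
    lsfm_stop("dt_min must be a single positive frame interval (constant by contract)")
  set.seed(as.integer(seed))
  nf <- unique(c(vapply(filopodia, function(f) length(f$lengths), integer(1)),
                 vapply(bundles, function(b) nrow(b$positions), integer(1))))
  if (length(nf) == 0) lsfm_stop("no scripted objects")
  if (length(nf) != 1) lsfm_stop("all scripts must cover the same number of frames")
  rows <- list(); truth_f <- list(); truth_b <- list()
  tid <- 0
  for (f in filopodia) {
    tid <- tid + 1
    diru <- normalize3(f$dir)
    tips <- matrix(f$base, nf, 3, byrow = TRUE) + outer(f$lengths, diru)
    rows[[length(rows) + 1]] <- data.frame(track_id = tid, frame = seq_len(nf) - 1,
                                           x_um = tips[, 1], y_um = tips[, 2], z_um = tips[, 3])
    truth_f[[length(truth_f) + 1]] <- c(list(track_id = tid, base = f$base, lengths = f$lengths),
                                        scripted_filopodium_truth(f$lengths, dt_min, eps_um))
  }
  for (b in bundles) {
    tid <- tid + 1
    p <- b$positions
    rows[[length(rows) + 1]] <- data.frame(track_id = tid, frame = seq_len(nf) - 1,
                                           x_um = p[, 1], y_um = p[, 2], z_um = p[, 3])
    steps <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nf, , drop = FALSE])^2))
    truth_b[[length(truth_b) + 1]] <- list(track_id = tid,
                                           path_length_um = sum(steps),
                                           duration_min = (nf - 1) * dt_min,
                                           average_speed_um_min = sum(steps) / ((nf - 1) * dt_min))
  }
  tracks <- do.call(rbind, rows)
  vol <- NULL
  if (render) {
    d <- volume_shape
    frames <- array(0, dim = c(nf, d))
    for (t in seq_len(nf)) {
      m <- array(FALSE, dim = d)
      for (f in filopodia) {
        if (f$lengths[t] > 0) {
          diru <- normalize3(f$dir)
          m <- raster_tube(m, spacing, rbind(f$base, f$base + diru * f$lengths[t]), 0.9)
        }
      }
      for (b in bundles) m <- raster_tube(m, spacing, rbind(b$positions[t, ]), 1.5)
      frames[t, , , ] <- render_channel(m, spacing, noise)
    }
    vol <- lsfm_volume(list(actin = frames), spacing = spacing, dt_min = dt_min)
  }
  truth <- structure(list(kind = "timelapse", dt_min = dt_min, eps_um = eps_um,
                          filopodia = truth_f, bundles = truth_b, seed = seed),
                     class = "lsfm_truth")
  list(volume = vol, tracks = tracks, truth = truth)
}

#' Closed-form kinematics of a scripted length series (ground-truth side)
#' @noRd
scripted_filopodium_truth <- function(lengths, dt_min, eps_um) {
  alive <- which(lengths > eps_um)
  if (length(alive) == 0) lsfm_stop("scripted filopodium never exceeds eps")
  a0 <- alive[1]
  after <- which(seq_along(lengths) > a0 & lengths <= eps_um)
  censored <- length(after) == 0
  a1 <- if (censored) length(lengths) + 1 else after[1]
  seg <- lengths[a0:min(a1, length(lengths))]
  dl <- diff(lengths[max(1, a0 - 1):min(a1, length(lengths))]) / dt_min
  list(max_length_um = max(seg),
       lifetime_min = (a1 - a0) * dt_min,
       censored = censored,
       extension_speed_um_min = if (any(dl > 0)) mean(dl[dl > 0]) else 0,
       retraction_speed_um_min = if (any(dl < 0)) mean(-dl[dl < 0]) else 0)
}

#' Scripted filopodium populations for the two live-imaging conditions
#'
#' Draws triangular grow/shrink length scripts whose population mean maximum
#' length matches the study condition: developing (P5) retinas with long
#' filopodia (mean max 14.84 µm) or OIR tufts with short ones (mean 4.3 µm),
#' over a 40-frame, 1 min interval session.
#'
#' @param n number of filopodia.
#' @param condition `"P5"` or `"OIR"`.
#' @param n_frames frames in the session.
#' @param seed integer seed.
#' @return list of scripts usable as `filopodia` in [make_timelapse()].
#' @export
scripted_filopodia_population <- function(n, condition = c("P5", "OIR"),
                                          n_frames = 40, seed = 1) {
  condition <- match.arg(condition)
  set.seed(as.integer(seed))
  mean_max <- if (condition == "P5") 14.84 else 4.3
  out <- vector("list", n)
  for (i in seq_len(n)) {
    peak <- max(1.2, rnorm(1, mean_max, 0.25 * mean_max))
    rate <- runif(1, 0.5, 1) * peak / 4 # reach peak in ~4-8 frames
    up <- seq(0, peak, by = rate)
    if (up[length(up)] < peak) up <- c(up, peak)
    down <- rev(up)[-1]
    lengths <- c(up, down)
    start <- sample.int(max(1, n_frames - length(lengths)), 1)
    full <- numeric(n_frames)
    idx <- start + seq_along(lengths) - 1
    keep <- idx <= n_frames
    full[idx[keep]] <- lengths[keep]
    base <- c(runif(1, 10, 50), runif(1, 10, 50), runif(1, 8, 16))
    dir0 <- normalize3(c(rnorm(2), abs(rnorm(1))))
    out[[i]] <- list(base = base, dir = dir0, lengths = full)
  }
  out
}

#' Scripted actin-bundle random walks at a target speed
#'
#' Each bundle moves a constant per-frame step of `speed * dt` in a smoothly
#' varying direction, emulating the tracked actin-rich bundles (average
#' speed 2.56 µm/min in the source live-imaging condition).
#'
#' @param n bundles; @param n_frames frames; @param dt_min interval (min).
#' @param speed_mean_um_min,speed_sd_um_min per-bundle speed distribution.
#' @param seed integer seed.
#' @return list of scripts usable as `bundles` in [make_timelapse()].
#' @export
scripted_bundle_population <- function(n, n_frames = 40, dt_min = 1,
                                       speed_mean_um_min = 2.56,
                                       speed_sd_um_min = 0.4, seed = 1) {
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- max(0.3, rnorm(1, speed_mean_um_min, speed_sd_um_min))
    step <- sp * dt_min
    pos <- matrix(NA_real_, n_frames, 3)
    pos[1, ] <- c(runif(1, 15, 45), runif(1, 15, 45), runif(1, 8, 16))
    dir0 <- normalize3(rnorm(3))
    for (t in 2:n_frames) {
      dir0 <- normalize3(dir0 + 0.4 * rnorm(3))
      pos[t, ] <- pos[t - 1, ] + dir0 * step
    }
    out[[i]] <- list(positions = pos, speed_um_min = sp)
  }
  out
}

# ---- layered nuclei --------------------------------------------------------

#' Generate a synthetic nuclear layer (ONL-like slab) volume
#'
#' Places nuclei by a uniform point process at the requested areal density
#' inside a slab of the requested thickness following the reference surface,
#' and renders them as spheres in a `nuclei` channel.
#'
#' @param density_per_um2 nuclei per µm² of lateral area (> 0 unless 0 for an
#'   empty layer).
#' @param thickness_um slab thickness (> 0).
#' @param volume_shape,spacing voxel grid.
#' @param surface reference surface of the slab's upper boundary.
#' @param nucleus_radius_um rendered nucleus radius.
#' @param seed integer seed.
#' @param noise imaging model as in [scene_spec()].
#' @return list `(volume, truth)`; truth holds centroids, realized density,
#'   thickness, and an `overlap_warning` flag when nuclei are packed so
#'   densely that rendered blobs are expected to merge.
#' @export
make_layered_volume <- function(density_per_um2, thickness_um,
                                volume_shape = c(80, 100, 100), spacing = c(1, 1, 1),
                                surface = NULL, nucleus_radius_um = 2.2, seed = 1,
                                noise = list(background = 0.05, sigma = 0.02,
                                             blur_um = c(0.8, 0.8, 0.8))) {
  if (density_per_um2 < 0) lsfm_stop("density must be >= 0")
  if (thickness_um <= 0) lsfm_stop("thickness must be > 0")
  set.seed(as.integer(seed))
  d <- volume_shape; sp <- spacing
  ext_x <- (d[3] - 1) * sp[3]; ext_y <- (d[2] - 1) * sp[2]
  if (is.null(surface))
    surface <- surface_plane(z0 = (d[1] - 1) * sp[1] * 0.75)
  area <- ext_x * ext_y
  n <- round(density_per_um2 * area)
  margin <- nucleus_radius_um + 1
  centres <- if (n > 0) {
    x <- runif(n, margin, ext_x - margin)
    y <- runif(n, margin, ext_y - margin)
    depth <- runif(n, margin, thickness_um - margin)
    z <- surface_elevation(surface, x, y) - depth
    cbind(x, y, z)
  } else matrix(numeric(0), 0, 3)
  mask <- array(FALSE, dim = d)
  for (i in seq_len(n)) mask <- raster_tube(mask, sp, rbind(centres[i, ]), nucleus_radius_um)
  overlap <- FALSE
  if (n > 1) {
    dd <- as.matrix(stats::dist(centres))
    diag(dd) <- Inf
    overlap <- mean(apply(dd, 1, min) < 2 * nucleus_radius_um) > 0.05
    if (overlap) warning("nucleus density high enough that rendered blobs may merge")
  }
  vol <- lsfm_volume(list(nuclei = render_channel(mask, sp, noise)), spacing = sp)
  truth <- structure(list(kind = "layers", surface = surface, spacing = sp, dim = d,
                          centroids = centres, n_nuclei = n,
                          density_per_um2 = n / area, area_um2 = area,
                          thickness_um = thickness_um, overlap_warning = overlap,
                          clean_mask = mask, seed = seed),
                     class = "lsfm_truth")
  list(volume = vol, truth = truth)
}
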