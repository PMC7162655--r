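#' Diameter/distortion recovery study on synthetic tubes
#'
#' Generates `n_tubes` plexus scenes on a spherical-cap surface with target
#' vessel radii uniform in `radius_range_um`, measures plane-referenced
#' width and depth in the native geometry and again after unbending plus
#' axial compression, and summarises recovery: measurement errors against
#' the true diameter 2r, the depth/width ratio under compression, and the
#' unpaired t-test between distorted and undistorted depths (on the
#' dimensionless depth/2r scale, since radii vary by design).
#'
#' @param n_tubes number of tubes.
#' @param radius_range_um sampling range of tube radii.
#' @param compression axial compression factor of the flat-mounted copy.
#' @param seed integer seed.
#' @return list with `per_tube` (data frame) and `summary`.
#' @export
run_distortion_study <- function(n_tubes = 50, radius_range_um = c(3, 15),
                                 compression = 0.4, seed = 1) {
  set.seed(seed)
  radii <- runif(n_tubes, radius_range_um[1], radius_range_um[2])
  scene_seeds <- sample.int(1e6, n_tubes)
  rows <- vector("list", n_tubes)
  measure_one <- function(vol, surface, modality) {
    vm <- segment_vessels(vol)
    sk <- skeletonize_mask(vm, prune_um = 4)
    d <- vol_dim(vol); sp <- vol$spacing
    xy <- c((d[3] - 1) * sp[3] / 2, (d[2] - 1) * sp[2] / 2)
    site <- c(xy, surface_elevation(surface, xy[1], xy[2]))
    pl <- fit_plexus_plane(sk, site, fit_radius = 30)
    measure_diameters(vm, site, pl, sk, modality = modality)
  }
  for (i in seq_len(n_tubes)) {
    gen <- make_plexus_volume(plexus_scene_spec(seed = scene_seeds[i],
                                                target_radius_um = radii[i]))
    pair <- apply_flatmount_distortion(gen$volume, gen$truth,
                                       compression = compression, unbend = TRUE)
    ml <- measure_one(gen$volume, gen$truth$surface, "lsfm")
    mc <- measure_one(pair$volume, pair$truth$surface, "confocal")
    rows[[i]] <- data.frame(radius_um = radii[i],
                            width_um = ml$width_um, depth_um = ml$depth_um,
                            width_c_um = mc$width_um, depth_c_um = mc$depth_um)
  }
  per_tube <- do.call(rbind, rows)
  tt <- safe_t_test(per_tube$depth_um / (2 * per_tube$radius_um),
                    per_tube$depth_c_um / (2 * per_tube$radius_um))
  list(per_tube = per_tube,
       summary = list(
         n = n_tubes,
         max_width_err_um = max(abs(per_tube$width_um - 2 * per_tube$radius_um)),
         max_depth_err_um = max(abs(per_tube$depth_um - 2 * per_tube$radius_um)),
         median_width_err_um = median(abs(per_tube$width_um - 2 * per_tube$radius_um)),
         median_depth_err_um = median(abs(per_tube$depth_um - 2 * per_tube$radius_um)),
         median_depth_width_ratio = median(per_tube$depth_c_um / per_tube$width_c_um),
         compression = compression,
         t_statistic = tt$statistic, t_p_value = tt$p.value))
}

#' Tuft morphometric recovery study
#'
#' Generates scenes with tufts cycling through the small/medium/large
#' classes until `n_tufts` tufts exist, runs the full measurement pipeline,
#' and matches each measured tuft to its ground truth by anchor position.
#'
#' @param n_tufts total number of tufts across scenes.
#' @param seed integer seed.
#' @return list with `per_tuft` (truth vs measured, one row per tuft) and
#'   `summary` recovery rates.
#' @export
run_tuft_recovery_study <- function(n_tufts = 30, seed = 1) {
  set.seed(seed)
  classes <- rep(c("small", "medium", "large"), length.out = n_tufts)
  chunks <- split(classes, ceiling(seq_along(classes) / 4))
  scene_seeds <- sample.int(1e6, length(chunks))
  rows <- list()
  for (ci in seq_along(chunks)) {
    gen <- make_tuft_volume(tuft_scene_spec(seed = scene_seeds[ci],
                                            classes = chunks[[ci]]))
    res <- measure_tuft_scene(gen$volume, gen$truth$surface)
    m <- res$tufts
    co <- voxel_coords(gen$truth$dim, gen$truth$spacing)
    for (tf in gen$truth$tufts) {
      j <- which.min((m$x_um - tf$anchor[1])^2 + (m$y_um - tf$anchor[2])^2)
      hh <- surface_height(gen$truth$surface,
                           cbind(co$X[tf$mask_idx], co$Y[tf$mask_idx], co$Z[tf$mask_idx]))
      truth_vol <- sum(hh > 10) * prod(gen$truth$spacing)
      # per-nucleus curved-flag agreement by centroid matching
      nm <- res$nuclei[res$nuclei$tuft_id == m$tuft_id[j], ]
      agree <- 0L; matched <- 0L
      for (i in seq_len(tf$n_nuclei)) {
        ctr <- tf$nuclei_centroids[i, ]
        d2 <- (nm$x_um - ctr[1])^2 + (nm$y_um - ctr[2])^2 + (nm$z_um - ctr[3])^2
        k <- which.min(d2)
        if (length(k) == 1 && d2[k] < 25) {
          matched <- matched + 1L
          agree <- agree + as.integer(nm$curved[k] == tf$nuclei_curved[i])
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        scene_seed = scene_seeds[ci], tuft_id = tf$id,
        true_nuclei = tf$n_nuclei, meas_nuclei = m$n_nuclei[j],
        true_connections = tf$n_connections, meas_connections = m$n_connections[j],
        true_tunnels = tf$n_tunnels, meas_tunnels = m$n_tunnels[j],
        true_class = as.character(classify_tuft(tf$n_nuclei)),
        meas_class = as.character(m$size_class[j]),
        true_volume_um3 = truth_vol, meas_volume_um3 = m$volume_um3[j],
        true_depth_um = tf$protrusion_height_um, meas_depth_um = m$depth_um[j],
        nuclei_matched = matched, curved_agree = agree)
    }
  }
  per_tuft <- do.call(rbind, rows)
  list(per_tuft = per_tuft,
       summary = list(
         n = nrow(per_tuft),
         nuclei_exact_rate = mean(per_tuft$meas_nuclei == per_tuft$true_nuclei),
         connections_exact_rate = mean(per_tuft$meas_connections == per_tuft$true_connections),
         tunnels_exact_rate = mean(per_tuft$meas_tunnels == per_tuft$true_tunnels),
         class_accuracy = mean(per_tuft$meas_class == per_tuft$true_class),
         max_volume_rel_err = max(abs(per_tuft$meas_volume_um3 / per_tuft$true_volume_um3 - 1)),
         curved_flag_agreement = sum(per_tuft$curved_agree) / sum(per_tuft$nuclei_matched)))
}
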