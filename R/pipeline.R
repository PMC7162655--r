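#' Built-in synthetic scene presets
#'
#' Deterministic study-condition scenes used by the pipeline and the
#' validation suite:
#' \describe{
#'   \item{plexus}{a spherical-cap plexus (radius 1700 µm) carrying a target
#'     vessel and a surrounding capillary web.}
#'   \item{distortion_pair}{the plexus scene plus its flat-mounted twin
#'     (unbent, compressed 0.4 along z).}
#'   \item{tufts}{four tufts spanning the small/medium/large classes with
#'     known nuclei, connections and tunnels.}
#'   \item{timelapse}{scripted filopodia (P5 and OIR conditions) and actin
#'     bundles over 40 one-minute frames.}
#'   \item{layers}{an ONL-like nuclear slab.}
#' }
#' @name presets
NULL

#' Scene for one measurable vessel embedded in a plexus web
#'
#' @param seed integer seed.
#' @param target_radius_um radius of the central vessel.
#' @param spacing voxel spacing.
#' @param shape volume shape `(z, y, x)`.
#' @return a [scene_spec()]; the target vessel is the first one, running
#'   along x through the lateral centre.
#' @export
plexus_scene_spec <- function(seed, target_radius_um = 8, spacing = c(1, 1, 1),
                              shape = c(56, 96, 96)) {
  ext_x <- (shape[3] - 1) * spacing[3]
  ext_y <- (shape[2] - 1) * spacing[2]
  cx <- ext_x / 2; cy <- ext_y / 2
  surf <- surface_cap(c(cx, cy), radius_um = 1700, apex_z = (shape[1] - 1) * spacing[1] * 0.45)
  on_surface <- function(x, y) cbind(x, y, surface_elevation(surf, x, y))
  line_x <- function(y0) {
    xs <- seq(0, ext_x, by = 8)
    list(points = on_surface(xs, rep(y0, length(xs))), radius = 3)
  }
  line_y <- function(x0) {
    ys <- seq(0, ext_y, by = 8)
    list(points = on_surface(rep(x0, length(ys)), ys), radius = 3)
  }
  target <- list(points = on_surface(seq(0, ext_x, by = 8), rep(cy, length(seq(0, ext_x, by = 8)))),
                 radius = target_radius_um)
  vessels <- c(list(target),
               lapply(c(cy - 24, cy + 24), line_x),
               lapply(c(cx - 28, cx + 28), line_y))
  scene_spec(seed = seed, volume_shape = shape, spacing = spacing,
             surface = surf, vessels = vessels)
}

#' Scene with tufts spanning the three size classes
#'
#' @param seed integer seed.
#' @param classes character vector drawn from `c("small","medium","large")`,
#'   one tuft per entry (at most 4 per scene).
#' @param spacing voxel spacing.
#' @return a [scene_spec()] with a plexus web and the requested tufts.
#' @export
tuft_scene_spec <- function(seed, classes = c("small", "medium", "large", "medium"),
                            spacing = c(1, 1, 1)) {
  if (length(classes) > 4) lsfm_stop("at most 4 tufts per scene")
  set.seed(seed * 7 + 1)
  shape <- c(72, 184, 184)
  ext <- (shape[2] - 1) * spacing[2]
  surf <- surface_cap(c(ext / 2, ext / 2), radius_um = 1700, apex_z = 8)
  anchors <- list(c(47, 47), c(137, 47), c(47, 137), c(137, 137))
  tufts <- list()
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tufts[[i]] <- switch(
      cl,
      small = tuft_spec(anchors[[i]], n_nuclei = sample(2:3, 1), n_connections = 1,
                        n_tunnels = 0, curved_nuclei_fraction = 0,
                        target_volume_um3 = 4200, protrusion_height_um = 34),
      medium = {
        n <- sample(5:16, 1)
        tuft_spec(anchors[[i]], n_nuclei = n, n_connections = sample(1:3, 1),
                  n_tunnels = sample(0:1, 1), curved_nuclei_fraction = 0.4,
                  target_volume_um3 = max(11000, 2300 * n),
                  protrusion_height_um = 36, ring_factor = 2.2)
      },
      large = {
        tun <- sample(1:2, 1)
        n <- if (tun == 1) sample(21:24, 1) else sample(21:22, 1)
        tuft_spec(anchors[[i]], n_nuclei = n,
                  n_connections = sample(4:6, 1),
                  n_tunnels = tun, curved_nuclei_fraction = 0.2,
                  target_volume_um3 = (if (tun == 1) 3000 else 2500) * n,
                  protrusion_height_um = 46,
                  ring_factor = if (tun == 1) 2.8 else 2.0)
      },
      lsfm_stop(sprintf("unknown tuft class '%s'", cl)))
  }
  on_surface <- function(x, y) cbind(x, y, surface_elevation(surf, x, y))
  mk_x <- function(y0) list(points = on_surface(seq(0, ext, by = 8), rep(y0, length(seq(0, ext, by = 8)))), radius = 3)
  mk_y <- function(x0) list(points = on_surface(rep(x0, length(seq(0, ext, by = 8))), seq(0, ext, by = 8)), radius = 3)
  vessels <- c(lapply(c(47, 137), mk_x), lapply(c(47, 137), mk_y))
  scene_spec(seed = seed, volume_shape = shape, spacing = spacing, surface = surf,
             vessels = vessels, tufts = tufts)
}

#' Write ground truth to JSON (arrays and voxel indices summarised)
#' @noRd
write_truth <- function(truth, path) {
  slim <- truth
  slim$clean_mask <- NULL; slim$clean_nuclei_mask <- NULL; slim$plexus_mask <- NULL
  if (!is.null(slim$tufts))
    slim$tufts <- lapply(slim$tufts, function(tf) { tf$mask_idx <- length(tf$mask_idx); names(tf)[names(tf) == "mask_idx"] <- "mask_idx"; tf$n_mask_voxels <- tf$mask_idx; tf$mask_idx <- NULL; tf$spec <- unclass(tf$spec); tf })
  slim$surface <- unclass(slim$surface)
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Run manifest: config snapshot, input hashes, seed, outputs
#' @noRd
write_manifest <- function(out_dir, command, config, seed, inputs = character(0),
                           outputs = character(0), t0 = Sys.time()) {
  manifest <- list(
    tool = "retinalsfm", version = as.character(utils::packageVersion("retinalsfm")),
    command = command, seed = seed,
    config = config[!vapply(config, is.null, logical(1))],
    inputs = lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a preset scene and write volumes, tracks and ground truth
#'
#' @param preset one of `plexus`, `distortion_pair`, `tufts`, `timelapse`,
#'   `layers`.
#' @param seed integer seed.
#' @param out_dir output directory (created).
#' @param config an [lsfm_config()].
#' @return invisible list of written files.
#' @export
cmd_simulate <- function(preset, seed = 1, out_dir = ".", config = lsfm_config()) {
  presets <- c("plexus", "distortion_pair", "tufts", "timelapse", "layers")
  if (!preset %in% presets)
    lsfm_usage_stop(sprintf("unknown preset '%s' (choose from: %s)", preset,
                            paste(presets, collapse = ", ")))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- config$spacing_um
  outs <- character(0)
  emit_vol <- function(vol, name) {
    p <- file.path(out_dir, paste0(name, ".tif"))
    write_volume(vol, p)
    outs <<- c(outs, p, paste0(p, ".json"))
    p
  }
  if (preset == "plexus") {
    gen <- make_plexus_volume(plexus_scene_spec(seed, spacing = sp))
    emit_vol(gen$volume, "plexus")
    write_truth(gen$truth, file.path(out_dir, "truth.json"))
    outs <- c(outs, file.path(out_dir, "truth.json"))
  } else if (preset == "distortion_pair") {
    gen <- make_plexus_volume(plexus_scene_spec(seed, spacing = sp))
    emit_vol(gen$volume, "lsfm")
    dis <- apply_flatmount_distortion(gen$volume, gen$truth, compression = 0.4, unbend = TRUE)
    emit_vol(dis$volume, "confocal")
    write_truth(gen$truth, file.path(out_dir, "truth_lsfm.json"))
    write_truth(dis$truth, file.path(out_dir, "truth_confocal.json"))
    outs <- c(outs, file.path(out_dir, c("truth_lsfm.json", "truth_confocal.json")))
  } else if (preset == "tufts") {
    gen <- make_tuft_volume(tuft_scene_spec(seed, spacing = sp))
    emit_vol(gen$volume, "tufts")
    write_truth(gen$truth, file.path(out_dir, "truth.json"))
    tt <- truth_tuft_table(gen$truth)
    write.csv(tt, file.path(out_dir, "truth_tufts.csv"), row.names = FALSE)
    outs <- c(outs, file.path(out_dir, c("truth.json", "truth_tufts.csv")))
  } else if (preset == "timelapse") {
    fil <- scripted_filopodia_population(8, "P5", seed = seed)
    bun <- scripted_bundle_population(5, seed = seed + 1)
    tl <- make_timelapse(fil, bun, dt_min = config$dt_min, seed = seed)
    emit_vol(tl$volume, "timelapse")
    fil_ids <- vapply(tl$truth$filopodia, `[[`, numeric(1), "track_id")
    write_tracks(tl$tracks, file.path(out_dir, "tracks.csv"))
    write_tracks(tl$tracks[tl$tracks$track_id %in% fil_ids, ],
                 file.path(out_dir, "filopodia_tracks.csv"))
    write_tracks(tl$tracks[!tl$tracks$track_id %in% fil_ids, ],
                 file.path(out_dir, "bundle_tracks.csv"))
    write_truth(tl$truth, file.path(out_dir, "truth.json"))
    outs <- c(outs, file.path(out_dir, c("tracks.csv", "filopodia_tracks.csv",
                                         "bundle_tracks.csv", "truth.json")))
  } else {
    gen <- make_layered_volume(density_per_um2 = 5e-3, thickness_um = 60, seed = seed)
    emit_vol(gen$volume, "layers")
    write_truth(gen$truth, file.path(out_dir, "truth.json"))
    outs <- c(outs, file.path(out_dir, "truth.json"))
  }
  write_manifest(out_dir, paste("simulate", preset), config, seed, outputs = outs, t0 = t0)
  invisible(outs)
}

#' Ground-truth tuft table as a data frame
#' @param truth an `lsfm_truth` from [make_tuft_volume()].
#' @return data frame, one row per tuft.
#' @export
truth_tuft_table <- function(truth) {
  do.call(rbind, lapply(truth$tufts, function(tf) data.frame(
    tuft_id = tf$id, n_nuclei = tf$n_nuclei, n_curved_nuclei = tf$n_curved_nuclei,
    n_connections = tf$n_connections, n_tunnels = tf$n_tunnels,
    protrusion_height_um = tf$protrusion_height_um,
    size_class = as.character(classify_tuft(tf$n_nuclei)))))
}

#' Measure the full tuft morphometric table from a generated scene
#'
#' End-to-end analysis of a tuft scene: segment the vessels, detect tufts
#' against the plexus surface, skeletonize, and per tuft compute volume,
#' nuclei (with curvature), connections, tunnels, depth and size class.
#'
#' @param volume the scene volume (channels `vessels`, `nuclei`).
#' @param plexus the plexus reference (`lsfm_surface` or `plexus_plane`).
#' @param config an [lsfm_config()].
#' @return list with `tufts` (data frame, one row per tuft) and `nuclei`
#'   (per-nucleus records with `tuft_id`).
#' @export
measure_tuft_scene <- function(volume, plexus, config = lsfm_config()) {
  vm <- segment_vessels(volume, method = config$segment_method,
                        threshold = config$segment_threshold,
                        min_size_um3 = config$min_component_um3)
  tufts <- detect_tufts(vm, plexus, min_height_um = config$tuft_min_height_um,
                        min_volume_um3 = config$tuft_min_volume_um3)
  if (nrow(tufts$records) == 0)
    return(list(tufts = data.frame(), nuclei = data.frame()))
  skel <- skeletonize_mask(vm)
  rows <- list(); nuc_all <- list()
  for (id in tufts$records$tuft_id) {
    vol_um3 <- tuft_volume(tufts, id)
    depth <- tuft_depth(tufts, id)
    ncon <- count_connections(skel, tufts, id)
    ntun <- tuft_topology(tufts, id)
    nuc <- detect_nuclei(volume, within = tufts$labels == id)
    curved <- if (nrow(nuc)) classify_nucleus_curvature(
      nuc, config$nucleus_bend_threshold, config$nucleus_angle_threshold_deg) else logical(0)
    if (nrow(nuc)) { nuc$curved <- curved; nuc$tuft_id <- id; nuc_all[[length(nuc_all) + 1]] <- nuc }
    rec <- tufts$records[tufts$records$tuft_id == id, ]
    rows[[length(rows) + 1]] <- data.frame(
      tuft_id = id, x_um = rec$x_um, y_um = rec$y_um, z_um = rec$z_um,
      volume_um3 = vol_um3, n_nuclei = nrow(nuc),
      n_curved_nuclei = sum(curved), n_connections = ncon, n_tunnels = ntun,
      depth_um = depth,
      size_class = if (nrow(nuc) >= 1) as.character(classify_tuft(nrow(nuc))) else NA_character_)
  }
  list(tufts = do.call(rbind, rows),
       nuclei = if (length(nuc_all)) do.call(rbind, nuc_all) else data.frame())
}

#' Run a measurement stage on files produced by [cmd_simulate()]
#'
#' @param stage one of `distortion`, `tufts`, `tracks`, `layers`, `polarity`.
#' @param inputs named list of input paths (see Details).
#' @param config an [lsfm_config()].
#' @param out_dir output directory.
#' @details Input keys: `distortion` needs `lsfm`, `confocal` (TIFFs from the
#'   distortion_pair preset; sites are taken along the target vessel).
#'   `tufts` needs `volume` and `truth` (for the plexus surface). `tracks`
#'   needs `tracks` (CSV) and optionally `kind` (`filopodia`/`bundles`).
#'   `layers` needs `volume`. `polarity` needs `nuclei` and `golgi` CSVs of
#'   centroids plus optional `reference`.
#' @return invisible list of written files.
#' @export
cmd_measure <- function(stage, inputs, config = lsfm_config(), out_dir = ".") {
  stages <- c("distortion", "tufts", "tracks", "layers", "polarity")
  if (!stage %in% stages)
    lsfm_usage_stop(sprintf("unknown stage '%s' (choose from: %s)", stage,
                            paste(stages, collapse = ", ")))
  for (p in unlist(inputs[vapply(inputs, is.character, logical(1))]))
    if (grepl("[./]", p) && !file.exists(p) && !dir.exists(p))
      lsfm_stop(sprintf("missing input file: %s", p))
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- character(0)
  if (stage == "distortion") {
    res <- measure_distortion_pair(read_volume(inputs$lsfm), read_volume(inputs$confocal),
                                   truth_path = inputs$truth, config = config)
    p1 <- file.path(out_dir, "diameters.csv")
    write.csv(res$measurements, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "distortion_report.json")
    jsonlite::write_json(list(groups = res$report$groups, tests = res$report$tests),
                         p2, auto_unbox = TRUE, digits = NA, force = TRUE)
    outs <- c(p1, p2)
  } else if (stage == "tufts") {
    vol <- read_volume(inputs$volume)
    truth <- jsonlite::read_json(inputs$truth, simplifyVector = TRUE)
    surf <- truth_surface(truth)
    res <- measure_tuft_scene(vol, surf, config)
    p1 <- file.path(out_dir, "tuft_table.csv"); write.csv(res$tufts, p1, row.names = FALSE)
    p2 <- file.path(out_dir, "nuclei_table.csv"); write.csv(res$nuclei, p2, row.names = FALSE)
    outs <- c(p1, p2)
    if (nrow(res$tufts) >= 3) {
      reg <- regress_morphometrics(res$tufts, "n_nuclei", "volume_um3")
      p3 <- file.path(out_dir, "regression.json")
      jsonlite::write_json(reg, p3, auto_unbox = TRUE, digits = NA)
      outs <- c(outs, p3)
    }
  } else if (stage == "tracks") {
    kind <- if (is.null(inputs$kind)) "bundles" else inputs$kind
    tracks <- read_tracks(inputs$tracks, dt_min = config$dt_min)
    stats <- if (kind == "filopodia") {
      lapply(tracks, function(tr) filopodium_stats(filopodium_lengths(tr),
                                                   config$dt_min, config$filopodium_eps_um))
    } else lapply(tracks, bundle_stats, dt_min = config$dt_min)
    summ <- summarize_condition(stats)
    p1 <- file.path(out_dir, "track_stats.csv")
    write.csv(do.call(rbind, lapply(seq_along(stats), function(i)
      data.frame(track_id = names(tracks)[i],
                 as.data.frame(stats[[i]][vapply(stats[[i]], function(v)
                   is.numeric(v) && length(v) == 1, logical(1))])))), p1, row.names = FALSE)
    p2 <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, p2, auto_unbox = TRUE, digits = NA, force = TRUE)
    outs <- c(p1, p2)
  } else if (stage == "layers") {
    vol <- read_volume(inputs$volume)
    arr <- vol_channel(vol, names(vol$channels)[1])
    d <- dim(arr)
    # default ROI: central 80% of the slab's mid slice and stride-sampled ones
    rois <- list()
    for (iz in seq(1, d[1], by = max(1, config$onl_stride_slices))) {
      poly <- rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.9, 0.9), c(0.1, 0.9)) *
        matrix(c((d[3] - 1) * vol$spacing[3], (d[2] - 1) * vol$spacing[2]), 4, 2, byrow = TRUE)
      rois[[length(rois) + 1]] <- layer_roi(iz, poly)
    }
    dens <- onl_density(vol, rois, channel = names(vol$channels)[1],
                        min_particle_um2 = config$onl_min_particle_um2)
    p1 <- file.path(out_dir, "layers.json")
    jsonlite::write_json(list(mean_density_per_um2 = dens$mean_density_per_um2,
                              per_slice = dens$per_slice), p1,
                         auto_unbox = TRUE, digits = NA)
    outs <- p1
  } else {
    nuc <- as.matrix(read.csv(inputs$nuclei))
    gol <- as.matrix(read.csv(inputs$golgi))
    ref <- if (is.null(inputs$reference)) c(1, 0, 0) else inputs$reference
    pol <- nucleus_golgi_polarity(nuc, gol, ref)
    p1 <- file.path(out_dir, "polarity.csv")
    write.csv(pol, p1, row.names = FALSE)
    outs <- p1
  }
  write_manifest(out_dir, paste("measure", stage), config,
                 seed = config$seed,
                 inputs = unlist(Filter(function(p) is.character(p) && file.exists(p), inputs)),
                 outputs = outs, t0 = t0)
  invisible(outs)
}

#' Surface model from a parsed truth JSON
#' @noRd
truth_surface <- function(truth) {
  s <- truth$surface
  if (identical(s$type, "plane")) surface_plane(s$z0)
  else structure(list(type = "spherical_cap", centre = as.numeric(s$centre),
                      radius = s$radius), class = "lsfm_surface")
}

#' Measure a correlative LSFM/confocal distortion pair
#'
#' Segments both volumes, skeletonizes, fits the local plexus plane at sites
#' spaced along the target vessel, and measures width/depth at each site in
#' both modalities, returning the combined measurement table and the group
#' comparison report.
#'
#' @param lsfm_vol,confocal_vol volumes from the distortion_pair preset.
#' @param truth_path optional truth JSON (for site positions; otherwise
#'   sites are taken along the mid-line of the volume).
#' @param config an [lsfm_config()].
#' @param n_sites number of measurement sites per modality.
#' @return list with `measurements` (data frame) and `report`
#'   ([compare_distortion()] result).
#' @export
measure_distortion_pair <- function(lsfm_vol, confocal_vol, truth_path = NULL,
                                    config = lsfm_config(), n_sites = 5) {
  measure_one <- function(vol, modality) {
    vm <- segment_vessels(vol, method = config$segment_method,
                          threshold = config$segment_threshold,
                          min_size_um3 = config$min_component_um3)
    skel <- skeletonize_mask(vm, prune_um = 4)
    d <- vol_dim(vol); sp <- vol$spacing
    cy <- (d[2] - 1) * sp[2] / 2
    xs <- seq(0.3, 0.7, length.out = n_sites) * (d[3] - 1) * sp[3]
    rows <- list()
    for (x0 in xs) {
      # site: skeleton point of the target vessel nearest to (x0, cy)
      pts <- skel$points
      cand <- pts[abs(pts[, 2] - cy) < 6, , drop = FALSE]
      if (nrow(cand) == 0) next
      site <- cand[which.min(abs(cand[, 1] - x0)), ]
      pl <- fit_plexus_plane(skel, site, fit_radius = config$plane_fit_radius_um)
      m <- tryCatch(measure_diameters(vm, site, pl, skel, modality = modality),
                    lsfm_error = function(e) NULL)
      if (!is.null(m)) rows[[length(rows) + 1]] <- m
    }
    do.call(rbind, rows)
  }
  ml <- measure_one(lsfm_vol, "lsfm")
  mc <- measure_one(confocal_vol, "confocal")
  list(measurements = rbind(ml, mc), report = compare_distortion(ml, mc))
}

#' Recompute summary statistics from a deposited source-data table
#'
#' Reads a per-figure source-data spreadsheet and recomputes its printed
#' summary statistics: the volume~nuclei and connections~nuclei (large
#' tufts) R² for the tuft figure, per-condition mean maximum filopodium
#' lengths, and the mean actin-bundle speed. When reference values are
#' supplied (defaults are the printed ones) a comparison table is printed.
#'
#' @param path XLSX or CSV source-data file.
#' @param figure_key as in [read_source_table()].
#' @param columns optional column rename map.
#' @param reference named numeric vector of printed values to compare
#'   against (NULL to skip the comparison).
#' @return named list of recomputed statistics.
#' @export
cmd_benchmark <- function(path, figure_key, columns = NULL, reference = NULL) {
  df <- read_source_table(path, figure_key, columns)
  out <- switch(
    figure_key,
    fig5_tufts = {
      res <- list(r2_volume_nuclei = regress_morphometrics(df, "n_nuclei", "volume_um3")$r_squared)
      if ("n_connections" %in% names(df)) {
        large <- df[df$n_nuclei > 20, ]
        if (nrow(large) >= 3)
          res$r2_connections_nuclei_large <-
            regress_morphometrics(large, "n_nuclei", "n_connections")$r_squared
        res$fold_connections <- tryCatch(class_fold_change(df, "n_connections"),
                                         lsfm_error = function(e) NA_real_)
        res$fold_volume <- tryCatch(class_fold_change(df, "volume_um3"),
                                    lsfm_error = function(e) NA_real_)
      }
      res
    },
    fig7_filopodia = {
      means <- tapply(df$max_length_um, df$condition, mean)
      setNames(as.list(as.numeric(means)),
               paste0("mean_max_length_um_", names(means)))
    },
    fig4_bundles = {
      sp <- df$path_length_um / df$duration_min
      list(mean_bundle_speed_um_min = mean(sp),
           mean_bundle_distance_um = mean(df$path_length_um))
    },
    fig3_vessels = {
      rep <- compare_distortion(df[df$modality == "lsfm", ],
                                df[df$modality == "confocal", ])
      list(mean_depth_lsfm_um = rep$groups$mean_depth_um[1],
           mean_depth_confocal_um = rep$groups$mean_depth_um[2],
           p_depth_student = rep$tests$depth_um$student$p.value)
    })
  if (is.null(reference)) reference <- benchmark_reference_values(figure_key)
  if (length(reference)) {
    common <- intersect(names(out), names(reference))
    if (length(common)) {
      cmp <- data.frame(statistic = common,
                        recomputed = unlist(out[common]),
                        printed = unlist(reference[common]))
      cmp$rel_diff <- (cmp$recomputed - cmp$printed) / cmp$printed
      print(cmp, row.names = FALSE)
    }
  }
  out
}

#' Printed reference statistics per figure key (for benchmark comparison)
#' @noRd
benchmark_reference_values <- function(figure_key) {
  switch(figure_key,
         fig5_tufts = list(r2_volume_nuclei = 0.83, r2_connections_nuclei_large = 0.61,
                           fold_connections = 2.5, fold_volume = 3),
         fig7_filopodia = list(mean_max_length_um_OIR = 4.3, mean_max_length_um_P5 = 14.84),
         fig4_bundles = list(mean_bundle_speed_um_min = 2.56),
         list())
}
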