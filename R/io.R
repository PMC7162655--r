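#' Write a volume to TIFF with a JSON metadata sidecar
#'
#' Pages are written channel-major (all z of channel 1, then channel 2, ...;
#' for 4D data frame-major then channel then z). Voxel spacing, axis order,
#' channel names and frame interval go into `<path>.json`, since baseline
#' TIFF tags cannot carry them portably.
#'
#' @param vol an [lsfm_volume()]; intensities are clipped to `[0, 1]` and
#'   stored as 32-bit float.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  d <- dim(vol$channels[[1]])
  is4d <- length(d) == 4
  pages <- list()
  if (is4d) {
    for (t in seq_len(d[1])) for (ch in names(vol$channels)) {
      a <- vol$channels[[ch]]
      for (iz in seq_len(d[2])) pages[[length(pages) + 1]] <- a[t, iz, , ]
    }
  } else {
    for (ch in names(vol$channels)) {
      a <- vol$channels[[ch]]
      for (iz in seq_len(d[1])) pages[[length(pages) + 1]] <- a[iz, , ]
    }
  }
  pages <- lapply(pages, function(m) { m[] <- pmin(1, pmax(0, m)); m })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(axes = if (is4d) "TCZYX" else "CZYX",
               shape_zyx = utils::tail(d, 3),
               n_frames = if (is4d) d[1] else 1L,
               channels = names(vol$channels),
               spacing_um = unname(vol$spacing),
               dt_min = vol$dt_min)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a TIFF/OME-style volume
#'
#' Reconstructs the channel arrays using the JSON sidecar written by
#' [write_volume()]. Plain TIFF stacks without a sidecar are treated as one
#' channel; voxel spacing then comes from `config$spacing_um`, else defaults
#' to 1 µm per axis with a warning.
#'
#' @param path `.tif` path.
#' @param config optional list with `spacing_um` (z, y, x) fallback.
#' @return an [lsfm_volume()].
#' @export
read_volume <- function(path, config = NULL) {
  if (!file.exists(path)) lsfm_stop(sprintf("cannot read volume: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  if (is.null(meta)) {
    if (length(pages) < 2) lsfm_stop("not a volume: single 2D image")
    spacing <- if (!is.null(config$spacing_um)) config$spacing_um else {
      warning("no spacing metadata or config: assuming 1 um per axis")
      c(1, 1, 1)
    }
    d <- c(length(pages), dim(pages[[1]]))
    arr <- array(0, dim = d)
    for (iz in seq_along(pages)) arr[iz, , ] <- pages[[iz]]
    return(lsfm_volume(list(intensity = arr), spacing = spacing))
  }
  dz <- meta$shape_zyx
  nch <- length(meta$channels)
  nt <- meta$n_frames
  channels <- list()
  p <- 1
  if (nt > 1) {
    for (ch in meta$channels) channels[[ch]] <- array(0, dim = c(nt, dz))
    for (t in seq_len(nt)) for (ch in meta$channels) for (iz in seq_len(dz[1])) {
      channels[[ch]][t, iz, , ] <- pages[[p]]; p <- p + 1
    }
  } else {
    for (ch in meta$channels) {
      arr <- array(0, dim = dz)
      for (iz in seq_len(dz[1])) { arr[iz, , ] <- pages[[p]]; p <- p + 1 }
      channels[[ch]] <- arr
    }
  }
  if (length(dz) < 3 || (nt == 1 && dz[1] < 2 && nch == 1))
    lsfm_stop("not a volume: single 2D image")
  lsfm_volume(channels, spacing = meta$spacing_um,
              dt_min = if (is.null(meta$dt_min)) NA_real_ else meta$dt_min)
}

# ---- tracks ----------------------------------------------------------------

#' Read time-lapse track tables
#'
#' Supports the package's native CSV (`track_id, frame, x_um, y_um[, z_um]`,
#' already in µm) and the ImageJ/Fiji Manual Tracking dialect (`Track n°`,
#' `Slice n°`, `X`, `Y` in pixels, converted with `pixel_size_um`; the slice
#' number is the frame). Frames are sorted within each track; duplicate
#' (track, frame) rows are an error.
#'
#' @param path CSV file.
#' @param dialect `"native"` or `"imagej_manual_tracking"`.
#' @param pixel_size_um lateral pixel size for the ImageJ dialect.
#' @param dt_min frame interval attached to each returned track.
#' @return list of `lsfm_track` objects (`id`, `frames`, `positions` n x 3
#'   µm, `dt_min`); empty list with a warning for an empty file.
#' @export
read_tracks <- function(path, dialect = c("native", "imagej_manual_tracking"),
                        pixel_size_um = 1, dt_min = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) lsfm_stop(sprintf("cannot read tracks: %s", path))
  df <- tryCatch(read.csv(path, check.names = FALSE), error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    warning("empty track file")
    return(list())
  }
  if (dialect == "imagej_manual_tracking") {
    nm <- tolower(gsub("[^a-z]", "", tolower(names(df))))
    pick <- function(what) {
      i <- which(nm == what)[1]
      if (is.na(i)) lsfm_stop(sprintf("ImageJ track table lacks a '%s' column (found: %s)",
                                      what, paste(names(df), collapse = ", ")))
      df[[i]]
    }
    z <- { i <- which(nm == "z")[1]; if (is.na(i)) 0 else df[[i]] * pixel_size_um }
    df <- data.frame(track_id = pick("trackn"), frame = pick("slicen"),
                     x_um = pick("x") * pixel_size_um, y_um = pick("y") * pixel_size_um,
                     z_um = z)
  } else {
    need <- c("track_id", "frame", "x_um", "y_um")
    if (!all(need %in% names(df)))
      lsfm_stop(sprintf("native track table needs columns %s (found: %s)",
                        paste(need, collapse = ", "), paste(names(df), collapse = ", ")))
    if (!"z_um" %in% names(df)) df$z_um <- 0
  }
  if (anyDuplicated(df[, c("track_id", "frame")]))
    lsfm_stop("duplicate (track, frame) rows in track table")
  lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$frame), ]
    structure(list(id = g$track_id[1], frames = g$frame,
                   positions = as.matrix(g[, c("x_um", "y_um", "z_um")]),
                   dt_min = dt_min),
              class = "lsfm_track")
  })
}

#' Write tracks in the native CSV dialect
#' @param tracks data frame with `track_id, frame, x_um, y_um, z_um`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

# ---- source-data spreadsheets ---------------------------------------------

#' Minimal XLSX worksheet reader (zip of SpreadsheetML)
#' @noRd
read_xlsx_sheet <- function(path) {
  tmp <- tempfile("xlsx")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  files <- utils::unzip(path, exdir = tmp)
  shared <- character(0)
  ss <- file.path(tmp, "xl", "sharedStrings.xml")
  if (file.exists(ss)) {
    doc <- xml2::read_xml(ss)
    shared <- vapply(xml2::xml_find_all(doc, ".//*[local-name()='si']"),
                     function(si) paste(xml2::xml_text(
                       xml2::xml_find_all(si, ".//*[local-name()='t']")), collapse = ""),
                     character(1))
  }
  sheet_files <- sort(grep("xl/worksheets/sheet[0-9]+\\.xml$", files, value = TRUE))
  if (!length(sheet_files)) lsfm_stop("no worksheet found in xlsx file")
  doc <- xml2::read_xml(sheet_files[1])
  rows <- xml2::xml_find_all(doc, ".//*[local-name()='row']")
  col_of <- function(ref) {
    letters_part <- gsub("[0-9]", "", ref)
    sum((utf8ToInt(letters_part) - utf8ToInt("A") + 1) *
          26^(rev(seq_len(nchar(letters_part))) - 1))
  }
  cells <- list()
  for (ri in seq_along(rows)) {
    cs <- xml2::xml_find_all(rows[[ri]], ".//*[local-name()='c']")
    for (cell in cs) {
      ref <- xml2::xml_attr(cell, "r")
      typ <- xml2::xml_attr(cell, "t")
      vnode <- xml2::xml_find_first(cell, ".//*[local-name()='v']")
      val <- if (!inherits(vnode, "xml_missing")) xml2::xml_text(vnode) else {
        tn <- xml2::xml_find_first(cell, ".//*[local-name()='t']")
        if (!inherits(tn, "xml_missing")) xml2::xml_text(tn) else NA_character_
      }
      if (identical(typ, "s")) val <- shared[as.integer(val) + 1]
      cells[[length(cells) + 1]] <- list(row = as.integer(gsub("[A-Z]", "", ref)),
                                         col = col_of(ref), value = val)
    }
  }
  if (!length(cells)) return(data.frame())
  nr <- max(vapply(cells, `[[`, integer(1), "row"))
  nc <- max(vapply(cells, function(c) as.integer(c$col), integer(1)))
  m <- matrix(NA_character_, nr, nc)
  for (cell in cells) m[cell$row, cell$col] <- cell$value
  header <- m[1, ]
  header[is.na(header)] <- paste0("V", which(is.na(header)))
  body <- m[-1, , drop = FALSE]
  out <- as.data.frame(body, stringsAsFactors = FALSE)
  names(out) <- header
  for (j in seq_along(out)) {
    num <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(num[!is.na(out[[j]])])) out[[j]] <- num
  }
  out
}

#' Expected column sets per source-data figure key
#' @noRd
source_table_columns <- function() list(
  fig3_vessels = c("vessel_id", "modality", "width_um", "depth_um"),
  fig4_bundles = c("bundle_id", "path_length_um", "duration_min"),
  fig5_tufts = c("tuft_id", "volume_um3", "n_nuclei"),
  fig7_filopodia = c("filopodium_id", "condition", "max_length_um"))

#' Read a deposited source-data table (XLSX or CSV)
#'
#' Normalises a per-figure measurement spreadsheet to a long-format data
#' frame (one row per vessel / tuft / bundle / filopodium). Column headers
#' may be remapped via `columns` (named vector: standard name = header in
#' the file) since deposited spreadsheets vary in their labels.
#'
#' @param path `.xlsx` or `.csv` file.
#' @param figure_key one of `"fig3_vessels"`, `"fig4_bundles"`,
#'   `"fig5_tufts"`, `"fig7_filopodia"`.
#' @param columns optional rename map, e.g.
#'   `c(volume_um3 = "Tuft volume (um3)")`.
#' @return data frame with at least the key's required columns.
#' @export
read_source_table <- function(path, figure_key, columns = NULL) {
  keys <- source_table_columns()
  if (!figure_key %in% names(keys))
    lsfm_stop(sprintf("unknown figure_key '%s' (known: %s)", figure_key,
                      paste(names(keys), collapse = ", ")))
  if (!file.exists(path)) lsfm_stop(sprintf("cannot read source table: %s", path))
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    read.csv(path, check.names = FALSE) else read_xlsx_sheet(path)
  if (!is.null(columns)) {
    for (std in names(columns)) {
      if (!columns[[std]] %in% names(df))
        lsfm_stop(sprintf("mapped column '%s' not in table (found: %s)",
                          columns[[std]], paste(names(df), collapse = ", ")))
      names(df)[names(df) == columns[[std]]] <- std
    }
  }
  need <- keys[[figure_key]]
  missing <- setdiff(need, names(df))
  if (length(missing))
    lsfm_stop(sprintf("source table lacks columns %s (found: %s)",
                      paste(missing, collapse = ", "), paste(names(df), collapse = ", ")))
  df
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' Every key consumed anywhere in the pipeline, with its default. Unknown
#' keys are rejected by [lsfm_config()].
#' @return named list of defaults.
#' @export
lsfm_config_defaults <- function() list(
  spacing_um = c(1, 1, 1),        # voxel spacing (z, y, x), um
  dt_min = 1,                     # time-lapse frame interval, minutes
  segment_method = "otsu",        # vessel segmentation method
  segment_threshold = NULL,       # fixed threshold when not otsu
  min_component_um3 = 20,         # segmentation cleanup size
  plane_fit_radius_um = 30,       # plexus plane neighbourhood
  tuft_min_height_um = 10,        # protrusion cutoff above the plexus
  tuft_min_volume_um3 = 200,      # tuft size filter
  nucleus_bend_threshold = 1.2,   # curved-nucleus arc/chord cutoff
  nucleus_angle_threshold_deg = 60,
  filopodium_eps_um = 0.5,        # presence threshold
  class_boundary_nuclei = 20,     # medium/large boundary
  onl_stride_slices = 50,         # slice stride for layer sampling
  onl_min_particle_um2 = 5,
  seed = 1)

#' Build a validated run configuration
#'
#' @param ... overrides of [lsfm_config_defaults()] keys.
#' @param yaml optional YAML file of overrides (applied before `...`).
#' @return named list (`lsfm_config`).
#' @export
lsfm_config <- function(..., yaml = NULL) {
  cfg <- lsfm_config_defaults()
  apply_over <- function(cfg, over) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      lsfm_usage_stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    for (k in names(over)) cfg[[k]] <- over[[k]]
    cfg
  }
  if (!is.null(yaml)) cfg <- apply_over(cfg, yaml::read_yaml(yaml))
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over)
  structure(cfg, class = "lsfm_config")
}
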