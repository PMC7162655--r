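test_that("volumes round-trip through TIFF with metadata intact", {
  vol <- lsfm_volume(list(a = array(runif(24 * 20 * 16), dim = c(24, 20, 16)),
                          b = array(runif(24 * 20 * 16), dim = c(24, 20, 16))),
                     spacing = c(2, 0.5, 0.5))
  p <- tempfile(fileext = ".tif")
  write_volume(vol, p)
  v2 <- read_volume(p)
  expect_equal(v2$channels$a, vol$channels$a, tolerance = 1e-6)
  expect_equal(v2$channels$b, vol$channels$b, tolerance = 1e-6)
  expect_equal(unname(v2$spacing), c(2, 0.5, 0.5))
  expect_equal(names(v2$channels), c("a", "b"))
})

test_that("4D time-lapse volumes round-trip", {
  vol <- lsfm_volume(list(actin = array(runif(3 * 8 * 10 * 12), dim = c(3, 8, 10, 12))),
                     spacing = c(1, 1, 1), dt_min = 0.75)
  p <- tempfile(fileext = ".tif")
  write_volume(vol, p)
  v2 <- read_volume(p)
  expect_equal(v2$channels$actin, vol$channels$actin, tolerance = 1e-6)
  expect_equal(v2$dt_min, 0.75)
})

test_that("plain TIFF stacks fall back to config spacing, then 1 um", {
  arr <- array(runif(5 * 6 * 7), dim = c(5, 6, 7))
  p <- tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:5, function(i) arr[i, , ]), p, bits.per.sample = 32L)
  v <- read_volume(p, config = list(spacing_um = c(2, 1, 1)))
  expect_equal(unname(v$spacing), c(2, 1, 1))
  expect_warning(v1 <- read_volume(p), "assuming 1 um")
  expect_equal(unname(v1$spacing), c(1, 1, 1))
})

test_that("a single 2D image is not a volume", {
  p <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(12), 3, 4), p, bits.per.sample = 32L)
  expect_error(read_volume(p), "not a volume")
  expect_error(lsfm_volume(list(a = matrix(1, 2, 2))), "not a volume|3D")
})

test_that("native track tables parse into one Track per id", {
  df <- data.frame(track_id = rep(1:2, each = 3), frame = rep(c(2, 0, 1), 2),
                   x_um = 1:6, y_um = 1:6, z_um = 0)
  p <- tempfile(fileext = ".csv")
  write_tracks(df, p)
  tr <- read_tracks(p)
  expect_length(tr, 2)
  expect_equal(tr[[1]]$frames, c(0, 1, 2)) # sorted
  expect_equal(nrow(tr[[1]]$positions), 3)
})

test_that("ImageJ manual-tracking pixel coordinates convert to um", {
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(" " = 1:2, "Track n" = 1, "Slice n" = 1:2,
                       X = c(10, 20), Y = c(4, 8), check.names = FALSE),
            p, row.names = FALSE)
  tr <- read_tracks(p, dialect = "imagej_manual_tracking", pixel_size_um = 0.5)
  expect_equal(unname(tr[[1]]$positions[, 1]), c(5, 10))
  expect_equal(unname(tr[[1]]$positions[, 2]), c(2, 4))
})

test_that("degenerate track files are handled", {
  p <- tempfile(fileext = ".csv")
  writeLines("track_id,frame,x_um,y_um,z_um", p)
  expect_warning(tr <- read_tracks(p), "empty")
  expect_length(tr, 0)
  dup <- data.frame(track_id = 1, frame = c(0, 0), x_um = 1:2, y_um = 1, z_um = 0)
  write.csv(dup, p, row.names = FALSE)
  expect_error(read_tracks(p), "duplicate")
})

test_that("source tables read from xlsx and csv with column mapping", {
  px <- tempfile(fileext = ".xlsx")
  write_toy_xlsx(px, c("tuft_id", "Tuft volume", "n_nuclei"),
                 lapply(1:5, function(i) list(i, 2.5 * i + 1, i)))
  df <- read_source_table(px, "fig5_tufts", columns = c(volume_um3 = "Tuft volume"))
  expect_equal(nrow(df), 5)
  expect_equal(df$volume_um3, 2.5 * (1:5) + 1)
  expect_error(read_source_table(px, "no_such_key"), "unknown figure_key")
  expect_error(read_source_table(px, "fig7_filopodia"), "lacks columns")
  # csv round trip gives the same table
  pc <- tempfile(fileext = ".csv")
  write.csv(df, pc, row.names = FALSE)
  df2 <- read_source_table(pc, "fig5_tufts")
  expect_equal(df2[names(df)], df)
})

test_that("run configuration validates keys and reads YAML", {
  cfg <- lsfm_config(tuft_min_height_um = 12)
  expect_equal(cfg$tuft_min_height_um, 12)
  expect_equal(cfg$class_boundary_nuclei, 20)
  expect_error(lsfm_config(not_a_key = 1), "unknown config key")
  y <- tempfile(fileext = ".yaml")
  writeLines("dt_min: 0.75\nplane_fit_radius_um: 40", y)
  cfg2 <- lsfm_config(yaml = y)
  expect_equal(cfg2$dt_min, 0.75)
  expect_equal(cfg2$plane_fit_radius_um, 40)
})
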