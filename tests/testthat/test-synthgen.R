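test_that("a straight tube rasterizes to the analytic cylinder volume", {
  # r = 5 um tube along y on a flat surface, spacing 1 um
  L <- 80
  spec <- scene_spec(seed = 1, volume_shape = c(32, 81, 24),
                     surface = surface_plane(16),
                     vessels = list(list(points = cbind(12, c(0, L), 16), radius = 5)),
                     noise = default_noise())
  gen <- make_plexus_volume(spec)
  expect_equal(sum(gen$truth$clean_mask), pi * 25 * (L + 1), tolerance = 0.05)
  expect_equal(gen$truth$vessels[[1]]$expected_width_um, 10)
})

test_that("a scene with zero vessels yields an empty mask and truth", {
  spec <- scene_spec(seed = 1, volume_shape = c(16, 24, 24),
                     surface = surface_plane(8), vessels = list())
  gen <- make_plexus_volume(spec)
  expect_false(any(gen$truth$clean_mask))
  expect_length(gen$truth$vessels, 0)
})

test_that("generation is bit-identical under the same spec and seed", {
  spec <- scene_spec(seed = 7, volume_shape = c(24, 40, 40),
                     surface = surface_plane(10),
                     vessels = list(list(points = cbind(c(0, 39), 20, 10), radius = 4)))
  g1 <- make_plexus_volume(spec)
  g2 <- make_plexus_volume(spec)
  expect_identical(g1$volume$channels$vessels, g2$volume$channels$vessels)
})

test_that("unresolvable vessels (radius < 2x max spacing) are rejected", {
  spec <- scene_spec(seed = 1, volume_shape = c(24, 40, 40), spacing = c(2, 0.5, 0.5),
                     surface = surface_plane(10),
                     vessels = list(list(points = cbind(c(0, 19), 10, 10), radius = 3)))
  expect_error(make_plexus_volume(spec), "unresolvable")
})

test_that("anisotropic spacing is honoured by the rasterizer", {
  spec <- scene_spec(seed = 2, volume_shape = c(24, 80, 80), spacing = c(2, 0.5, 0.5),
                     surface = surface_plane(20),
                     vessels = list(list(points = cbind(c(0, 39.5), 20, 20), radius = 5)))
  gen <- make_plexus_volume(spec)
  vol_um3 <- sum(gen$truth$clean_mask) * prod(spec$spacing)
  # 2 um z-pitch against a 10 um tube: allow one voxel of surface quantization
  expect_equal(vol_um3, pi * 25 * 40, tolerance = 0.1)
})

test_that("flat-mount distortion obeys its contract", {
  spec <- scene_spec(seed = 3, volume_shape = c(32, 48, 48),
                     surface = surface_plane(16),
                     vessels = list(list(points = cbind(c(0, 47), 24, 16), radius = 5)))
  gen <- make_plexus_volume(spec)
  # identity
  same <- apply_flatmount_distortion(gen$volume, gen$truth, compression = 1, unbend = FALSE)
  expect_identical(same$volume$channels$vessels, gen$volume$channels$vessels)
  # depth scales by the compression factor, width is invariant
  dis <- apply_flatmount_distortion(gen$volume, gen$truth, compression = 0.4)
  expect_equal(dis$truth$vessels[[1]]$expected_depth_um, 4)
  expect_equal(dis$truth$vessels[[1]]$expected_width_um, 10)
  # composition
  dis2 <- apply_flatmount_distortion(dis$volume, dis$truth, compression = 0.4)
  expect_equal(dis2$truth$vessels[[1]]$expected_depth_um, 1.6)
  expect_error(apply_flatmount_distortion(gen$volume, gen$truth, compression = 1.4),
               "compression")
})

test_that("tuft scenes realise the requested counts in the clean masks", {
  gen <- tuft_fixture(5)
  truth <- gen$truth
  # conservation: rendered nuclei blobs equal the sum of n_nuclei
  lab <- label_components(truth$clean_nuclei_mask, 26)
  expect_equal(attr(lab, "n_components"),
               sum(vapply(truth$tufts, `[[`, integer(1), "n_nuclei")))
  # topology by construction: Betti oracle on each tuft's clean body mask
  d <- truth$dim
  for (tf in truth$tufts) {
    m <- array(FALSE, dim = d)
    m[tf$mask_idx] <- TRUE
    co <- which(m, arr.ind = TRUE)
    zr <- range(co[, 1]); yr <- range(co[, 2]); xr <- range(co[, 3])
    crop <- m[max(1, zr[1] - 2):min(d[1], zr[2] + 2),
              max(1, yr[1] - 2):min(d[2], yr[2] + 2),
              max(1, xr[1] - 2):min(d[3], xr[2] + 2), drop = FALSE]
    expect_equal(unname(betti_oracle(crop)["b1"]), tf$n_tunnels,
                 info = sprintf("tuft %d", tf$id))
  }
})

test_that("invalid tuft specifications are rejected", {
  expect_error(tuft_spec(c(10, 10), n_nuclei = 0), "n_nuclei")
  expect_error(tuft_spec(c(10, 10), n_nuclei = 2, n_tunnels = 3), "unsupported")
  expect_error(tuft_spec(c(10, 10), n_nuclei = 2, n_connections = 0), "n_connections")
})

test_that("scripted time lapse reproduces its closed-form kinematics", {
  fil <- list(list(base = c(20, 20, 10), dir = c(1, 0, 0),
                   lengths = c(0, 2, 4, 6, 4, 2, 0)))
  bun <- list(list(positions = cbind(10 + 0:6 * 1, 30, 10)))
  tl <- make_timelapse(fil, bun, dt_min = 1, seed = 2, render = FALSE)
  f <- tl$truth$filopodia[[1]]
  expect_equal(f$max_length_um, 6)
  expect_equal(f$lifetime_min, 5)
  b <- tl$truth$bundles[[1]]
  expect_equal(b$path_length_um, 6)
  expect_equal(b$average_speed_um_min, 1)
  # bundle moving 1 um/frame for 10 frames -> path length 10
  b10 <- make_timelapse(bundles = list(list(positions = cbind(5 + 0:10, 12, 8))),
                        dt_min = 1, seed = 1, render = FALSE)
  expect_equal(b10$truth$bundles[[1]]$path_length_um, 10)
})

test_that("time lapse emission is deterministic and rejects bad intervals", {
  fil <- scripted_filopodia_population(3, "OIR", n_frames = 12, seed = 9)
  t1 <- make_timelapse(fil, dt_min = 1, seed = 9, volume_shape = c(16, 48, 48))
  t2 <- make_timelapse(fil, dt_min = 1, seed = 9, volume_shape = c(16, 48, 48))
  expect_identical(t1$tracks, t2$tracks)
  expect_identical(t1$volume$channels$actin, t2$volume$channels$actin)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tracks(t1$tracks, f1); write_tracks(t2$tracks, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  expect_error(make_timelapse(fil, dt_min = c(1, 2), seed = 1), "constant")
  expect_error(make_timelapse(fil, dt_min = 0, seed = 1), "positive|constant")
})

test_that("layered volumes realise density and thickness ground truth", {
  lay <- make_layered_volume(5e-3, 60, seed = 3)
  area <- lay$truth$area_um2
  expect_equal(lay$truth$n_nuclei, round(5e-3 * area))
  expect_equal(lay$truth$density_per_um2, lay$truth$n_nuclei / area)
  expect_equal(lay$truth$thickness_um, 60)
  # density 0 -> empty channel
  empty <- make_layered_volume(0, 60, volume_shape = c(20, 30, 30), seed = 1)
  expect_equal(empty$truth$n_nuclei, 0)
  expect_false(any(empty$truth$clean_mask))
  expect_error(make_layered_volume(5e-3, 0), "thickness")
})
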