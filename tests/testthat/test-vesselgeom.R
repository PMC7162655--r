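test_that("otsu segmentation recovers at least 95% of the true tube", {
  gen <- plexus_fixture()
  vm <- segment_vessels(gen$volume)
  truth_mask <- gen$truth$clean_mask
  expect_gte(sum(vm$mask & truth_mask) / sum(truth_mask), 0.95)
})

test_that("segmentation edge cases behave as specified", {
  zero <- lsfm_volume(list(vessels = array(0, dim = c(8, 8, 8))))
  expect_error(segment_vessels(zero), "no vessels")
  pos <- lsfm_volume(list(vessels = array(runif(512, 0.1, 1), dim = c(8, 8, 8))))
  vm <- segment_vessels(pos, method = "fixed_threshold", threshold = 0,
                        min_size_um3 = 0)
  expect_true(all(vm$mask))
})

test_that("plane fitting is exact on planar skeletons and equivariant", {
  set.seed(1)
  pts <- cbind(runif(40, 0, 20), runif(40, 0, 20), 5)
  fake <- list(points = pts, voxels = NULL)
  pl <- fit_plexus_plane(fake, site = c(10, 10, 5), fit_radius = 30)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-10)
  expect_equal(pl$fit_residual, 0, tolerance = 1e-10)
  # rigid 30 degree rotation about x rotates the normal by 30 degrees
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- list(points = pts %*% t(R), voxels = NULL)
  pl2 <- fit_plexus_plane(rot, site = as.numeric(c(10, 10, 5) %*% t(R)), fit_radius = 30)
  expect_equal(abs(sum(pl2$normal * (R %*% c(0, 0, 1)))), 1, tolerance = 1e-10)
  expect_equal(pl2$fit_residual, 0, tolerance = 1e-8)
})

test_that("plane fitting on a 1700 um sphere recovers the surface normal within 3 degrees", {
  set.seed(2)
  Rs <- 1700
  # skeleton points scattered on the sphere cap around the apex
  th <- runif(200, 0, 2 * pi); rho <- sqrt(runif(200)) * 50
  x <- rho * cos(th); y <- rho * sin(th)
  z <- sqrt(Rs^2 - x^2 - y^2) - Rs # apex at 0
  fake <- list(points = cbind(x, y, z), voxels = NULL)
  pl <- fit_plexus_plane(fake, site = c(0, 0, 0), fit_radius = 50)
  ang <- acos(abs(pl$normal[3])) * 180 / pi
  expect_lt(ang, 3)
})

test_that("plane fitting demands enough neighbourhood support", {
  fake <- list(points = cbind(1:5, 1:5, 0), voxels = NULL)
  expect_error(fit_plexus_plane(fake, site = c(0, 0, 0), fit_radius = 10),
               "too sparse")
})

test_that("diameters of an undistorted tube read 2r in width and depth", {
  gen <- plexus_fixture() # target radius 8
  vm <- segment_vessels(gen$volume)
  sk <- skeletonize_mask(vm, prune_um = 4)
  site <- centre_site(gen$volume, gen$truth$surface)
  pl <- fit_plexus_plane(sk, site, fit_radius = 30)
  m <- measure_diameters(vm, site, pl, sk)
  expect_equal(m$width_um, 16, tolerance = 1 / 16)
  expect_equal(m$depth_um, 16, tolerance = 1 / 16)
  # max in-plane width is at least the perpendicular width
  m2 <- measure_diameters(vm, site, pl, sk, width_mode = "max_inplane")
  expect_gte(m2$width_um, m$width_um - 1e-6)
})

test_that("after 0.4 compression the depth shrinks and the width does not", {
  gen <- plexus_fixture()
  dis <- apply_flatmount_distortion(gen$volume, gen$truth, compression = 0.4,
                                    unbend = TRUE)
  vm <- segment_vessels(dis$volume)
  sk <- skeletonize_mask(vm, prune_um = 4)
  site <- centre_site(dis$volume, dis$truth$surface)
  pl <- fit_plexus_plane(sk, site, fit_radius = 30)
  m <- measure_diameters(vm, site, pl, sk, modality = "confocal")
  expect_equal(m$width_um, 16, tolerance = 1 / 16)
  expect_equal(m$depth_um, 6.4, tolerance = 1 / 6) # 0.4 x 16
})

test_that("diameter measurement is equivariant under a rigid rotation", {
  # the same tube+plane measured axis-aligned and rotated 25 degrees about y
  # (centreline off-lattice so boundary voxels are not knife-edge cases)
  d <- c(64L, 64L, 64L)
  ctr <- c(32.3, 32.4, 31.7)
  measure_tilted <- function(th_deg) {
    th <- th_deg * pi / 180
    axis <- c(cos(th), 0, sin(th)) # tilted in the x-z plane
    pts <- rbind(ctr - 45 * axis, ctr + 45 * axis)
    raw <- retinalsfm:::raster_tube(array(FALSE, dim = d), c(1, 1, 1), pts, 5)
    set.seed(1)
    vol <- lsfm_volume(list(vessels = retinalsfm:::render_channel(raw, c(1, 1, 1),
                                                                  default_noise())))
    vm <- segment_vessels(vol, method = "fixed_threshold", threshold = 0.5)
    skel <- skeletonize_mask(vm, prune_um = 4)
    plane <- list(normal = c(-sin(th), 0, cos(th)), anchor = ctr)
    measure_diameters(vm, ctr, plane, skel)
  }
  m0 <- measure_tilted(0)
  m25 <- measure_tilted(25)
  expect_lt(abs(m25$width_um - m0$width_um), 1)
  expect_lt(abs(m25$depth_um - m0$depth_um), 1)
})

test_that("sites whose vessel axis is near the plane normal are rejected", {
  d <- c(64L, 24L, 24L)
  pts <- rbind(c(12, 12, 0), c(12, 12, 63))
  mask <- retinalsfm:::raster_tube(array(FALSE, dim = d), c(1, 1, 1), pts, 5)
  skel <- skeletonize_mask(mask, spacing = c(1, 1, 1), prune_um = 4)
  plane <- list(normal = c(0, 0, 1), anchor = c(12, 12, 32))
  expect_error(measure_diameters(mask, c(12, 12, 32), plane, skel, spacing = c(1, 1, 1)),
               "not measurable")
})

test_that("group comparison matches the closed-form Student t-test", {
  mk <- function(d, w, modality) data.frame(width_um = w, depth_um = d,
                                            aspect = w / d, modality = modality)
  a <- mk(c(1, 2, 3), 10, "lsfm"); b <- mk(c(4, 5, 6), 10, "confocal")
  rep <- compare_distortion(a, b)
  # closed form: pooled variance two-sample t
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), 4, lower.tail = FALSE)
  expect_equal(rep$tests$depth_um$student$statistic, t_hand, tolerance = 1e-12)
  expect_equal(rep$tests$depth_um$student$p.value, p_hand, tolerance = 1e-12)
  # identical groups: degenerate, t = 0, p = 1
  rep0 <- compare_distortion(mk(c(2, 2), 8, "lsfm"), mk(c(2, 2), 8, "confocal"))
  expect_equal(rep0$tests$depth_um$student$statistic, 0)
  expect_equal(rep0$tests$depth_um$student$p.value, 1)
  expect_true(rep0$tests$depth_um$student$degenerate)
  # the study's group sizes are accepted
  set.seed(4)
  big <- compare_distortion(mk(rnorm(60, 10), 12, "lsfm"), mk(rnorm(28, 6), 12, "confocal"))
  expect_equal(big$groups$n, c(60, 28))
  expect_lt(big$tests$depth_um$student$p.value, 1e-6)
  expect_error(compare_distortion(mk(1, 1, "lsfm"), mk(c(1, 2), 1, "confocal")),
               "at least 2")
})
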