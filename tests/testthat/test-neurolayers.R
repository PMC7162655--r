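test_that("layer ROIs validate their polygons", {
  roi <- layer_roi(1, rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  expect_equal(roi$area_um2, 100)
  expect_error(layer_roi(1, rbind(c(0, 0), c(1, 1))), "3 vertices")
})

test_that("areal nuclei density is recovered from a layered phantom", {
  lay <- make_layered_volume(5e-3, 60, seed = 3)
  rois <- list(layer_roi(10, rbind(c(5, 5), c(94, 5), c(94, 94), c(5, 94))))
  d <- onl_density(lay$volume, rois)
  # Poisson-level tolerance around the realized density
  expect_equal(d$mean_density_per_um2, lay$truth$density_per_um2, tolerance = 0.15)
})

test_that("density edge cases: empty channel and dominant particle filter", {
  lay <- suppressWarnings(make_layered_volume(5e-3, 60, volume_shape = c(40, 60, 60), seed = 4))
  rois <- list(layer_roi(5, rbind(c(5, 5), c(54, 5), c(54, 54), c(5, 54))))
  # min particle size far above any nucleus cross-section -> density 0
  d0 <- onl_density(lay$volume, rois, min_particle_um2 = 1e4)
  expect_equal(d0$mean_density_per_um2, 0)
  empty <- lsfm_volume(list(nuclei = array(0, dim = c(10, 30, 30))))
  de <- onl_density(empty, list(layer_roi(2, rbind(c(2, 2), c(25, 2), c(25, 25), c(2, 25)))))
  expect_equal(de$mean_density_per_um2, 0)
})

test_that("slab thickness is measured to within 2 um and is rotation invariant", {
  d <- c(80L, 60L, 60L)
  co <- retinalsfm:::voxel_coords(d, c(1, 1, 1))
  slab <- array(co$Z >= 12 & co$Z < 72, dim = d)
  th <- onl_thickness(slab, stride = 20)
  expect_equal(th$mean_thickness_um, 60, tolerance = 2 / 60)
  # in-plane rotation (swap the lateral axes) leaves thickness unchanged
  rot <- aperm(slab, c(1, 3, 2))
  th2 <- onl_thickness(rot, stride = 20)
  expect_equal(th2$mean_thickness_um, th$mean_thickness_um)
})

test_that("manual line lengths average per slice and overall", {
  th <- onl_thickness(lines_um = list(c(10, 20, 30), c(20, 20, 20)))
  expect_equal(th$per_slice$thickness_um, c(20, 20))
  expect_equal(th$mean_thickness_um, 20)
})

test_that("a stride larger than the stack warns and still estimates", {
  d <- c(20L, 30L, 30L)
  co <- retinalsfm:::voxel_coords(d, c(1, 1, 1))
  slab <- array(co$Z >= 2 & co$Z < 17, dim = d)
  expect_warning(th <- onl_thickness(slab, stride = 100), "single-slice")
  expect_equal(th$mean_thickness_um, 15, tolerance = 0.15)
})

test_that("the density estimator is unbiased over repeated phantoms", {
  vals <- vapply(1:8, function(s) {
    lay <- suppressWarnings(make_layered_volume(4e-3, 50, volume_shape = c(60, 80, 80),
                                                seed = 100 + s))
    rois <- list(layer_roi(5, rbind(c(6, 6), c(73, 6), c(73, 73), c(6, 73))))
    onl_density(lay$volume, rois)$mean_density_per_um2
  }, numeric(1))
  expect_equal(mean(vals), 4e-3, tolerance = 0.08)
})
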