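test_that("tufts are detected at their generated anchors", {
  gen <- tuft_fixture(5)
  m <- gen$measured$tufts
  expect_equal(nrow(m), length(gen$truth$tufts))
  for (tf in gen$truth$tufts) {
    d2 <- (m$x_um - tf$anchor[1])^2 + (m$y_um - tf$anchor[2])^2
    expect_lt(min(d2), 30^2)
  }
})

test_that("a flat plexus or an excessive height cutoff yields zero tufts", {
  gen <- plexus_fixture()
  vm <- segment_vessels(gen$volume)
  ts <- detect_tufts(vm, gen$truth$surface, min_height_um = 10)
  expect_equal(nrow(ts$records), 0)
  tg <- tuft_fixture(5)
  vm2 <- segment_vessels(tg$volume)
  ts2 <- detect_tufts(vm2, tg$truth$surface, min_height_um = 500)
  expect_equal(nrow(ts2$records), 0)
  expect_error(detect_tufts(vm, NULL), "no plexus")
})

test_that("tuft volume is voxel count times voxel volume", {
  # digital ellipsoid semi-axes (10, 5, 5) um at 1 um spacing
  d <- c(24L, 24L, 44L)
  g <- expand.grid(z = 1:24, y = 1:24, x = 1:44)
  ell <- array(((g$x - 22) / 10)^2 + ((g$y - 12) / 5)^2 + ((g$z - 12) / 5)^2 <= 1, dim = d)
  labels <- array(0L, dim = d); labels[ell] <- 1L
  expect_equal(tuft_volume(labels, 1, spacing = c(1, 1, 1)), 4 / 3 * pi * 250,
               tolerance = 0.05)
  # single voxel at anisotropic spacing
  one <- array(0L, dim = c(2, 2, 2)); one[1] <- 1L
  expect_equal(tuft_volume(one, 1, spacing = c(2, 1, 1)), 2)
  # doubling the spacing per axis scales the volume by 8
  expect_equal(tuft_volume(labels, 1, spacing = c(2, 2, 2)),
               8 * tuft_volume(labels, 1, spacing = c(1, 1, 1)))
})

test_that("size classes follow the published nuclei boundaries", {
  expect_equal(as.character(classify_tuft(c(2, 3, 4, 20, 21, 100))),
               c("small", "small", "medium", "medium", "large", "large"))
  expect_error(classify_tuft(0), "n_nuclei")
})

test_that("morphometrics recover the generated tuft ground truth", {
  gen <- tuft_fixture(5)
  m <- gen$measured$tufts
  co <- retinalsfm:::voxel_coords(gen$truth$dim, gen$truth$spacing)
  for (tf in gen$truth$tufts) {
    j <- which.min((m$x_um - tf$anchor[1])^2 + (m$y_um - tf$anchor[2])^2)
    expect_equal(m$n_nuclei[j], tf$n_nuclei, info = sprintf("tuft %d nuclei", tf$id))
    expect_equal(m$n_connections[j], tf$n_connections, info = sprintf("tuft %d connections", tf$id))
    expect_equal(m$n_tunnels[j], tf$n_tunnels, info = sprintf("tuft %d tunnels", tf$id))
    expect_equal(as.character(m$size_class[j]),
                 as.character(classify_tuft(tf$n_nuclei)))
    hh <- surface_height(gen$truth$surface,
                         cbind(co$X[tf$mask_idx], co$Y[tf$mask_idx], co$Z[tf$mask_idx]))
    truth_vol <- sum(hh > 10) * prod(gen$truth$spacing)
    expect_equal(m$volume_um3[j], truth_vol, tolerance = 0.1)
    expect_equal(m$depth_um[j], tf$protrusion_height_um, tolerance = 2 / tf$protrusion_height_um)
  }
})

test_that("connection counts are stable to small height perturbations", {
  gen <- tuft_fixture(5)
  vm <- segment_vessels(gen$volume)
  tufts <- detect_tufts(vm, gen$truth$surface)
  skel <- skeletonize_mask(vm)
  id <- tufts$records$tuft_id[which.max(tufts$records$volume_um3)]
  base <- count_connections(skel, tufts, id)
  expect_equal(count_connections(skel, tufts, id, min_height_um = 8), base)
  expect_equal(count_connections(skel, tufts, id, min_height_um = 12), base)
})

test_that("tuft topology equals the independent Euler oracle on phantoms", {
  shapes <- list(list(phantom_ball(5), 0), list(phantom_torus(), 1),
                 list(phantom_double_torus(), 2),
                 list(phantom_random_blob(3), NA))
  for (s in shapes) {
    m <- s[[1]]
    got <- tuft_topology(m, largest_component = FALSE)
    expect_equal(got, unname(betti_oracle(m)["b1"]))
    if (!is.na(s[[2]])) expect_equal(got, s[[2]])
  }
  expect_error(tuft_topology(array(TRUE, dim = c(3, 3, 3)), largest_component = FALSE),
               "pad required")
})

test_that("touching nuclei are split by the watershed while single bent nuclei are not", {
  d <- c(24L, 40L, 48L)
  g <- expand.grid(z = 1:24, y = 1:40, x = 1:48)
  two <- array((g$z - 12)^2 + (g$y - 20)^2 + (g$x - 18)^2 <= 16 |
                 (g$z - 12)^2 + (g$y - 20)^2 + (g$x - 27)^2 <= 16, dim = d)
  set.seed(1)
  arr <- retinalsfm:::render_channel(two, c(1, 1, 1), default_noise())
  nr <- detect_nuclei(lsfm_volume(list(nuclei = arr)))
  expect_equal(nrow(nr), 2)
  # a single bent capsule must stay one nucleus
  poly <- retinalsfm:::nucleus_polyline(c(24, 20, 12), c(1, 0, 0), c(0, 1, 0), 12, 200)
  bent <- retinalsfm:::raster_tube(array(FALSE, dim = d), c(1, 1, 1), poly, 1.7)
  arr2 <- retinalsfm:::render_channel(bent, c(1, 1, 1), default_noise())
  nr2 <- detect_nuclei(lsfm_volume(list(nuclei = arr2)))
  expect_equal(nrow(nr2), 1)
  expect_true(classify_nucleus_curvature(nr2))
})

test_that("two parallel straight nuclei read as two flat records, not one curved", {
  d <- c(24L, 40L, 40L)
  m <- array(FALSE, dim = d)
  for (x0 in c(17, 23))
    m <- retinalsfm:::raster_tube(m, c(1, 1, 1), rbind(c(x0, 20, 6), c(x0, 20, 15)), 1.7)
  set.seed(2)
  arr <- retinalsfm:::render_channel(m, c(1, 1, 1), default_noise())
  nr <- detect_nuclei(lsfm_volume(list(nuclei = arr)))
  expect_equal(nrow(nr), 2)
  expect_false(any(classify_nucleus_curvature(nr)))
})

test_that("curvature classification follows the bend-ratio and angle rules", {
  rec <- data.frame(bend_ratio = c(1.0, 1.414, 1.1, 1.1),
                    max_turning_deg = c(5, 90, 80, 30),
                    degenerate = c(FALSE, FALSE, FALSE, FALSE))
  expect_equal(classify_nucleus_curvature(rec), c(FALSE, TRUE, TRUE, FALSE))
  # the 90-degree bent capsule of arms 5: chord 5*sqrt(2), arc 10
  expect_equal(10 / (5 * sqrt(2)), 1.414, tolerance = 1e-3)
  # degenerate nuclei are never curved
  degen <- data.frame(bend_ratio = 2, max_turning_deg = 90, degenerate = TRUE)
  expect_false(classify_nucleus_curvature(degen))
})

test_that("OLS regression matches brute-force arithmetic and its invariances", {
  df <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
  expect_equal(regress_morphometrics(df, "x", "y")$r_squared, 1)
  expect_equal(regress_morphometrics(data.frame(x = 1:5, y = rep(3, 5)), "x", "y")$r_squared, 0)
  set.seed(9)
  rnd <- data.frame(x = runif(10), y = runif(10))
  got <- regress_morphometrics(rnd, "x", "y")
  # brute-force normal equations
  b <- cov(rnd$x, rnd$y) / var(rnd$x)
  a <- mean(rnd$y) - b * mean(rnd$x)
  res <- rnd$y - a - b * rnd$x
  r2 <- 1 - sum(res^2) / sum((rnd$y - mean(rnd$y))^2)
  expect_equal(got$slope, b, tolerance = 1e-12)
  expect_equal(got$intercept, a, tolerance = 1e-12)
  expect_equal(got$r_squared, r2, tolerance = 1e-12)
  # R^2 invariant under affine rescaling of both variables
  rnd2 <- data.frame(x = 3 * rnd$x - 7, y = 0.1 * rnd$y + 2)
  expect_equal(regress_morphometrics(rnd2, "x", "y")$r_squared, r2, tolerance = 1e-12)
  expect_error(regress_morphometrics(df[1:2, ], "x", "y"), "at least 3")
})

test_that("class fold change is the large/medium mean ratio", {
  rec <- data.frame(n_nuclei = c(5, 10, 20, 25, 30), v = c(2, 2, 2, 5, 5))
  expect_equal(class_fold_change(rec, "v"), 2.5)
  expect_equal(class_fold_change(data.frame(n_nuclei = c(5, 25), v = c(3, 3)), "v"), 1)
  expect_error(class_fold_change(data.frame(n_nuclei = c(5, 6), v = 1:2), "v"),
               "above the boundary")
})

test_that("nucleus-golgi polarity pairs to the nearest body with correct angles", {
  expect_equal(nucleus_golgi_polarity(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0))$angle_deg, 0)
  expect_equal(nucleus_golgi_polarity(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))$angle_deg, 180)
  set.seed(11)
  nuc <- matrix(runif(15, 0, 50), 5)
  gol <- matrix(runif(15, 0, 50), 5)
  pol <- nucleus_golgi_polarity(nuc, gol, c(0, 0, 1))
  # brute-force all-pairs nearest search
  for (i in 1:5) {
    dd <- apply(gol, 1, function(g) sqrt(sum((g - nuc[i, ])^2)))
    expect_equal(pol$golgi_id[i], which.min(dd))
    expect_equal(pol$distance_um[i], min(dd))
  }
  expect_true(all(pol$angle_deg >= 0 & pol$angle_deg <= 180))
  expect_error(nucleus_golgi_polarity(matrix(numeric(0), 0, 3), gol, c(1, 0, 0)),
               "at least one")
})
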