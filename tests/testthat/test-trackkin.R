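test_that("filopodium length series are Euclidean distances from the base", {
  tr <- data.frame(x_um = c(0, 1, 2, 3), y_um = 0, z_um = 0)
  expect_equal(filopodium_lengths(tr, base = c(0, 0, 0)), 0:3)
  # first tip position is the default base
  expect_equal(filopodium_lengths(tr), 0:3)
  # stationary tip
  still <- data.frame(x_um = rep(2, 4), y_um = 1, z_um = 5)
  expect_equal(filopodium_lengths(still, base = c(0, 0, 0)),
               rep(sqrt(4 + 1 + 25), 4))
  # 3D motion matches hand-computed norms
  tr3 <- data.frame(x_um = c(0, 1, 2), y_um = c(0, 2, 1), z_um = c(0, 2, 4))
  expect_equal(filopodium_lengths(tr3, base = c(0, 0, 0)),
               c(0, 3, sqrt(21)))
})

test_that("the canonical triangular script yields its closed-form stats", {
  s <- filopodium_stats(c(0, 2, 4, 6, 4, 2, 0), dt_min = 1, eps_um = 0)
  expect_equal(s$max_length_um, 6)
  expect_equal(s$lifetime_min, 5)
  expect_false(s$censored)
  expect_equal(s$extension_speed_um_min, 2)
  expect_equal(s$retraction_speed_um_min, 2)
})

test_that("censoring, monotone growth and dead frames follow the conventions", {
  cens <- filopodium_stats(c(0, 5, 5, 5), dt_min = 1, eps_um = 0)
  expect_true(cens$censored)
  expect_equal(cens$lifetime_min, 3)
  mono <- filopodium_stats(c(0, 1, 2, 3), dt_min = 1, eps_um = 0)
  expect_equal(mono$retraction_speed_um_min, 0)
  expect_true(mono$no_retraction)
  expect_error(filopodium_stats(c(0, 0, 0), dt_min = 1), "no filopodium")
  # lifetime invariant to appending dead frames after disappearance
  a <- filopodium_stats(c(0, 2, 4, 0), dt_min = 1, eps_um = 0)
  b <- filopodium_stats(c(0, 2, 4, 0, 0, 0, 0), dt_min = 1, eps_um = 0)
  expect_equal(a$lifetime_min, b$lifetime_min)
  expect_equal(a$max_length_um, b$max_length_um)
})

test_that("halving the frame interval doubles every speed exactly", {
  lens <- c(0, 3, 7, 5, 1, 0)
  s1 <- filopodium_stats(lens, dt_min = 1, eps_um = 0)
  s2 <- filopodium_stats(lens, dt_min = 0.5, eps_um = 0)
  expect_equal(s2$extension_speed_um_min, 2 * s1$extension_speed_um_min)
  expect_equal(s2$retraction_speed_um_min, 2 * s1$retraction_speed_um_min)
  expect_equal(s2$lifetime_min, s1$lifetime_min / 2)
  tr <- data.frame(x_um = c(0, 1, 3), y_um = 0, z_um = 0)
  expect_equal(bundle_stats(tr, dt_min = 0.5)$average_speed_um_min,
               2 * bundle_stats(tr, dt_min = 1)$average_speed_um_min)
})

test_that("bundle kinematics: path length, duration, speed, displacement", {
  tr <- data.frame(x_um = c(0, 1, 2), y_um = 0, z_um = 0)
  b <- bundle_stats(tr, dt_min = 1)
  expect_equal(b$path_length_um, 2)
  expect_equal(b$duration_min, 2)
  expect_equal(b$average_speed_um_min, 1)
  # back and forth: path exceeds net displacement
  bf <- bundle_stats(data.frame(x_um = c(0, 1, 0), y_um = 0, z_um = 0), dt_min = 1)
  expect_equal(bf$path_length_um, 2)
  expect_equal(bf$net_displacement_um, 0)
  expect_error(bundle_stats(tr[1, ], dt_min = 1), "at least 2")
  # a scripted 40-frame walk matches the generator's cumulative step sum
  walk <- scripted_bundle_population(1, n_frames = 40, seed = 3)[[1]]
  bs <- bundle_stats(data.frame(x_um = walk$positions[, 1], y_um = walk$positions[, 2],
                                z_um = walk$positions[, 3]), dt_min = 1)
  expect_equal(bs$average_speed_um_min, walk$speed_um_min, tolerance = 1e-10)
})

test_that("condition summaries aggregate and test between groups", {
  mk <- function(v) structure(list(max_length_um = v), class = "filopodium_stats")
  same <- lapply(rep(5, 4), mk)
  s <- summarize_condition(same)
  expect_equal(s$summary$sd, 0)
  two <- lapply(c(4, 5, 14, 15), mk)
  s2 <- summarize_condition(two, grouping = c("a", "a", "b", "b"), test = TRUE)
  expect_equal(sort(s2$summary$mean), c(4.5, 14.5))
  expect_true(s2$tests$max_length_um$p.value < 0.05)
  expect_error(summarize_condition(list()), "no records")
})

test_that("simulated filopodium populations recover the scripted mean length", {
  fil <- scripted_filopodia_population(100, "P5", seed = 21)
  tl <- make_timelapse(fil, dt_min = 1, seed = 21, render = FALSE)
  stats <- lapply(split(tl$tracks, tl$tracks$track_id), function(g)
    filopodium_stats(filopodium_lengths(g), dt_min = 1, eps_um = 0.5))
  m <- mean(vapply(stats, `[[`, numeric(1), "max_length_um"))
  se <- sd(vapply(stats, `[[`, numeric(1), "max_length_um")) / sqrt(100)
  expect_lt(abs(m - 14.84), 3 * se + 0.5)
  # measured stats equal the scripted ground truth exactly, track by track
  for (i in seq_along(stats)) {
    expect_equal(stats[[i]]$max_length_um, tl$truth$filopodia[[i]]$max_length_um)
    expect_equal(stats[[i]]$lifetime_min, tl$truth$filopodia[[i]]$lifetime_min)
  }
})
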