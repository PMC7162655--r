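test_that("connected-component labelling matches an igraph flood oracle", {
  for (seed in 1:4) {
    m <- phantom_random_blob(seed)
    for (conn in c(6, 26)) {
      lab <- label_components(m, conn)
      oracle <- betti_oracle(m) # b0 side uses igraph at 26
      if (conn == 26) expect_equal(attr(lab, "n_components"), unname(oracle["b0"]))
      # labels partition the mask
      expect_equal(sum(lab > 0), sum(m))
      expect_true(all(lab[!m] == 0))
    }
  }
})

test_that("Euler characteristic agrees with the set-enumeration oracle", {
  shapes <- list(ball = phantom_ball(5), torus = phantom_torus(),
                 double = phantom_double_torus(),
                 blob1 = phantom_random_blob(7), blob2 = phantom_random_blob(8))
  for (nm in names(shapes)) {
    m <- shapes[[nm]]
    expect_equal(euler_characteristic(m), euler_oracle(m), info = nm)
  }
})

test_that("Betti numbers identify balls, tori and double tori", {
  expect_equal(unname(betti_numbers(phantom_ball(5))), c(1, 0, 0))
  expect_equal(unname(betti_numbers(phantom_torus())), c(1, 1, 0))
  expect_equal(unname(betti_numbers(phantom_double_torus())), c(1, 2, 0))
  # hollow shell: one cavity, no tunnels
  n <- 21
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  r2 <- (g$z - 11)^2 + (g$y - 11)^2 + (g$x - 11)^2
  shell <- array(r2 <= 49 & r2 >= 16, dim = c(n, n, n))
  expect_equal(unname(betti_numbers(shell)), c(1, 0, 1))
})

test_that("a mask touching the border is rejected (pad required)", {
  m <- array(TRUE, dim = c(3, 3, 3))
  expect_error(betti_numbers(m), "pad required")
})

test_that("chamfer distance transform approximates exact Euclidean distance", {
  m <- phantom_ball(6)
  dt <- distance_transform(m, c(1, 1, 1))
  # exact distance at ball centre is r (to the first background voxel shell)
  expect_equal(max(dt), 7, tolerance = 0.15)
  expect_true(all(dt[!m] == 0))
  # doubling the spacing doubles every distance
  d2 <- distance_transform(m, c(2, 2, 2))
  expect_equal(d2, 2 * dt)
})

test_that("a straight tube skeletonizes to a single full-length edge", {
  d <- c(16L, 16L, 101L)
  g <- expand.grid(z = 1:16, y = 1:16, x = 1:101)
  tube <- array((g$z - 8)^2 + (g$y - 8)^2 <= 25, dim = d)
  sk <- skeletonize_mask(tube, spacing = c(1, 1, 1))
  expect_equal(length(sk$edges), 1)
  expect_equal(sk$edges[[1]]$length_um, 100, tolerance = 2)
  expect_equal(sum(sk$nodes$degree == 1), 2)
})

test_that("a Y junction yields exactly one degree-3 node", {
  d <- c(16L, 48L, 64L)
  g <- expand.grid(z = 1:16, y = 1:48, x = 1:64)
  main <- (g$z - 8)^2 + (g$y - 24)^2 <= 16
  branch <- (g$z - 8)^2 + (g$y - (24 + pmax(0, g$x - 32) * 0.8))^2 <= 16 & g$x >= 32
  sk <- skeletonize_mask(array(main | branch, dim = d), spacing = c(1, 1, 1),
                         prune_um = 4)
  expect_equal(sum(sk$nodes$degree == 3), 1)
})

test_that("a single isolated blob becomes one node and no edges", {
  d <- c(20L, 20L, 20L)
  g <- expand.grid(z = 1:20, y = 1:20, x = 1:20)
  blob <- array((g$z - 10)^2 + (g$y - 10)^2 + (g$x - 10)^2 <= 16, dim = d)
  sk <- skeletonize_mask(blob, spacing = c(1, 1, 1))
  expect_equal(length(sk$edges), 0)
  expect_equal(nrow(sk$nodes), 1)
})

test_that("skeletonizing an empty mask errors", {
  expect_error(skeletonize_mask(array(FALSE, dim = c(4, 4, 4))), "empty")
})
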