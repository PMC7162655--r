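# Independent brute-force oracles and shared phantom builders.

# Euler characteristic of the cubical complex, by enumerating the distinct
# cells each foreground voxel contributes (set-based; independent of the
# C++ occupancy-array implementation).
euler_oracle <- function(mask) {
  d <- dim(mask)
  vox <- which(mask, arr.ind = TRUE) # iz iy ix, 1-based
  if (nrow(vox) == 0) return(0L)
  gz <- d[1] + 2; gy <- d[2] + 2
  enc <- function(off) vox[, 1] + off[1] + gz * ((vox[, 2] + off[2]) + gy * (vox[, 3] + off[3]))
  count_cells <- function(offsets)
    length(unique(unlist(lapply(offsets, enc), use.names = FALSE)))
  o8 <- lapply(0:7, function(k) c(k %% 2, (k %/% 2) %% 2, k %/% 4))
  V <- count_cells(o8)
  E <- count_cells(list(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 1, 1))) + # along z
    count_cells(list(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1))) +    # along y
    count_cells(list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))      # along x
  F <- count_cells(list(c(0, 0, 0), c(1, 0, 0))) + # normal z
    count_cells(list(c(0, 0, 0), c(0, 1, 0))) +    # normal y
    count_cells(list(c(0, 0, 0), c(0, 0, 1)))      # normal x
  V - E + F - nrow(vox)
}

# Betti numbers via the oracle chi plus igraph component counts (independent
# of the package's union-find labelling).
betti_oracle <- function(mask) {
  d <- dim(mask)
  comp_count <- function(m, connectivity) {
    vox <- which(m, arr.ind = TRUE)
    n <- nrow(vox)
    if (n == 0) return(0L)
    key <- array(0L, dim = d); key[m] <- seq_len(n)
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
    el <- list()
    for (k in seq_len(nrow(offs))) {
      zz <- vox[, 1] + offs[k, 1]; yy <- vox[, 2] + offs[k, 2]; xx <- vox[, 3] + offs[k, 3]
      ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
      nb <- rep(0L, n); nb[ok] <- key[cbind(zz[ok], yy[ok], xx[ok])]
      hit <- which(nb > 0)
      if (length(hit)) el[[length(el) + 1]] <- cbind(hit, nb[hit])
    }
    g <- if (length(el)) igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
    else igraph::make_empty_graph(n)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    igraph::components(g)$no
  }
  b0 <- comp_count(mask, 26)
  bg <- !mask
  nbg <- comp_count(bg, 6)
  # background components touching the border
  border <- array(FALSE, dim = d)
  border[1, , ] <- border[d[1], , ] <- TRUE
  border[, 1, ] <- border[, d[2], ] <- TRUE
  border[, , 1] <- border[, , d[3]] <- TRUE
  # count border-touching bg components by flooding from border bg voxels
  lab_bg <- label_components(bg, 6) # only used to bucket; counts come from igraph
  touch <- length(setdiff(unique(lab_bg[border & bg]), 0L))
  b2 <- nbg - touch
  chi <- euler_oracle(mask)
  c(b0 = b0, b1 = b0 + b2 - chi, b2 = b2)
}

# Solid phantoms, padded away from the border.
phantom_ball <- function(r = 6, pad = 4) {
  n <- 2 * (r + pad) + 1
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  c0 <- r + pad + 1
  array((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2, dim = c(n, n, n))
}

phantom_torus <- function(R = 8, r = 3, pad = 4) {
  n <- 2 * (R + r + pad) + 1
  nz <- 2 * (r + pad) + 1
  g <- expand.grid(z = 1:nz, y = 1:n, x = 1:n)
  c0 <- R + r + pad + 1; cz <- r + pad + 1
  rad <- sqrt((g$y - c0)^2 + (g$x - c0)^2)
  array((rad - R)^2 + (g$z - cz)^2 <= r^2, dim = c(nz, n, n))
}

phantom_double_torus <- function(R = 7, r = 2.6, pad = 4) {
  width <- 2 * (2 * R + r + pad) + 1
  n <- 2 * (R + r + pad) + 1
  nz <- 2 * (r + pad) + 1
  g <- expand.grid(z = 1:nz, y = 1:n, x = 1:width)
  cz <- r + pad + 1; cy <- R + r + pad + 1
  cx1 <- R + r + pad + 1; cx2 <- cx1 + 2 * R # tangent cores
  rad1 <- sqrt((g$y - cy)^2 + (g$x - cx1)^2)
  rad2 <- sqrt((g$y - cy)^2 + (g$x - cx2)^2)
  array((rad1 - R)^2 + (g$z - cz)^2 <= r^2 | (rad2 - R)^2 + (g$z - cz)^2 <= r^2,
        dim = c(nz, n, width))
}

phantom_random_blob <- function(seed, n = 20, pad = 3) {
  set.seed(seed)
  d <- c(n, n, n)
  m <- array(FALSE, dim = d)
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  for (i in 1:4) {
    c0 <- runif(3, pad + 3, n - pad - 3)
    r <- runif(1, 2, 4)
    m <- m | array((g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2 <= r^2, dim = d)
  }
  m
}

default_noise <- function() list(background = 0.05, sigma = 0.02, blur_um = c(0.8, 0.8, 0.8))

# Toy source-data spreadsheet written at test time (xlsx is a binary
# container, so it cannot be a stored fixture).
write_toy_xlsx <- function(path, header, rows) {
  body <- paste(vapply(rows, function(r)
    paste0("ws.append([", paste(vapply(r, function(v)
      if (is.character(v)) sprintf("\"%s\"", v) else format(v, digits = 15),
      character(1)), collapse = ","), "])"), character(1)), collapse = "\n")
  script <- sprintf(
    "import openpyxl\nwb = openpyxl.Workbook()\nws = wb.active\nws.append([%s])\n%s\nwb.save(%s)\n",
    paste(sprintf("\"%s\"", header), collapse = ","), body, sprintf("\"%s\"", path))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  path
}

# Shared heavy fixtures, built once per test run.
.fixture_cache <- new.env()
cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tuft_fixture <- function(seed = 5) {
  cached(paste0("tufts_", seed), function() {
    gen <- make_tuft_volume(tuft_scene_spec(seed = seed))
    gen$measured <- measure_tuft_scene(gen$volume, gen$truth$surface)
    gen
  })
}

plexus_fixture <- function(seed = 3, radius = 8) {
  cached(paste0("plexus_", seed, "_", radius), function() {
    spec <- plexus_scene_spec(seed = seed, target_radius_um = radius)
    gen <- make_plexus_volume(spec)
    gen$spec <- spec
    gen
  })
}

# Measurement site on the target vessel at the lateral centre of a scene.
centre_site <- function(volume, surface) {
  d <- retinalsfm:::vol_dim(volume)
  sp <- volume$spacing
  xy <- c((d[3] - 1) * sp[3] / 2, (d[2] - 1) * sp[2] / 2)
  c(xy, retinalsfm:::surface_elevation(surface, xy[1], xy[2]))
}
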