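#' Label connected components of a 3D binary mask
#'
#' @param mask logical array `(z, y, x)` (a 2D slice may be passed with a
#'   singleton z dimension).
#' @param connectivity 6 (face) or 26 (face+edge+vertex), the package-wide
#'   convention being 26 for foreground and 6 for background.
#' @return integer array of labels (0 = background) with attribute
#'   `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  d <- dim(mask)
  if (length(d) == 2) d <- c(1L, d)
  .cc_label_3d(as.logical(mask), as.integer(d), as.integer(connectivity))
}

#' Euler characteristic of a 3D binary mask
#'
#' Computed as \eqn{V - E + F - C} over the distinct vertices, edges, faces
#' and cubes of the union of closed unit voxels. This realisation makes the
#' foreground 26-connected and the background 6-connected.
#' @param mask logical array `(z, y, x)`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mask) {
  .euler_characteristic_3d(as.logical(mask), as.integer(dim(mask)))
}

#' Betti numbers of a 3D binary mask
#'
#' `b0` = number of 26-connected foreground components, `b2` = number of
#' enclosed background cavities (6-connected background components not
#' reaching the volume border), and `b1 = b0 + b2 - chi` = number of
#' independent tunnels.
#' @param mask logical array `(z, y, x)`; must not touch the volume border
#'   (pad first) so that cavity detection is well defined.
#' @return named integer vector `c(b0, b1, b2)`.
#' @export
betti_numbers <- function(mask) {
  d <- dim(mask)
  border <- any(mask[1, , ]) || any(mask[d[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, d[2], ]) ||
    any(mask[, , 1]) || any(mask[, , d[3]])
  if (border) lsfm_stop("mask touches the volume border: pad required", "lsfm_pad_error")
  lab <- label_components(mask, 26)
  b0 <- attr(lab, "n_components")
  bg <- label_components(!mask, 6)
  nbg <- attr(bg, "n_components")
  touch <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ], bg[, , 1], bg[, , d[3]]))
  b2 <- nbg - length(setdiff(touch, 0L)) # cavities
  chi <- euler_characteristic(mask)
  b1 <- b0 + b2 - chi
  c(b0 = b0, b1 = b1, b2 = b2)
}

#' Euclidean-weighted chamfer distance transform
#'
#' Distance from each foreground voxel to the nearest background voxel,
#' propagated over the 26-neighbourhood with anisotropic step weights, in µm.
#' @param mask logical array `(z, y, x)`.
#' @param spacing voxel spacing `(z, y, x)` µm.
#' @return numeric array of distances, µm.
#' @export
distance_transform <- function(mask, spacing = c(1, 1, 1)) {
  .chamfer_dt_3d(as.logical(mask), as.integer(dim(mask)), as.numeric(spacing))
}

#' Skeletonize a 3D binary mask into a spatial graph
#'
#' Reduces the mask to a one-voxel-wide medial curve skeleton by topology
#' preserving directional thinning, then converts the skeleton to a graph:
#' nodes are endpoints and branch points (26-adjacent clusters of skeleton
#' voxels with degree != 2 merged into one node), edges are the voxel chains
#' between them with physical polyline lengths in µm. Isolated skeleton
#' voxels become zero-edge nodes; pure cycles get one anchor node.
#'
#' @param mask logical array `(z, y, x)` or a `vessel_mask` from
#'   [segment_vessels()].
#' @param spacing voxel spacing `(z, y, x)` µm (taken from a `vessel_mask`).
#' @param prune_um remove terminal branches shorter than this (µm); side
#'   spurs of tube-radius scale are thinning artefacts. Default 0 (off).
#' @return `skeleton_graph`: list with `points` (n x 3 µm coordinates of all
#'   skeleton voxels), `voxels` (their 1-based `(z,y,x)` indices), `nodes`
#'   (data frame: id, x, y, z, degree), `edges` (list of polylines with
#'   `length_um` and endpoint node ids), `dim`, `spacing`.
#' @export
skeletonize_mask <- function(mask, spacing = c(1, 1, 1), prune_um = 0) {
  if (inherits(mask, "vessel_mask")) { spacing <- mask$spacing; mask <- mask$mask }
  if (!any(mask)) lsfm_stop("empty mask cannot be skeletonized")
  skel <- .thin_3d(as.logical(mask), as.integer(dim(mask)))
  g <- skeleton_to_graph(skel, spacing)
  # thinning leaves a short stub for a roughly isotropic blob: collapse
  # sub-resolution isolated single-edge components to one node
  tiny <- vapply(g$edges, function(e) {
    e$from != e$to && g$nodes$degree[e$from] == 1 && g$nodes$degree[e$to] == 1 &&
      e$length_um <= 2 * max(spacing) * sqrt(3)
  }, logical(1))
  if (any(tiny)) {
    drop_nodes <- integer(0)
    for (e in g$edges[tiny]) {
      mid <- colMeans(e$polyline)
      g$nodes[e$from, c("x", "y", "z")] <- as.list(mid)
      g$nodes$degree[e$from] <- 0L
      drop_nodes <- c(drop_nodes, e$to)
    }
    keep <- setdiff(seq_len(nrow(g$nodes)), drop_nodes)
    remap <- match(seq_len(nrow(g$nodes)), keep)
    g$edges <- g$edges[!tiny]
    g$edges <- lapply(g$edges, function(e) { e$from <- remap[e$from]; e$to <- remap[e$to]; e })
    g$nodes <- g$nodes[keep, , drop = FALSE]
    g$nodes$id <- seq_len(nrow(g$nodes))
    rownames(g$nodes) <- NULL
  }
  if (prune_um > 0) {
    keep <- vapply(g$edges, function(e) {
      e$length_um >= prune_um ||
        (g$nodes$degree[e$from] > 1 && g$nodes$degree[e$to] > 1)
    }, logical(1))
    if (!all(keep)) {
      g$edges <- g$edges[keep]
      deg <- integer(nrow(g$nodes))
      for (e in g$edges) { deg[e$from] <- deg[e$from] + 1L; deg[e$to] <- deg[e$to] + 1L }
      g$nodes$degree <- deg
    }
  }
  g
}

#' @noRd
skeleton_to_graph <- function(skel, spacing) {
  d <- dim(skel)
  idx <- which(skel)
  vox <- which(skel, arr.ind = TRUE) # iz iy ix
  n <- length(idx)
  pts <- cbind(x = (vox[, 3] - 1) * spacing[3],
               y = (vox[, 2] - 1) * spacing[2],
               z = (vox[, 1] - 1) * spacing[1])
  key <- array(0L, dim = d); key[idx] <- seq_len(n)
  # 26-neighbour adjacency among skeleton voxels
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  adj <- vector("list", n)
  step_um <- sqrt((offs[, "dz"] * spacing[1])^2 + (offs[, "dy"] * spacing[2])^2 +
                    (offs[, "dx"] * spacing[3])^2)
  for (k in seq_len(nrow(offs))) {
    zz <- vox[, 1] + offs[k, "dz"]; yy <- vox[, 2] + offs[k, "dy"]; xx <- vox[, 3] + offs[k, "dx"]
    ok <- zz >= 1 & zz <= d[1] & yy >= 1 & yy <= d[2] & xx >= 1 & xx <= d[3]
    nb <- rep(0L, n)
    nb[ok] <- key[cbind(zz[ok], yy[ok], xx[ok])]
    hit <- which(nb > 0)
    for (i in hit) adj[[i]] <- c(adj[[i]], nb[i])
  }
  deg <- lengths(adj)
  is_node_vox <- deg != 2L
  # pure cycles: anchor one voxel per all-degree-2 component
  if (any(!is_node_vox)) {
    gg <- igraph::graph_from_edgelist(
      do.call(rbind, c(list(matrix(integer(), 0, 2)),
                       lapply(which(deg > 0), function(i) cbind(i, adj[[i]])))),
      directed = FALSE)
    gg <- igraph::simplify(gg)
    if (igraph::vcount(gg) < n) gg <- igraph::add_vertices(gg, n - igraph::vcount(gg))
    comp <- igraph::components(gg)$membership
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (!any(is_node_vox[members])) is_node_vox[members[1]] <- TRUE
    }
  }
  # merge 26-adjacent node voxels into single nodes
  node_vox <- which(is_node_vox)
  node_id <- integer(n)
  nodes <- list(); nid <- 0L
  seen <- logical(n)
  for (s in node_vox) {
    if (seen[s]) next
    nid <- nid + 1L
    stack <- s; members <- integer(0)
    while (length(stack)) {
      i <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[i]) next
      seen[i] <- TRUE; members <- c(members, i)
      nbrs <- adj[[i]]
      stack <- c(stack, nbrs[is_node_vox[nbrs] & !seen[nbrs]])
    }
    node_id[members] <- nid
    nodes[[nid]] <- colMeans(pts[members, , drop = FALSE])
  }
  nodes_df <- if (nid > 0) {
    m <- do.call(rbind, nodes)
    data.frame(id = seq_len(nid), x = m[, 1], y = m[, 2], z = m[, 3], degree = 0L)
  } else data.frame(id = integer(0), x = numeric(0), y = numeric(0), z = numeric(0), degree = integer(0))
  # trace chains from each node voxel through degree-2 voxels
  edges <- list()
  used_step <- new.env(hash = TRUE)
  step_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  for (s in which(is_node_vox)) {
    for (t0 in adj[[s]]) {
      k0 <- step_key(s, t0)
      if (!is.null(used_step[[k0]])) next
      used_step[[k0]] <- TRUE
      if (is_node_vox[t0] && node_id[t0] == node_id[s]) next # intra-cluster step
      chain <- c(s, t0)
      prev <- s; cur <- t0
      while (!is_node_vox[cur]) {
        nbrs <- adj[[cur]]
        nxt <- nbrs[nbrs != prev]
        if (length(nxt) == 0) break
        nxt <- nxt[1]
        used_step[[step_key(cur, nxt)]] <- TRUE
        chain <- c(chain, nxt)
        prev <- cur; cur <- nxt
      }
      poly <- pts[chain, , drop = FALSE]
      len <- sum(sqrt(rowSums((poly[-1, , drop = FALSE] - poly[-nrow(poly), , drop = FALSE])^2)))
      edges[[length(edges) + 1L]] <- list(from = node_id[s], to = node_id[cur],
                                          chain = chain, polyline = poly, length_um = len)
    }
  }
  deg_node <- integer(nid)
  for (e in edges) { deg_node[e$from] <- deg_node[e$from] + 1L; deg_node[e$to] <- deg_node[e$to] + 1L }
  nodes_df$degree <- deg_node
  structure(list(points = pts, voxels = vox, voxel_node = node_id, nodes = nodes_df,
                 edges = edges, dim = d, spacing = spacing, skeleton = skel),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d skeleton voxels, %d nodes, %d edges (total %.1f um)\n",
              nrow(x$points), nrow(x$nodes), length(x$edges),
              sum(vapply(x$edges, `[[`, numeric(1), "length_um"))))
  invisible(x)
}
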