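# Triangulated tumor surfaces.
#
# The surface is extracted as the set of voxel faces separating mask
# foreground from background, each split into two triangles with outward
# orientation, then Laplacian-smoothed.  For a single foreground component
# without edge-only or corner-only voxel contacts this yields a closed,
# genus-0 2-manifold; anything else is rejected as degenerate.  Vertices are
# in mm (voxel index times spacing).

#' Triangulate a tumor mask
#'
#' @param mask binary 3D array (single 26-connected component with at least
#'   ~20 voxels).
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param smooth_iters Laplacian smoothing iterations (default 10).
#' @param smooth_factor smoothing step size in (0, 1] (default 0.5).
#' @return object of class `surface_mesh`: `nodes` (I x 3 matrix, mm),
#'   `triangles` (T x 3 integer matrix, 1-based), `neighbors` (per-node
#'   index sets), `area_raw` (total area before smoothing, mm^2).
#' @export
mask_to_mesh <- function(mask, spacing = c(1, 1, 1), smooth_iters = 10,
                         smooth_factor = 0.5) {
  mask <- mask != 0
  if (sum(mask) < 20) stop("mesh degenerate")
  # work on the bounding box; world coordinates keep the original offset
  bidx <- which(mask, arr.ind = TRUE)
  lo <- apply(bidx, 2, min)
  hi <- apply(bidx, 2, max)
  offset <- (lo - 1L) * spacing
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  d <- dim(mask)
  nc <- d + 1L  # corner lattice dimensions

  corner_key <- function(x, y, z) 1 + x + nc[1] * (y + nc[2] * z)

  quads <- vector("list", 6)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_along(dirs)) {
    dd <- dirs[[s]]
    boundary <- mask & !shift_array(mask, -dd[1], -dd[2], -dd[3])
    idx <- which(boundary, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    # 0-based corner coordinates of the exposed face, ordered so the quad
    # (p1,p2,p3,p4) has outward orientation (see design notes in tests)
    i <- idx[, 1]; j <- idx[, 2]; k <- idx[, 3]
    f <- switch(s,
      `1` = cbind(corner_key(i, j - 1, k - 1), corner_key(i, j, k - 1),
                  corner_key(i, j, k), corner_key(i, j - 1, k)),
      `2` = cbind(corner_key(i - 1, j - 1, k - 1), corner_key(i - 1, j - 1, k),
                  corner_key(i - 1, j, k), corner_key(i - 1, j, k - 1)),
      `3` = cbind(corner_key(i - 1, j, k - 1), corner_key(i - 1, j, k),
                  corner_key(i, j, k), corner_key(i, j, k - 1)),
      `4` = cbind(corner_key(i - 1, j - 1, k - 1), corner_key(i, j - 1, k - 1),
                  corner_key(i, j - 1, k), corner_key(i - 1, j - 1, k)),
      `5` = cbind(corner_key(i - 1, j - 1, k), corner_key(i, j - 1, k),
                  corner_key(i, j, k), corner_key(i - 1, j, k)),
      `6` = cbind(corner_key(i - 1, j - 1, k - 1), corner_key(i - 1, j, k - 1),
                  corner_key(i, j, k - 1), corner_key(i, j - 1, k - 1)))
    quads[[s]] <- f
  }
  quads <- do.call(rbind, quads)
  keys <- sort(unique(as.vector(quads)))
  vid <- match(quads, keys)
  dim(vid) <- dim(quads)

  # decode corner keys back to lattice coordinates, voxel center i -> (i-1)*dx
  k0 <- keys - 1
  cx <- k0 %% nc[1]
  cy <- (k0 %/% nc[1]) %% nc[2]
  cz <- k0 %/% (nc[1] * nc[2])
  nodes <- cbind((cx - 0.5) * spacing[1] + offset[1],
                 (cy - 0.5) * spacing[2] + offset[2],
                 (cz - 0.5) * spacing[3] + offset[3])

  tris <- rbind(vid[, c(1, 2, 3)], vid[, c(1, 3, 4)])

  # manifold + genus-0 check: every undirected edge in exactly two triangles,
  # Euler characteristic V - E + F = 2
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ekey <- sort((pmin(e[, 1], e[, 2]) - 1) * nrow(nodes) + pmax(e[, 1], e[, 2]))
  runs <- rle(ekey)$lengths
  if (any(runs != 2)) stop("mesh degenerate")
  V <- nrow(nodes); E <- length(runs); F <- nrow(tris)
  if (V - E + F != 2L) stop("mesh degenerate")

  area_raw <- mesh_area(nodes, tris)
  nbrs <- mesh_neighbors(tris, V)
  if (any(lengths(nbrs) < 3)) stop("mesh degenerate")
  nodes <- laplacian_smooth(nodes, nbrs, smooth_iters, smooth_factor)

  structure(list(nodes = nodes, triangles = tris, neighbors = nbrs,
                 area_raw = area_raw),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$triangles),
      " triangles\n", sep = "")
  invisible(x)
}

mesh_neighbors <- function(tris, nvert) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2], factor(e[, 1], levels = seq_len(nvert)))
}

mesh_area <- function(nodes, tris) {
  a <- nodes[tris[, 2], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  b <- nodes[tris[, 3], , drop = FALSE] - nodes[tris[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

laplacian_smooth <- function(nodes, nbrs, iters, factor) {
  if (iters <= 0) return(nodes)
  n <- nrow(nodes)
  ii <- rep.int(seq_len(n), lengths(nbrs))
  jj <- unlist(nbrs, use.names = FALSE)
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  dinv <- 1 / Matrix::rowSums(A)
  for (it in seq_len(iters))
    nodes <- (1 - factor) * nodes + factor * dinv * as.matrix(A %*% nodes)
  nodes
}

# Midpoint 4-to-1 subdivision of a mesh and (optionally) its spherical map.
# New mesh vertices are edge midpoints; new map points are normalized edge
# midpoints on the sphere, which preserves the bijection.
subdivide_mesh_map <- function(nodes, tris, map = NULL) {
  n <- nrow(nodes)
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
  key <- (a - 1) * n + b
  ukey <- unique(key)
  mid_id <- n + match(key, ukey)
  ua <- (ukey - 1) %/% n + 1
  ub <- (ukey - 1) %% n + 1
  mids <- (nodes[ua, , drop = FALSE] + nodes[ub, , drop = FALSE]) / 2
  nodes2 <- rbind(nodes, mids)
  nt <- nrow(tris)
  m12 <- mid_id[seq_len(nt)]
  m23 <- mid_id[nt + seq_len(nt)]
  m31 <- mid_id[2 * nt + seq_len(nt)]
  tris2 <- rbind(cbind(tris[, 1], m12, m31),
                 cbind(m12, tris[, 2], m23),
                 cbind(m31, m23, tris[, 3]),
                 cbind(m12, m23, m31))
  map2 <- NULL
  if (!is.null(map)) {
    mm <- (map[ua, , drop = FALSE] + map[ub, , drop = FALSE]) / 2
    mm <- mm / sqrt(rowSums(mm^2))
    map2 <- rbind(map, mm)
  }
  list(nodes = nodes2, triangles = tris2, map = map2)
}
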