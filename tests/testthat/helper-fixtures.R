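# Geometric fixtures and small study builders, all generated in code.

# icosahedron subdivided n times and projected to the unit sphere
icosphere_mesh <- function(n = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  sub <- hepatocad:::subdivide_mesh_map
  for (i in seq_len(n)) {
    r <- sub(v, f, v)
    v <- r$map
    f <- r$triangles
  }
  structure(list(nodes = v, triangles = f,
                 neighbors = hepatocad:::mesh_neighbors(f, nrow(v))),
            class = "surface_mesh")
}

radial_map <- function(mesh) {
  v <- sweep(mesh$nodes, 2, colMeans(mesh$nodes))
  hepatocad:::as_spherical_map(v / sqrt(rowSums(v^2)))
}

digital_ball <- function(radius, grid = 2 * radius + 8) {
  ax <- seq_len(grid) - (grid + 1) / 2
  rho <- sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  rho <= radius
}

# four-phase study on an arbitrary mask with reproducible noise
toy_study <- function(mask = digital_ball(6, 20), seed = 1, grade = NULL,
                      means = c(100, 170, 155, 129), noise = 5,
                      spacing = c(1, 1, 1)) {
  set.seed(seed)
  d <- dim(mask)
  phases <- lapply(means, function(m) array(m + rnorm(prod(d), 0, noise), d))
  names(phases) <- c("pre", "arterial", "venous", "delayed")
  tumor_study(paste0("toy", seed), phases, mask, spacing = spacing,
              grade = grade)
}

small_phantom <- function(grade, seed, grid = 24, radius = 6, ...) {
  make_phantom_study(phantom_params(grade, grid = grid, radius = radius,
                                    seed = seed, ...))
}

# desk-scale configuration used throughout the tests
tiny_cfg <- function(L_max = 12L, max_iters = 100L) {
  test_scale_config(L_max = L_max, max_iters = max_iters)
}
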