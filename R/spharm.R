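# Spherical-harmonic shape description.
#
# A tumor surface mesh is mapped one-to-one onto the unit sphere by the
# attraction-repulsion iteration, the three Cartesian coordinate functions
# are expanded in real orthonormal spherical harmonics on that sphere, and
# the per-degree reconstruction errors E_1..E_L (summed node-wise Euclidean
# distance between the mesh and its degree-d approximation) are the
# morphological markers.  Smooth, near-spherical tumors are captured by low
# degrees; spiculated surfaces leave error mass at high degrees.

#' Attraction-repulsion parameters
#'
#' `ca1` and `ca2` weight the long-range (cubic) and short-range
#' (constant-magnitude) attraction toward mesh neighbours, `cr` the global
#' pairwise repulsion that keeps the map from collapsing, `tol` the maximum
#' node displacement below which the iteration stops, and `max_iters` the
#' iteration cap.  The defaults were chosen for stable convergence on
#' icosphere meshes; none is prescribed by theory.
#'
#' @param ca1,ca2 attraction factors (> 0).
#' @param cr repulsion factor (> 0).
#' @param tol stop threshold on the maximum node displacement (> 0).
#' @param max_iters iteration cap (>= 1).
#' @param literal_alpha logical; reuse pre-attraction positions in the
#'   repulsion step instead of recomputing displacements from the
#'   post-attraction positions.
#' @return list of class `ar_params`.
#' @export
ar_params <- function(ca1 = 0.003, ca2 = 0.3, cr = 1.0, tol = 1e-4,
                      max_iters = 5000, literal_alpha = FALSE) {
  stopifnot(ca1 > 0, ca2 > 0, cr > 0, tol > 0, max_iters >= 1)
  structure(list(ca1 = ca1, ca2 = ca2, cr = cr, tol = tol,
                 max_iters = as.integer(max_iters),
                 literal_alpha = isTRUE(literal_alpha)),
            class = "ar_params")
}

#' Map a surface mesh onto the unit sphere
#'
#' Initializes with the radial projection of the nodes about their centroid,
#' then alternates neighbour attraction, global repulsion and re-projection
#' until the largest node displacement falls below `p$tol`.  If the cap is
#' reached first the best map is returned with `converged = FALSE` and a
#' warning.
#'
#' @param mesh a `surface_mesh`.
#' @param p an [ar_params()] object.
#' @return object of class `spherical_map`: `coords` (I x 3 unit vectors),
#'   `theta` (polar angle, `[0, pi]`), `phi` (azimuth, `[0, 2*pi)`),
#'   `iterations`, `converged`.
#' @export
attraction_repulsion <- function(mesh, p = ar_params()) {
  nodes <- mesh$nodes
  ctr <- colMeans(nodes)
  v <- sweep(nodes, 2, ctr)
  r <- sqrt(rowSums(v^2))
  if (any(r == 0)) stop("duplicate node")
  init <- v / r
  res <- ar_run_cpp(init, mesh$neighbors, p$ca1, p$ca2, p$cr, p$tol,
                    p$max_iters, p$literal_alpha)
  if (!res$converged)
    warning("attraction-repulsion did not converge within ", p$max_iters,
            " iterations (last displacement ", format(res$last_disp), ")")
  as_spherical_map(res$coords, iterations = res$iterations,
                   converged = res$converged)
}

as_spherical_map <- function(coords, iterations = NA_integer_,
                             converged = TRUE) {
  z <- pmin(1, pmax(-1, coords[, 3]))
  theta <- acos(z)
  phi <- atan2(coords[, 2], coords[, 1]) %% (2 * pi)
  structure(list(coords = coords, theta = theta, phi = phi,
                 iterations = iterations, converged = converged),
            class = "spherical_map")
}

#' Real orthonormal spherical-harmonic basis
#'
#' Evaluates all real spherical harmonics of degree 0..L at the given
#' angles, in the convention without the Condon-Shortley phase: the order-0
#' harmonic of degree tau is `sqrt((2*tau+1)/(4*pi)) * P_tau(cos theta)` and
#' the cosine/sine harmonics carry an extra `sqrt(2)`.  Columns are ordered
#' by degree, within a degree by order `-tau..tau` (sine terms, zonal term,
#' cosine terms), so degree prefixes are contiguous.
#'
#' @param theta polar angles in `[0, pi]`.
#' @param phi azimuths in `[0, 2*pi)`.
#' @param L maximum degree (>= 0).
#' @return numeric matrix `length(theta) x (L+1)^2`; a plain vector when a
#'   single angle pair is given.
#' @export
sh_basis <- function(theta, phi, L) {
  B <- sh_basis_matrix(theta, phi, L)
  if (nrow(B) == 1L) drop(B) else B
}

sh_basis_matrix <- function(theta, phi, L) {
  stopifnot(L >= 0, length(theta) == length(phi))
  if (any(theta < 0 | theta > pi) || any(phi < 0 | phi >= 2 * pi) ||
      any(!is.finite(theta)) || any(!is.finite(phi)))
    stop("bad angle")
  n <- length(theta)
  x <- cos(theta)
  s <- sin(theta)
  M <- (L + 1L)^2
  B <- matrix(0, n, M)
  col_of <- function(l, beta) l^2 + beta + l + 1L

  # fully-normalized associated Legendre recursion, stable to high degree
  pmm <- rep(sqrt(1 / (4 * pi)), n)
  for (m in 0:L) {
    if (m > 0) pmm <- pmm * sqrt((2 * m + 1) / (2 * m)) * s
    pl_prev <- NULL  # P_{l-1}^m
    pl <- pmm        # P_l^m starting at l = m
    cm <- if (m > 0) sqrt(2) * cos(m * phi)
    sm <- if (m > 0) sqrt(2) * sin(m * phi)
    for (l in m:L) {
      if (l > m) {
        a <- sqrt((4 * l^2 - 1) / (l^2 - m^2))
        b <- sqrt(((l - 1)^2 - m^2) / (4 * (l - 1)^2 - 1))
        pl_new <- a * (x * pl - b * if (is.null(pl_prev)) 0 else pl_prev)
        pl_prev <- pl
        pl <- pl_new
      }
      if (m == 0) {
        B[, col_of(l, 0L)] <- pl
      } else {
        B[, col_of(l, m)] <- pl * cm
        B[, col_of(l, -m)] <- pl * sm
      }
    }
  }
  B
}

#' Per-degree spherical-harmonic reconstruction errors
#'
#' Least-squares fits the x, y and z coordinate functions of the mesh (as
#' functions on the sphere through `map`) with harmonics of degree at most
#' d, for d = 1..L, and returns the summed Euclidean node distance between
#' mesh and reconstruction at each degree.  The fits are nested, so the
#' error sequence is non-increasing.  When the mesh has fewer than `(L+1)^2`
#' nodes it is midpoint-subdivided (together with the map) until the system
#' is overdetermined; set `subdivide = FALSE` to get an error instead.
#'
#' All degree-prefix solutions come from one Cholesky factor of the full
#' Gram matrix: the leading k x k block of the factor is the factor of every
#' prefix model, so no per-degree refactorization is needed.
#'
#' @param mesh a `surface_mesh`.
#' @param map the matching `spherical_map`.
#' @param L_max maximum degree (default 70).
#' @param subdivide logical; subdivide the mesh until it has at least
#'   `(L_max+1)^2` nodes.
#' @param normalize divide each error by the node count (default `FALSE`,
#'   the raw distance sum).
#' @return numeric vector `E_1..E_{L_max}`.
#' @export
sh_reconstruction_errors <- function(mesh, map, L_max = 70, subdivide = TRUE,
                                     normalize = FALSE) {
  stopifnot(L_max >= 1)
  nodes <- mesh$nodes
  tris <- mesh$triangles
  sph <- map$coords
  if (nrow(sph) != nrow(nodes)) stop("map does not match mesh")
  M <- (L_max + 1L)^2
  while (nrow(nodes) < M) {
    if (!subdivide) stop("insufficient nodes")
    sub <- subdivide_mesh_map(nodes, tris, sph)
    nodes <- sub$nodes; tris <- sub$triangles; sph <- sub$map
  }
  sm <- as_spherical_map(sph)
  B <- sh_basis_matrix(sm$theta, sm$phi, L_max)
  G <- crossprod(B)
  R <- tryCatch(chol(G), error = function(e) {
    chol(G + diag(1e-10 * mean(diag(G)), ncol(G)))
  })
  bmat <- crossprod(B, nodes)

  blocks <- lapply(0:L_max, function(d) B[, (d^2 + 1L):((d + 1L)^2), drop = FALSE])
  E <- numeric(L_max)
  for (d in seq_len(L_max)) {
    k <- (d + 1L)^2
    z <- backsolve(R, bmat[seq_len(k), , drop = FALSE], k = k, transpose = TRUE)
    cf <- backsolve(R, z, k = k)
    recon <- matrix(0, nrow(nodes), 3)
    for (dd in 0:d) {
      rng <- (dd^2 + 1L):((dd + 1L)^2)
      recon <- recon + blocks[[dd + 1L]] %*% cf[rng, , drop = FALSE]
    }
    res <- nodes - recon
    E[d] <- sum(sqrt(rowSums(res^2)))
  }
  if (normalize) E <- E / nrow(nodes)
  E
}

#' Morphological markers of a study
#'
#' Triangulates the tumor mask, maps the mesh to the unit sphere, and
#' returns the `L_max` per-degree reconstruction errors, named
#' `SH_err_001..SH_err_<L_max>`.
#'
#' @param study a [tumor_study()].
#' @param cfg configuration list (see [default_config()]), of which
#'   `morph$L_max`, `morph$ar`, `morph$smooth` and `morph$normalize_errors`
#'   are used.
#' @return named numeric vector of length `morph$L_max`.
#' @export
morphological_markers <- function(study, cfg = default_config()) {
  m <- cfg$morph
  mesh <- mask_to_mesh(study$mask, study$spacing,
                       smooth_iters = m$smooth$iters,
                       smooth_factor = m$smooth$factor)
  p <- ar_params(ca1 = m$ar$CA1, ca2 = m$ar$CA2, cr = m$ar$CR, tol = m$ar$T,
                 max_iters = m$ar$max_iters,
                 literal_alpha = isTRUE(m$ar$literal_alpha))
  map <- attraction_repulsion(mesh, p)
  E <- sh_reconstruction_errors(mesh, map, L_max = m$L_max,
                                normalize = isTRUE(m$normalize_errors))
  names(E) <- sprintf("SH_err_%03d", seq_len(m$L_max))
  E
}
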