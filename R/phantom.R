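# Grade-conditioned digital phantoms.
#
# Each phantom is a star-shaped tumor: a radial surface
# r(theta, phi) = r0 * (1 + a * f(theta, phi)), with f a unit-RMS random
# combination of spherical harmonics in a grade-specific degree band,
# voxelized into a binary mask.  Higher grades draw their perturbation from
# higher-degree bands with larger amplitude (spikier surfaces), have
# shorter-range / whiter intensity texture (more heterogeneous after
# min-max quantization), and steeper enhancement kinetics (faster wash-in,
# deeper wash-out).  Phase volumes follow a piecewise-linear enhancement
# curve sampled at the nominal times (0, 35, 50, 180) s with a shared
# multiplicative texture field, so generative slopes are recovered by
# `enhancement_slopes` to well within 2%.

PHANTOM_GRADE_TABLE <- data.frame(
  grade = c("LR1", "LR2", "LR3", "LR4", "LR5"),
  surf_amp = c(0.015, 0.03, 0.05, 0.07, 0.09),
  band_lo = c(2L, 3L, 5L, 8L, 12L),
  band_hi = c(4L, 6L, 10L, 16L, 24L),
  noise_sd = c(0.02, 0.04, 0.06, 0.08, 0.10),
  corr_sigma = c(2.5, 2.1, 1.8, 1.4, 1.0),
  white_frac = c(0.10, 0.20, 0.35, 0.50, 0.65),
  rate_washin = c(0.6, 0.9, 1.4, 2.0, 2.6),
  rate_pv = c(-0.10, -0.25, -0.50, -0.90, -1.20),
  rate_del = c(-0.02, -0.05, -0.08, -0.12, -0.15),
  stringsAsFactors = FALSE)

#' Phantom generator parameters
#'
#' Grade-conditioned defaults come from the internal grade table (surface
#' perturbation amplitude and harmonic band, texture noise level /
#' correlation length / white-noise fraction, and enhancement rates in
#' intensity units per second); any of them can be overridden.  `jitter_sd`
#' is the standard deviation of the log-normal per-study variation applied
#' to the kinetic rates and the surface amplitude, which is what makes a
#' cohort a sample rather than five points.
#'
#' @param grade one of `"LR1"`..`"LR5"`.
#' @param grid cubic grid side in voxels (default 64).
#' @param radius base tumor radius in voxels (default 10, minimum 6).
#' @param seed integer seed; every phantom is a pure function of its params.
#' @param jitter_sd log-scale SD of per-study kinetic/shape variation
#'   (default 0.08).
#' @param base_intensity pre-contrast mean intensity (arbitrary units).
#' @param ... named overrides of the grade-table fields
#'   (`surf_amp`, `band_lo`, `band_hi`, `noise_sd`, `corr_sigma`,
#'   `white_frac`, `rate_washin`, `rate_pv`, `rate_del`).
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(grade, grid = 64L, radius = 10, seed = 1L,
                           jitter_sd = 0.08, base_intensity = 100, ...) {
  stopifnot(grade %in% GRADES, radius >= 6, grid >= 4 * 4)
  row <- PHANTOM_GRADE_TABLE[PHANTOM_GRADE_TABLE$grade == grade, ]
  p <- as.list(row)
  over <- list(...)
  bad <- setdiff(names(over), setdiff(names(p), "grade"))
  if (length(bad)) stop("unknown phantom parameter: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  p$grid <- as.integer(grid)
  p$radius <- radius
  p$seed <- as.integer(seed)
  p$jitter_sd <- jitter_sd
  p$base_intensity <- base_intensity
  structure(p, class = "phantom_params")
}

#' Generate a phantom tumor study
#'
#' @param p a [phantom_params()] object.
#' @return a [tumor_study()] with the grade attached, unit voxel spacing,
#'   and nominal phase times.
#' @export
make_phantom_study <- function(p) {
  stopifnot(inherits(p, "phantom_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(p$seed)

  jit <- function(x) x * exp(rnorm(1, 0, p$jitter_sd))
  amp <- jit(p$surf_amp)
  r_wi <- jit(p$rate_washin)
  r_pv <- -jit(-p$rate_pv)
  r_del <- -jit(-p$rate_del)

  g <- p$grid
  ctr <- (g + 1) / 2
  r_max <- p$radius * (1 + 3 * amp)
  if (ctr + r_max + 1 > g) stop("grid too small")

  # radial surface r(theta, phi) on the voxels of a shell around the surface
  ax <- seq_len(g) - ctr
  rho2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  rho <- sqrt(rho2)
  shell <- rho <= r_max + 1
  idx <- which(shell)
  xs <- ax[(idx - 1) %% g + 1]
  ys <- ax[((idx - 1) %/% g) %% g + 1]
  zs <- ax[(idx - 1) %/% (g * g) + 1]
  rr <- rho[idx]
  theta <- acos(pmin(1, pmax(-1, ifelse(rr > 0, zs / rr, 1))))
  phi <- atan2(ys, xs) %% (2 * pi)

  # resolution cap: a degree-l wave has wavelength ~ 2*pi*r/l voxels; degrees
  # beyond ~pi*r/2 (4-voxel wavelength) voxelize into tunnels, not spikes
  hi <- min(p$band_hi, max(2L, floor(pi * p$radius / 2)))
  lo <- min(p$band_lo, hi)
  band_cols <- (lo^2 + 1L):((hi + 1L)^2)
  B <- sh_basis_matrix(theta, phi, hi)[, band_cols, drop = FALSE]
  w <- rnorm(length(band_cols))
  f <- drop(B %*% w) / sqrt(sum(w^2) / (4 * pi))  # unit RMS over the sphere
  f <- pmin(3, pmax(-3, f))
  # Voxelize; if the sampled surface folds below voxel resolution the
  # boundary acquires handles, so damp the perturbation amplitude (same
  # random field) until the boundary is a closed genus-0 surface.
  mask <- NULL
  for (try in 0:6) {
    a_try <- amp * 0.75^try
    cand <- array(FALSE, c(g, g, g))
    cand[idx] <- rr <= p$radius * (1 + a_try * f)
    if (!any(cand)) next
    cand <- repair_voxel_contacts(cand)
    ok <- is_single_component_26(cand) &&
      !inherits(tryCatch(mask_to_mesh(cand, smooth_iters = 0),
                         error = function(e) e), "error")
    if (ok) {
      mask <- cand
      amp <- a_try
      break
    }
  }
  if (is.null(mask)) stop("phantom surface not voxelizable")

  # shared texture field: correlated + white mixture, zero mean / unit-free
  corr <- gaussian_random_field(c(g, g, g), p$corr_sigma)
  white <- array(rnorm(g^3), c(g, g, g))
  field <- sqrt(1 - p$white_frac) * corr / sd(corr) +
    sqrt(p$white_frac) * white
  mv <- field[mask]
  field[mask] <- (mv - mean(mv)) / sd(mv) * p$noise_sd

  t4 <- c(0, 35, 50, 180)
  means <- cumsum(c(p$base_intensity,
                    r_wi * 35, r_pv * 15, r_del * 130))
  phases <- setNames(vector("list", 4), PHASES)
  for (k in 1:4) {
    vol <- array(60 + rnorm(g^3, 0, 1), c(g, g, g))  # liver-ish background
    vol[mask] <- means[k] * (1 + field[mask]) +
      rnorm(sum(mask), 0, 0.003 * means[k])
    phases[[k]] <- vol
  }
  study <- tumor_study(sprintf("%s_seed%d", p$grade, p$seed), phases, mask,
                       spacing = c(1, 1, 1), phase_times = t4, grade = p$grade)
  attr(study, "generative") <- list(rate_washin = r_wi, rate_pv = r_pv,
                                    rate_del = r_del, surf_amp = amp,
                                    means = means)
  study
}

# Remove edge-only and corner-only voxel contacts so the boundary-face
# surface is a closed 2-manifold: wherever two foreground voxels share only
# an edge (their two common face-neighbours background) or only a corner
# (all six in-between voxels background), one in-between voxel is filled.
# Filling can create new contacts, so the pass iterates to a fixed point.
repair_voxel_contacts <- function(mask) {
  # operate on the bounding box only; paste the repaired block back
  idx <- which(mask, arr.ind = TRUE)
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  full <- mask
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  nb <- function(a, d) shift_array(a, -d[1], -d[2], -d[3])
  axes <- diag(3)
  for (it in 1:10) {
    fixed <- FALSE
    # edge contacts
    for (a1 in 1:2) for (a2 in (a1 + 1):3) for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) {
      e1 <- s1 * axes[a1, ]; e2 <- s2 * axes[a2, ]
      bad <- mask & nb(mask, e1 + e2) & !nb(mask, e1) & !nb(mask, e2)
      if (any(bad)) {
        mask <- mask | shift_array(bad, e1[1], e1[2], e1[3])
        fixed <- TRUE
      }
    }
    # corner contacts
    for (s1 in c(-1, 1)) for (s2 in c(-1, 1)) for (s3 in c(-1, 1)) {
      e1 <- s1 * axes[1, ]; e2 <- s2 * axes[2, ]; e3 <- s3 * axes[3, ]
      bad <- mask & nb(mask, e1 + e2 + e3) &
        !nb(mask, e1) & !nb(mask, e2) & !nb(mask, e3) &
        !nb(mask, e1 + e2) & !nb(mask, e1 + e3) & !nb(mask, e2 + e3)
      if (any(bad)) {
        mask <- mask | shift_array(bad, e1[1], e1[2], e1[3])
        fixed <- TRUE
      }
    }
    if (!fixed) break
  }
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- mask
  full
}

# periodic Gaussian smoothing of white noise via FFT
gaussian_random_field <- function(dims, sigma) {
  w <- array(rnorm(prod(dims)), dims)
  k1 <- function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- dnorm(d, 0, sigma)
    k / sum(k)
  }
  K <- outer(outer(k1(dims[1]), k1(dims[2])), k1(dims[3]))
  Re(fft(fft(w) * fft(K), inverse = TRUE)) / prod(dims)
}

#' Generate a phantom cohort
#'
#' Independent phantoms with per-study seeds derived from one master seed;
#' the default composition mirrors a 19-per-grade cohort (38 benign / 19
#' intermediate / 38 malignant, i.e. 40/20/40% across the three groups).
#'
#' @param n_per_grade integer vector of length 5 (LR1..LR5 counts).
#' @param master_seed integer master seed.
#' @param ... passed to [phantom_params()] (e.g. `grid`, `radius`).
#' @return list of [tumor_study()] objects.
#' @export
make_cohort <- function(n_per_grade = rep(19L, 5), master_seed = 1L, ...) {
  stopifnot(length(n_per_grade) == 5, all(n_per_grade >= 1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(master_seed %% .Machine$integer.max)
  seeds <- sample.int(.Machine$integer.max - 1L, sum(n_per_grade))
  grades <- rep(GRADES, times = n_per_grade)
  mapply(function(gr, sd) make_phantom_study(phantom_params(gr, seed = sd, ...)),
         grades, seeds, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
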