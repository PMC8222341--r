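# Texture markers on the masked tumor region.
#
# Intensities are min-max quantized per tumor and per phase to 256 gray
# levels; first-order markers come from the normalized level histogram,
# second-order markers from a single pooled 3D gray-level co-occurrence
# matrix (all 18 offsets of Euclidean length 1 or sqrt(2), both orders, so
# the matrix is symmetric and invariant to 90-degree rotations and axis
# permutations) and from a gray-level run-length matrix pooled over the two
# in-plane axes and the through-plane axis.

#' Quantize a masked region to 256 gray levels
#'
#' Affine min-max mapping of the mask-voxel intensities to integers 0..255
#' (rounded to nearest); a constant region maps to all zeros.
#'
#' @param volume 3D numeric array.
#' @param mask binary 3D array on the same grid.
#' @return object of class `quantized_region`: `levels` (integer vector, one
#'   per mask voxel), `array` (3D integer array, `NA` outside the mask),
#'   `n` (voxel count), `bbox_dims` (mask bounding-box extents).
#' @export
normalize_gray_levels <- function(volume, mask) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  if (!identical(dim(volume), dim(mask))) stop("grid mismatch")
  v <- volume[mask]
  rng <- range(v)
  lev <- if (rng[1] == rng[2]) integer(length(v))
         else as.integer(round(255 * (v - rng[1]) / (rng[2] - rng[1])))
  a <- array(NA_integer_, dim(mask))
  a[mask] <- lev
  idx <- which(mask, arr.ind = TRUE)
  bbox <- apply(idx, 2, function(x) diff(range(x)) + 1L)
  # keep only the mask bounding box: offsets and runs never leave it
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  a <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  structure(list(levels = lev, array = a, n = length(lev),
                 bbox_dims = as.integer(bbox)),
            class = "quantized_region")
}

#' First-order histogram markers (26 values)
#'
#' Six scalars of the normalized 256-bin level histogram (mean, variance,
#' standard deviation, skewness, kurtosis, Shannon entropy in bits), the
#' histogram CDF evaluated at the ten level thresholds `k * 25.5`
#' (k = 1..10), and the ten percentile levels at cumulative probabilities
#' 10%..100%.  Population moments are used; a zero-variance region has
#' skewness and kurtosis 0 by convention.
#'
#' @param q a [normalize_gray_levels()] result.
#' @return named numeric vector of length 26.
#' @export
first_order_markers <- function(q) {
  counts <- tabulate(q$levels + 1L, nbins = 256L)
  p <- counts / q$n
  g <- 0:255
  mu <- sum(p * g)
  v2 <- sum(p * (g - mu)^2)
  sdv <- sqrt(v2)
  skew <- if (v2 > 0) sum(p * (g - mu)^3) / sdv^3 else 0
  kurt <- if (v2 > 0) sum(p * (g - mu)^4) / v2^2 else 0
  ent <- -sum(ifelse(p > 0, p * log2(p), 0))
  cdf <- cumsum(p)
  thr <- 25.5 * (1:10)
  cdf_at <- vapply(thr, function(t) cdf[max(which(g <= t))], 0)
  pct <- vapply((1:10) / 10, function(qq) g[which(cdf >= qq - 1e-12)[1]], 0)
  out <- c(mu, v2, sdv, skew, kurt, ent, cdf_at, pct)
  names(out) <- c("mean", "variance", "sd", "skewness", "kurtosis", "entropy",
                  sprintf("cdf_%03d", seq(10, 100, 10)),
                  sprintf("pct_%03d", seq(10, 100, 10)))
  out
}

# The 9 unique 3D offsets of Euclidean length 1 or sqrt(2); counting both
# orders of every pair gives the 18-neighbourhood of the rotation-invariant
# co-occurrence model.
GLCM_OFFSETS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
  c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))

#' Pooled 3D gray-level co-occurrence matrix
#'
#' Counts all voxel pairs inside the mask separated by any offset of length
#' 1 or sqrt(2) (both orders), then normalizes to sum 1.  Pooling every
#' direction into one matrix makes the descriptor invariant under the
#' octahedral symmetries of the grid.
#'
#' @param q a [normalize_gray_levels()] result with at least 2 voxels.
#' @return 256 x 256 matrix of class `cooc_matrix`, symmetric, sum 1.
#' @export
glcm <- function(q) {
  if (q$n < 2) stop("no co-occurrences")
  a <- q$array
  counts <- numeric(65536L)
  for (s in seq_len(nrow(GLCM_OFFSETS))) {
    o <- GLCM_OFFSETS[s, ]
    pr <- offset_pairs(a, o)
    if (length(pr$g1) == 0) next
    counts <- counts + tabulate(pr$g1 * 256L + pr$g2 + 1L, nbins = 65536L)
  }
  P <- matrix(counts, 256, 256, byrow = TRUE)  # row = g1, col = g2
  P <- P + t(P)
  tot <- sum(P)
  if (tot == 0) stop("no co-occurrences")
  structure(P / tot, class = c("cooc_matrix", "matrix"))
}

# gray-level pairs for one displacement, mask-restricted
offset_pairs <- function(a, o) {
  d <- dim(a)
  if (any(abs(o) >= d)) return(list(g1 = integer(0), g2 = integer(0)))
  src <- function(n, s) if (s >= 0) seq_len(n - s) else (1 - s):n
  dst <- function(n, s) if (s >= 0) (1 + s):n else seq_len(n + s)
  g1 <- a[src(d[1], o[1]), src(d[2], o[2]), src(d[3], o[3])]
  g2 <- a[dst(d[1], o[1]), dst(d[2], o[2]), dst(d[3], o[3])]
  ok <- !is.na(g1) & !is.na(g2)
  list(g1 = g1[ok], g2 = g2[ok])
}

#' Haralick markers of a co-occurrence matrix (6 values)
#'
#' Contrast, dissimilarity, homogeneity (inverse difference moment), angular
#' second moment, energy (its square root), and correlation.  Correlation is
#' 1 by convention when the marginal variance vanishes.
#'
#' @param P a [glcm()] matrix (must sum to 1).
#' @return named numeric vector of length 6.
#' @export
glcm_markers <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("matrix not normalized")
  g <- 0:255
  D <- outer(g, g, `-`)
  contrast <- sum(P * D^2)
  dissim <- sum(P * abs(D))
  homog <- sum(P / (1 + D^2))
  asm <- sum(P^2)
  px <- rowSums(P)
  mu <- sum(px * g)
  s2 <- sum(px * (g - mu)^2)
  corr <- if (s2 > 0) sum(P * outer(g - mu, g - mu)) / s2 else 1
  c(contrast = contrast, dissimilarity = dissim, homogeneity = homog,
    asm = asm, energy = sqrt(asm), correlation = corr)
}

#' Pooled gray-level run-length matrix
#'
#' Maximal constant-level runs of mask voxels are collected along the two
#' in-plane axes and the through-plane axis (D = 3 directions pooled); a run
#' breaks at a mask boundary or a level change.  `M[g+1, l]` counts runs of
#' level g and length l; the column count is the largest bounding-box extent
#' of the mask.
#'
#' @param q a [normalize_gray_levels()] result.
#' @return 256 x R matrix of class `runlength_matrix` with attribute
#'   `directions = 3` and `n_voxels`.
#' @export
glrlm <- function(q) {
  a <- q$array
  R <- max(q$bbox_dims)
  M <- matrix(0, 256L, R)
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  for (pm in perms) {
    ap <- aperm(a, pm)
    d <- dim(ap)
    padded <- array(NA_integer_, c(d[1] + 1L, d[2], d[3]))
    padded[seq_len(d[1]), , ] <- ap
    r <- rle(as.vector(padded))
    keep <- !is.na(r$values)
    if (!any(keep)) next
    gl <- r$values[keep]
    ln <- r$lengths[keep]
    for (k in seq_along(gl)) M[gl[k] + 1L, ln[k]] <- M[gl[k] + 1L, ln[k]] + 1
  }
  structure(M, class = c("runlength_matrix", "matrix"),
            directions = 3L, n_voxels = q$n)
}

#' Run-length markers (12 values)
#'
#' The standard run-length statistics on the pooled matrix: SRE, LRE, GLN,
#' RLN, RP, LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE and run entropy.
#' Gray levels are weighted as g + 1 (1..256) so the low/high gray-level
#' emphases stay finite at level 0.  Run percentage divides the run count by
#' D * N, the voxel count summed over the three pooled directions, so it
#' lies in (0, 1].
#'
#' @param M a [glrlm()] matrix.
#' @return named numeric vector of length 12.
#' @export
glrlm_markers <- function(M) {
  nr <- sum(M)
  if (nr == 0) stop("empty run matrix")
  D <- attr(M, "directions")
  N <- attr(M, "n_voxels")
  gw <- (1:256)            # gray-level weights, 1-based
  lw <- seq_len(ncol(M))   # run lengths
  rg <- rowSums(M)         # runs per gray level
  rl <- colSums(M)         # runs per length
  p <- M / nr
  c(gln = sum(rg^2) / nr,
    hglre = sum(rg * gw^2) / nr,
    lre = sum(rl * lw^2) / nr,
    lrhgle = sum(M * outer(gw^2, lw^2)) / nr,
    lrlgle = sum(M * outer(1 / gw^2, lw^2)) / nr,
    lglre = sum(rg / gw^2) / nr,
    re = -sum(ifelse(p > 0, p * log2(p), 0)),
    rln = sum(rl^2) / nr,
    rp = nr / (D * N),
    sre = sum(rl / lw^2) / nr,
    srhgle = sum(M * outer(gw^2, 1 / lw^2)) / nr,
    srlgle = sum(M * outer(1 / gw^2, 1 / lw^2)) / nr)
}

#' Textural markers of a study (176 values)
#'
#' Per phase: quantize the masked intensities, then 26 first-order + 6 GLCM
#' + 12 GLRLM markers.  Names carry the phase prefix (`pre_`, `art_`,
#' `pv_`, `del_`); the returned order groups first all first-order blocks,
#' then the GLCM blocks, then the GLRLM blocks.
#'
#' @param study a [tumor_study()].
#' @return named numeric vector of length 176.
#' @export
textural_markers <- function(study) {
  pfx <- c(pre = "pre", arterial = "art", venous = "pv", delayed = "del")
  fo <- list(); gc <- list(); gr <- list()
  for (ph in PHASES) {
    q <- normalize_gray_levels(study$phases[[ph]], study$mask)
    f <- first_order_markers(q)
    names(f) <- paste0(pfx[ph], "_fo_", names(f))
    fo[[ph]] <- f
    cm <- glcm_markers(glcm(q))
    names(cm) <- paste0(pfx[ph], "_glcm_", names(cm))
    gc[[ph]] <- cm
    rm <- glrlm_markers(glrlm(q))
    names(rm) <- paste0(pfx[ph], "_glrlm_", names(rm))
    gr[[ph]] <- rm
  }
  c(do.call(c, unname(fo)), do.call(c, unname(gc)), do.call(c, unname(gr)))
}
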