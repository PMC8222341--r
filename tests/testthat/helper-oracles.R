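# Brute-force oracles, deliberately independent of the implementation:
# plain loops over voxels, pairs and runs.

# exhaustive pair enumeration over all offsets of length 1 or sqrt(2)
oracle_glcm <- function(a) {
  d <- dim(a)
  P <- matrix(0, 256, 256)
  offs <- list()
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    l2 <- di^2 + dj^2 + dk^2
    if (l2 %in% c(1, 2)) offs[[length(offs) + 1]] <- c(di, dj, dk)
  }
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    g1 <- a[i, j, k]
    if (is.na(g1)) next
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
      g2 <- a[ii, jj, kk]
      if (is.na(g2)) next
      P[g1 + 1, g2 + 1] <- P[g1 + 1, g2 + 1] + 1
    }
  }
  P / sum(P)
}

# exhaustive run enumeration along x, y, z
oracle_glrlm <- function(a, R) {
  M <- matrix(0, 256, R)
  d <- dim(a)
  scan_line <- function(vals) {
    cur <- NA_integer_
    len <- 0L
    for (v in c(vals, NA)) {
      if (!is.na(v) && !is.na(cur) && v == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) M[cur + 1, len] <<- M[cur + 1, len] + 1
        cur <- v
        len <- 1L
      }
    }
  }
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) scan_line(a[, j, k])
  for (i in seq_len(d[1])) for (k in seq_len(d[3])) scan_line(a[i, , k])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) scan_line(a[i, j, ])
  M
}

# first-order statistics straight from the level vector
oracle_first_order <- function(lev) {
  n <- length(lev)
  mu <- mean(lev)
  v2 <- mean((lev - mu)^2)
  p <- tabulate(lev + 1, 256) / n
  cdf <- cumsum(p)
  c(mean = mu, variance = v2, sd = sqrt(v2),
    skewness = if (v2 > 0) mean((lev - mu)^3) / v2^1.5 else 0,
    kurtosis = if (v2 > 0) mean((lev - mu)^4) / v2^2 else 0,
    entropy = -sum(p[p > 0] * log2(p[p > 0])),
    setNames(vapply(25.5 * (1:10), function(t) cdf[max(which(0:255 <= t))], 0),
             sprintf("cdf_%03d", seq(10, 100, 10))),
    setNames(vapply((1:10) / 10, function(q) (0:255)[which(cdf >= q - 1e-12)[1]], 0),
             sprintf("pct_%03d", seq(10, 100, 10))))
}
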