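# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own kernels: plain R loops and closed forms only.

# even-odd point-in-polygon by scalar crossing count (+x ray)
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  crossings <- 0L
  for (e in seq_len(n)) {
    x1 <- poly[e, 1]; y1 <- poly[e, 2]
    j <- if (e == n) 1L else e + 1L
    x2 <- poly[j, 1]; y2 <- poly[j, 2]
    if (y1 == y2) next
    if ((y1 <= py) != (y2 <= py)) {
      xint <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      if (px < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# nearest-neighbor pull-warp, scalar loop (ties: floor(x + 0.5))
oracle_warp_nearest <- function(vol, u) {
  d <- dim(vol)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    p <- c(i - 1, j - 1, k - 1) + u[i, j, k, ]
    q <- floor(p + 0.5)
    if (all(q >= 0) && all(q <= d - 1))
      out[i, j, k] <- vol[q[1] + 1, q[2] + 1, q[3] + 1]
  }
  out
}

# trilinear pull-warp, scalar loop, fill 0 outside the voxel-center box
oracle_warp_linear <- function(vol, u) {
  d <- dim(vol)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    p <- c(i - 1, j - 1, k - 1) + u[i, j, k, ]
    if (any(p < 0) || any(p > d - 1)) next
    p0 <- pmin(floor(p), d - 2)
    f <- p - p0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
           (if (cc) f[3] else 1 - f[3])
      acc <- acc + w * vol[p0[1] + a + 1, p0[2] + b + 1, p0[3] + cc + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# cubic B-spline basis function
oracle_b3 <- function(t) {
  t <- abs(t)
  ifelse(t < 1, 2 / 3 - t^2 + t^3 / 2,
         ifelse(t < 2, (2 - t)^3 / 6, 0))
}

# FFD displacement at one point by direct basis summation with
# edge-replicated coefficients
oracle_ffd_point <- function(coef, extent, pt) {
  n <- dim(coef)[1:3]
  h <- (extent - 1) / (n - 1)
  u <- numeric(3)
  for (ci in -1:(n[1])) for (cj in -1:(n[2])) for (ck in -1:(n[3])) {
    w <- oracle_b3(pt[1] / h[1] - ci) * oracle_b3(pt[2] / h[2] - cj) *
         oracle_b3(pt[3] / h[3] - ck)
    if (w == 0) next
    ii <- min(max(ci, 0), n[1] - 1) + 1
    jj <- min(max(cj, 0), n[2] - 1) + 1
    kk <- min(max(ck, 0), n[3] - 1) + 1
    u <- u + w * coef[ii, jj, kk, ]
  }
  u
}

# boundary voxels by direct neighbor inspection (0-based indices)
oracle_boundary <- function(m) {
  d <- dim(m)
  out <- NULL
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (m[i, j, k] == 0) next
    on_surface <- FALSE
    for (dd in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      q <- c(i, j, k) + dd
      if (any(q < 1) || any(q > d) || m[q[1], q[2], q[3]] == 0) {
        on_surface <- TRUE
        break
      }
    }
    if (on_surface) out <- rbind(out, c(i, j, k) - 1)
  }
  out
}

# pooled symmetric percentile of surface distances, all-pairs
oracle_hd <- function(ma, mb, spacing, percentile = 95) {
  pa <- sweep(oracle_boundary(ma), 2, spacing, FUN = "*")
  pb <- sweep(oracle_boundary(mb), 2, spacing, FUN = "*")
  dmat <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                Vectorize(function(i, j) sqrt(sum((pa[i, ] - pb[j, ])^2))))
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  unname(quantile(c(dab, dba), percentile / 100, type = 7))
}

# a smooth band-limited test image: a few low-frequency cosines
smooth_phantom_array <- function(d) {
  co <- propnet:::grid_points(c(d, d, d)) / (d - 1)
  v <- 0.5 + 0.2 * cos(2 * pi * co[, 1]) * sin(2 * pi * co[, 2]) +
    0.15 * sin(2 * pi * co[, 3]) + 0.1 * cos(2 * pi * (co[, 1] + co[, 3]))
  array(v, c(d, d, d))
}

random_mask_volume <- function(d, seed, spacing = c(1, 1, 1)) {
  with_seed_local(seed, {
    ctr <- (d - 1) / 2 + runif(3, -1, 1)
    r <- runif(3, d / 5, d / 3)
    pts <- propnet:::grid_points(c(d, d, d))
    q <- ((pts[, 1] - ctr[1]) / r[1])^2 + ((pts[, 2] - ctr[2]) / r[2])^2 +
      ((pts[, 3] - ctr[3]) / r[3])^2
    volume3d(array(as.double(q <= 1), c(d, d, d)), spacing = spacing,
             is_mask = TRUE)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

smooth_field <- function(d, amplitude, seed) {
  to_dense_field(sample_bspline(3, amplitude, d, seed = seed), d)
}
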