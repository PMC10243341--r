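# Independent reference implementations used as oracles. These share
# no code with the package internals.

# Siddon oracle: parametric crossing points of a ray with all grid
# lines, sorted; each segment's midpoint identifies its pixel. Returns
# (pixel, length_cm) like siddon_trace().
oracle_trace <- function(p0, p1, n, h = 1.0) {
  lim <- n * h / 2
  d <- p1 - p0
  ts <- c(0, 1)
  for (ax in 1:2) {
    if (abs(d[ax]) > 1e-12) {
      edges <- seq(-lim, lim, by = h)
      ts <- c(ts, (edges - p0[ax]) / d[ax])
    }
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  pix <- integer(0); len <- numeric(0)
  for (k in seq_len(length(ts) - 1)) {
    tm <- (ts[k] + ts[k + 1]) / 2
    pt <- p0 + tm * d
    if (any(abs(pt) >= lim)) next
    ix <- floor((pt[1] + lim) / h)
    iy <- floor((pt[2] + lim) / h)
    seg <- (ts[k + 1] - ts[k]) * sqrt(sum(d^2)) / 10
    if (seg <= 0) next
    pix <- c(pix, ix + iy * n + 1)
    len <- c(len, seg)
  }
  # merge duplicate pixels (possible when a crossing is degenerate)
  agg <- tapply(len, pix, sum)
  data.frame(pixel = as.integer(names(agg)), length_cm = as.numeric(agg))
}

# dense system matrix built ray by ray with the oracle tracer
oracle_system_matrix <- function(geom) {
  ep <- perfct:::ray_endpoints(geom)
  n <- geom$grid_size
  A <- matrix(0, geom$n_views * geom$n_detectors, n * n)
  for (v in seq_len(geom$n_views)) {
    for (dd in seq_len(geom$n_detectors)) {
      tr <- oracle_trace(c(ep$sx[v], ep$sy[v]),
                         c(ep$det_x[dd, v], ep$det_y[dd, v]),
                         n, geom$pixel_spacing)
      row <- (v - 1) * geom$n_detectors + dd
      if (nrow(tr)) A[row, tr$pixel] <- tr$length_cm
    }
  }
  A
}

# brute-force SSIM with explicit window loops (uniform-weight check is
# avoided: uses the same Gaussian weights, computed independently)
oracle_ssim <- function(x, r, window = 11, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03) {
  h <- (window - 1) / 2
  g1 <- exp(-(-h:h)^2 / (2 * sigma^2))
  w <- outer(g1, g1); w <- w / sum(w)
  L <- max(r) - min(r); if (L <= 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  n <- nrow(x); m <- ncol(x)
  vals <- c()
  for (i in seq_len(n - window + 1)) {
    for (j in seq_len(m - window + 1)) {
      wx <- x[i:(i + window - 1), j:(j + window - 1)]
      wr <- r[i:(i + window - 1), j:(j + window - 1)]
      mx <- sum(w * wx); mr <- sum(w * wr)
      vx <- sum(w * wx^2) - mx^2
      vr <- sum(w * wr^2) - mr^2
      cv <- sum(w * wx * wr) - mx * mr
      vals <- c(vals, ((2 * mx * mr + C1) * (2 * cv + C2)) /
                        ((mx^2 + mr^2 + C1) * (vx + vr + C2)))
    }
  }
  mean(vals)
}

# dense matrix of a linear operator, by applying it to unit vectors
operator_as_matrix <- function(op, in_dim) {
  n_in <- prod(in_dim)
  cols <- vector("list", n_in)
  for (k in seq_len(n_in)) {
    e <- array(0, in_dim); e[k] <- 1
    cols[[k]] <- as.vector(op(e))
  }
  do.call(cbind, cols)
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)),
                                                     1e-300)

# small lesioned phantom study shared by perfusion/evaluation tests
small_study <- function(grid = 48L, frames = 24L, seed = 1L) {
  spec <- phantom_spec(grid_size = grid, n_frames = frames, dt = 1,
                       pixel_spacing = 256 / grid, lesion = list(),
                       seed = seed)
  lm <- build_phantom(spec)
  list(spec = spec, lm = lm, series = render_dynamic_hu(lm, spec))
}
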