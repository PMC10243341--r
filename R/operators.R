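# Discrete spatiotemporal differential operators with exact adjoints.
# Forward differences with replicate (Neumann) boundary, so the last
# difference along each dimension is zero; the corresponding negative
# adjoints (divergences) are backward differences with the matching
# boundary rows.

diff_fwd <- function(x, dim) {
  diff_fwd_cpp(x, base::dim(x), as.integer(dim))
}

# negative adjoint of diff_fwd along the same dimension
div_1d <- function(p, dim) {
  div_1d_cpp(p, base::dim(p), as.integer(dim))
}

#' Spatiotemporal gradient of a dynamic series
#'
#' Forward differences with replicate boundary along x, y and time; the
#' temporal component is scaled by `temporal_weight`. [div3()] is the
#' exact negative adjoint: `<grad3(x), p> = -<x, div3(p)>`.
#'
#' @param x 3-D array (x, y, frame).
#' @param temporal_weight Scale of the temporal gradient relative to the
#'   spatial ones (default 1).
#' @param warn_single_frame Warn when the series has a single frame (the
#'   temporal component is then structurally zero).
#' @return 4-D array (x, y, frame, component), components in the order
#'   x, y, t.
#' @export
grad3 <- function(x, temporal_weight = 1.0, warn_single_frame = TRUE) {
  stopifnot(length(dim(x)) == 3L)
  if (dim(x)[3] == 1L && warn_single_frame)
    warning("single-frame series: temporal gradient component is zero")
  d <- dim(x)
  g <- array(0, dim = c(d, 3L))
  g[, , , 1] <- diff_fwd(x, 1L)
  g[, , , 2] <- diff_fwd(x, 2L)
  if (d[3] > 1L) g[, , , 3] <- temporal_weight * diff_fwd(x, 3L)
  g
}

#' Divergence: negative adjoint of [grad3()]
#'
#' @param p 4-D array (x, y, frame, component).
#' @param temporal_weight Must match the value used in [grad3()].
#' @return 3-D array (x, y, frame).
#' @export
div3 <- function(p, temporal_weight = 1.0) {
  stopifnot(length(dim(p)) == 4L, dim(p)[4] == 3L)
  out <- div_1d(comp3(p, 1L), 1L) + div_1d(comp3(p, 2L), 2L)
  if (dim(p)[3] > 1L)
    out <- out + temporal_weight * div_1d(comp3(p, 3L), 3L)
  out
}

# component slices that keep singleton spatial/temporal dimensions
comp3 <- function(a, k) array(a[, , , k], dim = dim(a)[1:3])
comp5 <- function(a, k, l) array(a[, , , k, l], dim = dim(a)[1:3])

#' Symmetrised gradient of a vector field
#'
#' For a 3-component field v on the series grid, returns the symmetric
#' tensor `E(v)_kl = (D_k v_l + D_l v_k) / 2` (forward differences,
#' replicate boundary, temporal component weighted). The full 3 x 3
#' tensor is stored, so the pointwise Frobenius magnitude counts
#' off-diagonal components twice, the standard isotropic convention.
#' [sym_div()] is the exact negative adjoint on symmetric fields.
#'
#' @param v 5-D array (x, y, frame, component) of dimension
#'   `c(nx, ny, nt, 3)`.
#' @param temporal_weight Temporal derivative scale (default 1).
#' @return 6-D array `c(nx, ny, nt, 3, 3)`, symmetric in its last two
#'   indices.
#' @export
sym_grad <- function(v, temporal_weight = 1.0) {
  stopifnot(length(dim(v)) == 4L, dim(v)[4] == 3L)
  d <- dim(v)[1:3]
  w <- c(1, 1, temporal_weight)
  E <- array(0, dim = c(d, 3L, 3L))
  dv <- vector("list", 3L)
  for (k in 1:3) {
    dv[[k]] <- lapply(1:3, function(l) {
      if (k == 3L && d[3] == 1L) array(0, d)
      else w[k] * diff_fwd(comp3(v, l), k)
    })
  }
  for (k in 1:3) for (l in 1:3)
    E[, , , k, l] <- 0.5 * (dv[[k]][[l]] + dv[[l]][[k]])
  E
}

#' Divergence of a symmetric tensor field: negative adjoint of
#' [sym_grad()]
#'
#' @param r 6-D array `c(nx, ny, nt, 3, 3)`, symmetric in its last two
#'   indices.
#' @param temporal_weight Must match the value used in [sym_grad()].
#' @return 5-D array `c(nx, ny, nt, 3)`.
#' @export
sym_div <- function(r, temporal_weight = 1.0) {
  stopifnot(length(dim(r)) == 5L, all(dim(r)[4:5] == 3L))
  d <- dim(r)[1:3]
  w <- c(1, 1, temporal_weight)
  out <- array(0, dim = c(d, 3L))
  for (l in 1:3) {
    acc <- array(0, d)
    for (k in 1:3) {
      if (k == 3L && d[3] == 1L) next
      # symmetrise so the adjoint is exact also for non-symmetric input
      rkl <- 0.5 * (comp5(r, k, l) + comp5(r, l, k))
      acc <- acc + w[k] * div_1d(rkl, k)
    }
    out[, , , l] <- acc
  }
  out
}
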