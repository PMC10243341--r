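# Proximal operators used by the primal-dual solver.

#' Isotropic soft thresholding
#'
#' Shrinks the Euclidean magnitude of `z` by `t`, flooring at zero and
#' preserving direction; for a scalar this is ordinary soft
#' thresholding.
#'
#' @param z Numeric scalar or vector (treated as one vector).
#' @param t Threshold, >= 0.
#' @return Shrunk value, same shape as `z`.
#' @examples
#' soft_threshold(3, 1)        # 2
#' soft_threshold(c(3, 4), 5)  # c(0, 0)
#' @export
soft_threshold <- function(z, t) {
  stopifnot(t >= 0)
  m <- sqrt(sum(z^2))
  if (m <= t) return(z * 0)
  z * (1 - t / m)
}

# pointwise soft threshold of a component field: magnitude over the
# trailing component dims (everything after the first 3)
soft_threshold_field <- function(z, t) {
  d <- dim(z)
  np <- prod(d[1:3])
  zc <- matrix(z, nrow = np)
  m <- sqrt(rowSums(zc^2))
  scale <- pmax(0, 1 - t / pmax(m, .Machine$double.eps))
  array(zc * scale, dim = d)
}

# pointwise projection of a dual field onto the radius-t magnitude ball
project_ball_field <- function(p, t) {
  d <- dim(p)
  np <- prod(d[1:3])
  pc <- matrix(p, nrow = np)
  m <- sqrt(rowSums(pc^2))
  scale <- 1 / pmax(1, m / t)
  array(pc * scale, dim = d)
}

#' Singular-value thresholding
#'
#' Proximal operator of `t * ||.||_*` (nuclear norm): soft-thresholds
#' the singular values and recomposes.
#'
#' @param M Numeric matrix.
#' @param t Threshold, >= 0.
#' @return Matrix of the same dimension.
#' @examples
#' svt(diag(c(3, 1)), 2)  # diag(c(1, 0))
#' @export
svt <- function(M, t) {
  stopifnot(t >= 0)
  if (any(!is.finite(M))) stop("non-finite entries")
  if (t == 0) return(M)
  s <- svd(M)
  keep <- pmax(s$d - t, 0)
  nz <- keep > 0
  if (!any(nz)) return(M * 0)
  s$u[, nz, drop = FALSE] %*% (keep[nz] * t(s$v[, nz, drop = FALSE]))
}
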