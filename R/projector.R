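# Equiangular fan-beam geometry, Siddon system matrix, and the
# Beer-Lambert counting-noise model.

#' Define an equiangular fan-beam scan geometry
#'
#' The source rotates on a circle of radius `source_to_iso` around the
#' isocentre (the image centre); the detector is an arc centred on the
#' source. Detector bins are equiangular and symmetric about the central
#' ray, with the fan half-angle chosen so that the field of view covers
#' the inscribed circle of the reconstruction grid with one bin of
#' margin.
#'
#' @param n_views Number of projection angles, equally spaced over
#'   `angular_range` degrees.
#' @param n_detectors Number of detector bins on the arc.
#' @param source_to_iso Source-to-isocentre distance in mm.
#' @param iso_to_detector Isocentre-to-detector distance in mm.
#' @param grid_size Reconstruction grid size in pixels (square grid).
#' @param pixel_spacing Pixel spacing in mm.
#' @param angular_range Total angular range in degrees (default 360).
#' @return An object of class `scan_geometry`.
#' @examples
#' geom <- scan_geometry(n_views = 60, n_detectors = 64, grid_size = 32)
#' @export
scan_geometry <- function(n_views = 1000L, n_detectors = 377L,
                          source_to_iso = 570, iso_to_detector = 470,
                          grid_size = 256L, pixel_spacing = 1.0,
                          angular_range = 360) {
  stopifnot(n_views >= 1L, n_detectors >= 2L, source_to_iso > 0,
            iso_to_detector > 0, grid_size >= 2L, pixel_spacing > 0)
  r_fov <- grid_size * pixel_spacing / 2        # inscribed circle, mm
  if (r_fov >= source_to_iso)
    stop("source_to_iso must exceed the field-of-view radius")
  gamma_half <- asin(r_fov / source_to_iso)
  # one-bin margin on each side of the required half fan
  dgamma <- 2 * gamma_half / (n_detectors - 2L)
  gammas <- (seq_len(n_detectors) - (n_detectors + 1) / 2) * dgamma
  betas <- (seq_len(n_views) - 1) * (angular_range * pi / 180) / n_views
  structure(list(
    n_views = as.integer(n_views), n_detectors = as.integer(n_detectors),
    source_to_iso = source_to_iso, iso_to_detector = iso_to_detector,
    grid_size = as.integer(grid_size), pixel_spacing = pixel_spacing,
    angular_range = angular_range,
    fan_half_angle = gamma_half + dgamma, dgamma = dgamma,
    gammas = gammas, betas = betas
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "fan-beam scan geometry: %d views / %.0f deg, %d detectors (arc)\n",
    x$n_views, x$angular_range, x$n_detectors))
  cat(sprintf("  SID %.0f mm, SDD %.0f mm, fan half-angle %.2f deg\n",
              x$source_to_iso, x$source_to_iso + x$iso_to_detector,
              x$fan_half_angle * 180 / pi))
  cat(sprintf("  grid %d x %d px at %.2f mm\n",
              x$grid_size, x$grid_size, x$pixel_spacing))
  invisible(x)
}

# source and detector positions (mm) for every view
ray_endpoints <- function(geom) {
  sdd <- geom$source_to_iso + geom$iso_to_detector
  sx <- geom$source_to_iso * cos(geom$betas)
  sy <- geom$source_to_iso * sin(geom$betas)
  # central direction for view v is -(cos beta, sin beta); detector d is
  # that direction rotated by gamma_d (counter-clockwise)
  det_x <- matrix(0, geom$n_detectors, geom$n_views)
  det_y <- matrix(0, geom$n_detectors, geom$n_views)
  for (v in seq_len(geom$n_views)) {
    ux <- -cos(geom$betas[v]); uy <- -sin(geom$betas[v])
    dx <- ux * cos(geom$gammas) - uy * sin(geom$gammas)
    dy <- ux * sin(geom$gammas) + uy * cos(geom$gammas)
    det_x[, v] <- sx[v] + sdd * dx
    det_y[, v] <- sy[v] + sdd * dy
  }
  list(sx = sx, sy = sy, det_x = det_x, det_y = det_y)
}

# package-local cache of system matrices keyed by geometry parameters
.perfct_cache <- new.env(parent = emptyenv())

geom_key <- function(geom) {
  paste(geom$n_views, geom$n_detectors, geom$source_to_iso,
        geom$iso_to_detector, geom$grid_size, geom$pixel_spacing,
        geom$angular_range, sep = "|")
}

#' Sparse Siddon system matrix for a scan geometry
#'
#' Rows index rays (detector fastest within view), columns index pixels
#' (x fastest, matching `as.vector()` of an image matrix). Entries are
#' ray-pixel intersection lengths in cm, so `A %*% as.vector(mu)` gives
#' dimensionless line integrals for `mu` in 1/cm. The matrix is cached
#' per geometry; its spectral norm (power iteration) is cached as
#' attribute `"opnorm"`.
#'
#' @param geom A [scan_geometry()].
#' @param use_cache Reuse a previously built matrix for an identical
#'   geometry (default `TRUE`).
#' @return A `dgCMatrix` of dimension `n_views * n_detectors` by
#'   `grid_size^2`.
#' @export
system_matrix <- function(geom, use_cache = TRUE) {
  stopifnot(inherits(geom, "scan_geometry"))
  key <- geom_key(geom)
  if (use_cache && !is.null(.perfct_cache[[key]]))
    return(.perfct_cache[[key]])
  ep <- ray_endpoints(geom)
  tri <- siddon_system_cpp(ep$sx, ep$sy, ep$det_x, ep$det_y,
                           geom$grid_size, geom$pixel_spacing)
  A <- Matrix::sparseMatrix(
    i = tri$i + 1L, j = tri$j + 1L, x = tri$x,
    dims = c(geom$n_views * geom$n_detectors, geom$grid_size^2))
  attr(A, "opnorm") <- opnorm_sparse(A)
  if (use_cache) .perfct_cache[[key]] <- A
  A
}

# spectral norm by power iteration on t(A) %*% A; deterministic start
opnorm_sparse <- function(A, n_iter = 50L) {
  v <- rep(1, ncol(A)) + sin(seq_len(ncol(A)))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(n_iter)) {
    w <- as.numeric(Matrix::crossprod(A, A %*% v))
    lam <- sum(w * v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
  }
  sqrt(lam)
}

#' Field-of-view mask of a scan geometry
#'
#' Logical matrix marking pixels inside the inscribed reconstruction
#' circle (the region every fan covers). Reconstructions are defined
#' on this support.
#'
#' @param geom A [scan_geometry()].
#' @return Logical `grid_size` x `grid_size` matrix.
#' @export
fov_mask <- function(geom) {
  n <- geom$grid_size
  cc <- seq_len(n) - (n + 1) / 2
  sqrt(outer(cc^2, cc^2, "+")) <= n / 2
}

#' Trace a single ray through a pixel grid (Siddon's algorithm)
#'
#' @param source Numeric length-2, source position in mm.
#' @param detector Numeric length-2, detector position in mm.
#' @param grid_size Grid size in pixels.
#' @param pixel_spacing Pixel spacing in mm.
#' @return A data frame with 1-based `pixel` (column-major index, x
#'   fastest) and `length_cm`; zero rows if the ray misses the grid.
#' @examples
#' siddon_trace(c(-100, 0.5), c(100, 0.5), grid_size = 10)
#' @export
siddon_trace <- function(source, detector, grid_size,
                         pixel_spacing = 1.0) {
  stopifnot(length(source) == 2, length(detector) == 2)
  if (all(source == detector)) stop("degenerate (zero-length) ray")
  tr <- siddon_trace_cpp(as.numeric(source), as.numeric(detector),
                         as.integer(grid_size), pixel_spacing)
  data.frame(pixel = tr$pixel + 1L, length_cm = tr$length_cm)
}

#' Forward project an attenuation image
#'
#' Computes line integrals `A %*% mu` for every ray of the geometry.
#'
#' @param mu Attenuation image (1/cm), `grid_size` x `grid_size` matrix.
#' @param geom A [scan_geometry()].
#' @return Sinogram matrix, `n_detectors` x `n_views`.
#' @export
forward_project <- function(mu, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!all(dim(mu) == geom$grid_size))
    stop("image dimensions do not match geometry grid")
  if (any(!is.finite(mu))) stop("non-finite attenuation values")
  A <- system_matrix(geom)
  matrix(as.numeric(A %*% as.vector(mu)),
         nrow = geom$n_detectors, ncol = geom$n_views)
}

#' Back project a sinogram (adjoint of the forward projector)
#'
#' Exact transpose of the Siddon system matrix; this is the unweighted
#' adjoint used by iterative solvers, not filtered back-projection.
#'
#' @param sino Sinogram matrix, `n_detectors` x `n_views`.
#' @param geom A [scan_geometry()].
#' @return Image matrix, `grid_size` x `grid_size`.
#' @export
back_project <- function(sino, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (!all(dim(sino) == c(geom$n_detectors, geom$n_views)))
    stop("sinogram dimensions do not match geometry")
  if (any(!is.finite(sino))) stop("non-finite sinogram values")
  A <- system_matrix(geom)
  matrix(as.numeric(Matrix::crossprod(A, as.vector(sino))),
         nrow = geom$grid_size, ncol = geom$grid_size)
}

#' Counting-noise model for low-dose projection data
#'
#' Photons surviving a ray with line integral P follow the Beer-Lambert
#' law, `I = I0 * exp(-P)`. Measured counts are Poisson draws plus
#' Gaussian readout noise; counts at or below zero are clamped to
#' `clamp_floor` before the log transform back to line integrals.
#'
#' @param I0 Incident photons per ray (default 2.5e5, roughly a 66 mAs
#'   exposure).
#' @param readout_variance Variance of additive Gaussian readout noise
#'   in counts^2 (default 10).
#' @param clamp_floor Minimum count substituted for non-positive
#'   measurements (default 1).
#' @param seed Integer seed; each frame uses an independent stream
#'   derived from it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(I0 = 2.5e5, readout_variance = 10,
                        clamp_floor = 1, seed = 1L) {
  if (I0 <= 0) stop("I0 must be positive")
  stopifnot(readout_variance >= 0, clamp_floor >= 1)
  structure(list(I0 = I0, readout_variance = readout_variance,
                 clamp_floor = clamp_floor, seed = as.integer(seed)),
            class = "noise_model")
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Add Beer-Lambert counting noise to a sinogram
#'
#' @param sino Sinogram matrix (line integrals) or 3-D array
#'   (detector, view, frame).
#' @param model A [noise_model()].
#' @param frame Frame index used to derive the per-frame noise stream
#'   when `sino` is a single frame (default 1).
#' @return Noisy line integrals, same shape as `sino`.
#' @export
add_counting_noise <- function(sino, model, frame = 1L) {
  stopifnot(inherits(model, "noise_model"))
  if (any(!is.finite(sino))) stop("non-finite line integrals")
  d <- dim(sino)
  if (length(d) == 3L) {
    out <- sino
    for (f in seq_len(d[3]))
      out[, , f] <- add_counting_noise(sino[, , f], model, frame = f)
    return(out)
  }
  frame_seed <- (model$seed * 1009L + as.integer(frame)) %% 2147483647L
  with_seed(frame_seed, {
    I_mean <- model$I0 * exp(-sino)
    counts <- stats::rpois(length(I_mean), lambda = as.vector(I_mean))
    if (model$readout_variance > 0)
      counts <- counts + stats::rnorm(length(counts),
                                      sd = sqrt(model$readout_variance))
    counts[counts <= 0] <- model$clamp_floor
    out <- log(model$I0 / counts)
    dim(out) <- d
    out
  })
}
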