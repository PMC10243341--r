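# Equiangular fan-beam filtered back-projection (Ram-Lak and
# Shepp-Logan filters).

# Discrete equiangular ramp kernel, sampled in the spatial (angular)
# domain: g(0) = 1/(8 dg^2), g(n even) = 0,
# g(n odd) = -1/2 * (1 / (pi * sin(n dg)))^2.
# Sampling the kernel (rather than inverting |f|) keeps the DC response
# consistent with the discrete convolution and avoids a bias offset.
ramp_kernel_equiangular <- function(n_det, dgamma) {
  n <- -(n_det - 1):(n_det - 1)
  g <- numeric(length(n))
  g[n == 0] <- 1 / (8 * dgamma^2)
  odd <- n %% 2 != 0
  g[odd] <- -0.5 / (pi * sin(n[odd] * dgamma))^2
  g
}

# frequency response of the chosen filter on a padded grid
filter_response <- function(n_det, dgamma, filter, n_pad) {
  g <- ramp_kernel_equiangular(n_det, dgamma)
  gpad <- numeric(n_pad)
  # wrap kernel: indices -(n_det-1)..(n_det-1)
  idx <- -(n_det - 1):(n_det - 1)
  gpad[(idx %% n_pad) + 1] <- g
  H <- Re(stats::fft(gpad))
  if (filter == "shepp-logan") {
    f <- c(seq(0, floor(n_pad / 2)), seq(-ceiling(n_pad / 2) + 1, -1))
    fn <- n_pad / 2                      # Nyquist index
    s <- ifelse(f == 0, 1, sin(pi * f / (2 * fn)) / (pi * f / (2 * fn)))
    H <- H * s
  }
  H
}

match_filter <- function(filter) {
  match.arg(tolower(filter), c("ram-lak", "shepp-logan"))
}

#' Filtered back-projection of one fan-beam sinogram frame
#'
#' Standard equiangular fan-beam FBP: cosine pre-weighting of the
#' detector samples, convolution with a discrete equiangular ramp
#' kernel (Ram-Lak, or its Shepp-Logan sinc-apodised variant), and
#' distance-weighted back-projection with linear interpolation in the
#' detector coordinate.
#'
#' @param sino Sinogram matrix, `n_detectors` x `n_views` (line
#'   integrals).
#' @param geom A [scan_geometry()].
#' @param filter `"ram-lak"` (default) or `"shepp-logan"`.
#' @return Reconstructed attenuation image (1/cm), `grid_size` square.
#' @export
fbp_reconstruct <- function(sino, geom, filter = "ram-lak") {
  stopifnot(inherits(geom, "scan_geometry"))
  filter <- match_filter(filter)
  if (!all(dim(sino) == c(geom$n_detectors, geom$n_views)))
    stop("sinogram dimensions do not match geometry")
  n_det <- geom$n_detectors
  sid_cm <- geom$source_to_iso / 10
  # cosine pre-weighting: q = p * D * cos(gamma)
  q <- sino * (sid_cm * cos(geom$gammas))
  # filter along the detector coordinate via FFT, zero-padded
  n_pad <- 2^ceiling(log2(2 * n_det))
  H <- filter_response(n_det, geom$dgamma, filter, n_pad)
  qpad <- matrix(0, n_pad, geom$n_views)
  qpad[seq_len(n_det), ] <- q
  qf <- Re(stats::mvfft(stats::mvfft(qpad) * H, inverse = TRUE)) / n_pad
  qf <- qf[seq_len(n_det), , drop = FALSE] * geom$dgamma
  # distance-weighted backprojection
  n <- geom$grid_size
  h_cm <- geom$pixel_spacing / 10
  cc <- (seq_len(n) - (n + 1) / 2) * h_cm
  px <- rep(cc, times = n)
  py <- rep(cc, each = n)
  dbeta <- (geom$angular_range * pi / 180) / geom$n_views
  img <- fan_backproject_cpp(qf, geom$betas, px, py, sid_cm,
                             geom$dgamma, dbeta)
  img <- matrix(img, n, n)
  # standard reconstruction-circle convention: pixels outside the
  # inscribed field-of-view circle are not covered by every fan and
  # are set to zero attenuation (air)
  img[!fov_mask(geom)] <- 0
  img
}

#' Filtered back-projection of a dynamic sinogram series
#'
#' Per-frame [fbp_reconstruct()] followed by conversion from
#' attenuation to CT numbers.
#'
#' @param sino_series 3-D array (detector, view, frame).
#' @param geom A [scan_geometry()].
#' @param filter `"ram-lak"` or `"shepp-logan"`.
#' @param dt Frame spacing in s carried to the output series.
#' @return A [dynamic_series()] in HU.
#' @export
fbp_series <- function(sino_series, geom, filter = "ram-lak", dt = 1.0) {
  stopifnot(length(dim(sino_series)) == 3L)
  nt <- dim(sino_series)[3]
  n <- geom$grid_size
  out <- array(0, dim = c(n, n, nt))
  for (f in seq_len(nt))
    out[, , f] <- mu_to_hu(fbp_reconstruct(sino_series[, , f], geom,
                                           filter))
  dynamic_series(out, dt = dt)
}
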