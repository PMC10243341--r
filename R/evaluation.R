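# Quantitative evaluation: PSNR, frame-averaged SSIM, linear
# regression of perfusion maps against the noise-free reference, ROI
# statistics, and the regularization-parameter sweep driver.

#' Peak signal-to-noise ratio of a dynamic series
#'
#' `PSNR = -10 log10( MSE / max(ref)^2 )` over the whole series, with
#' MSE the mean squared difference. Identical inputs return `Inf`.
#'
#' @param series,ref_series [dynamic_series()] objects or 3-D arrays of
#'   identical dimension.
#' @return PSNR in dB.
#' @export
psnr <- function(series, ref_series) {
  x <- if (inherits(series, "dynamic_series")) series$data else series
  r <- if (inherits(ref_series, "dynamic_series")) ref_series$data
       else ref_series
  if (!all(dim(x) == dim(r))) stop("dimension mismatch")
  if (max(abs(r)) == 0) stop("reference is identically zero")
  mse <- mean((x - r)^2)
  if (mse == 0) return(Inf)
  -10 * log10(mse / max(r)^2)
}

# 2-D Gaussian-weighted local moments via separable filtering with a
# truncated kernel (replicate-free: valid region only, like the
# reference sliding-window definition restricted to fully interior
# windows)
gauss_kernel <- function(size = 11L, sigma = 1.5) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h)^2) / (2 * sigma^2))
  g / sum(g)
}

filter2_valid <- function(img, k) {
  n <- length(k)
  nr <- nrow(img); nc <- ncol(img)
  # separable correlation, valid region
  tmp <- matrix(0, nr - n + 1, nc)
  for (i in seq_len(n))
    tmp <- tmp + k[i] * img[i:(nr - n + i), , drop = FALSE]
  out <- matrix(0, nr - n + 1, nc - n + 1)
  for (j in seq_len(n))
    out <- out + k[j] * tmp[, j:(nc - n + j), drop = FALSE]
  out
}

ssim_frame <- function(x, r, window = 11L, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03, L = NULL) {
  if (is.null(L)) L <- diff(range(r))
  if (L <= 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  k <- gauss_kernel(window, sigma)
  mx <- filter2_valid(x, k); mr <- filter2_valid(r, k)
  sxx <- filter2_valid(x * x, k) - mx^2
  srr <- filter2_valid(r * r, k) - mr^2
  sxr <- filter2_valid(x * r, k) - mx * mr
  num <- (2 * mx * mr + C1) * (2 * sxr + C2)
  den <- (mx^2 + mr^2 + C1) * (sxx + srr + C2)
  mean(num / den)
}

#' Mean structural similarity of a dynamic series
#'
#' Per-frame mean local SSIM (Gaussian 11 x 11 window, sigma 1.5,
#' K1 = 0.01, K2 = 0.03 — the standard defaults), averaged over all
#' frames. The dynamic range is taken per frame from the reference
#' (max - min). Local statistics are computed on fully interior
#' windows.
#'
#' @param series,ref_series [dynamic_series()] objects or 3-D arrays.
#' @param window Window size in pixels (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim_mean <- function(series, ref_series, window = 11L, sigma = 1.5) {
  x <- if (inherits(series, "dynamic_series")) series$data else series
  r <- if (inherits(ref_series, "dynamic_series")) ref_series$data
       else ref_series
  if (!all(dim(x) == dim(r))) stop("dimension mismatch")
  nt <- dim(x)[3]
  mean(vapply(seq_len(nt), function(f)
    ssim_frame(x[, , f], r[, , f], window = window, sigma = sigma), 0))
}

#' Regress a perfusion map against the reference map
#'
#' Ordinary least squares of the method values (y) on the reference
#' values (x) over the masked pixels, with the Pearson correlation
#' coefficient.
#'
#' @param map,ref_map Numeric matrices.
#' @param mask Logical matrix selecting pixels (e.g. perfused brain).
#' @return Object of class `regression_result`: `cc`, `slope`,
#'   `intercept`, `n_pixels`.
#' @export
regress_maps <- function(map, ref_map, mask) {
  stopifnot(all(dim(map) == dim(ref_map)), all(dim(map) == dim(mask)))
  xv <- ref_map[mask]; yv <- map[mask]
  if (length(xv) < 3) stop("need at least 3 masked pixels")
  if (stats::sd(xv) == 0) stop("zero variance in the reference map")
  fit <- stats::lm(yv ~ xv)
  structure(list(cc = stats::cor(xv, yv),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n_pixels = length(xv)), class = "regression_result")
}

#' ROI mean and standard deviation of perfusion maps
#'
#' Arithmetic mean and population standard deviation of CBF, CBV and
#' MTT within each named ROI.
#'
#' @param maps A `perfusion_maps` object (see [compute_maps()]).
#' @param rois Named list of logical ROI masks.
#' @return Tibble with columns roi, parameter, mean, sd, n_pixels.
#' @export
roi_stats <- function(maps, rois) {
  stopifnot(inherits(maps, "perfusion_maps"), length(rois) > 0)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  rows <- list()
  for (nm in names(rois)) {
    sel <- rois[[nm]]
    if (!any(sel)) stop("empty ROI: ", nm)
    for (par in c("cbf", "cbv", "mtt")) {
      v <- maps[[par]][sel]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = nm, parameter = par, mean = mean(v), sd = pop_sd(v),
        n_pixels = length(v))
    }
  }
  do.call(rbind, rows)
}

#' Sweep reconstruction methods over regularization parameter values
#'
#' For each (method, alpha) pair: reconstruct the noisy sinogram
#' series, score PSNR and mean SSIM against the reference series, and
#' optionally generate perfusion maps and emit regression and ROI
#' rows. Results are returned as a tidy table with one row per metric.
#'
#' @param sino_series Noisy sinogram array (detector, view, frame).
#' @param geom A [scan_geometry()].
#' @param ref_series Reference [dynamic_series()] (HU), typically the
#'   Ram-Lak FBP of the noise-free sinogram.
#' @param methods Character vector of methods (subset of tv, tgv, ltv,
#'   ltgv).
#' @param alphas Numeric vector of regularization weights (used as
#'   alpha for TV/LTV and alpha1 for TGV/LTGV, with alpha0 = 2 alpha1).
#' @param config_fn Function `(method, alpha) -> regularizer_config`,
#'   overriding the default construction (e.g. to cap `n_max`).
#' @param perfusion Optional list enabling perfusion metrics:
#'   `aif_roi` (logical mask), `brain_mask`, `baseline_frames`,
#'   `ref_maps` (a `perfusion_maps` object for regression), `rois`
#'   (named masks for [roi_stats()]), `threshold_frac`.
#' @param dt Frame spacing in s.
#' @return Tibble with columns method, alpha, metric, roi, value.
#' @export
parameter_sweep <- function(sino_series, geom, ref_series,
                            methods = c("tv", "tgv", "ltv", "ltgv"),
                            alphas = c(5e-4, 1e-3, 2.5e-3, 5e-3, 1e-2),
                            config_fn = NULL, perfusion = NULL,
                            dt = 1.0) {
  rows <- list()
  emit <- function(method, alpha, metric, value, roi = NA_character_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      method = method, alpha = alpha, metric = metric, roi = roi,
      value = value)
  }
  for (m in methods) {
    for (a in alphas) {
      cfg <- if (is.null(config_fn)) regularizer_config(m, alpha = a)
             else config_fn(m, a)
      res <- reconstruct(sino_series, geom, cfg, dt = dt)
      emit(m, a, "psnr", psnr(res$series, ref_series))
      emit(m, a, "ssim", ssim_mean(res$series, ref_series))
      emit(m, a, "n_iters", res$report$n_iters)
      if (!is.null(perfusion)) {
        pf <- perfusion
        ce <- contrast_enhancement(res$series, pf$baseline_frames)
        aif <- extract_aif(ce, pf$aif_roi)
        thr <- if (is.null(pf$threshold_frac)) 0.10 else pf$threshold_frac
        maps <- compute_maps(ce, aif, pf$brain_mask,
                             threshold_frac = thr)
        if (!is.null(pf$ref_maps)) {
          msk <- pf$brain_mask & pf$ref_maps$perfused
          for (par in c("cbf", "cbv", "mtt")) {
            rr <- regress_maps(maps[[par]], pf$ref_maps[[par]], msk)
            emit(m, a, paste0(par, "_cc"), rr$cc)
            emit(m, a, paste0(par, "_slope"), rr$slope)
            emit(m, a, paste0(par, "_intercept"), rr$intercept)
          }
        }
        if (!is.null(pf$rois)) {
          st <- roi_stats(maps, pf$rois)
          for (k in seq_len(nrow(st))) {
            emit(m, a, paste0(st$parameter[k], "_mean"), st$mean[k],
                 roi = st$roi[k])
            emit(m, a, paste0(st$parameter[k], "_sd"), st$sd[k],
                 roi = st$roi[k])
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
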