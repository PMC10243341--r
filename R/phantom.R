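# Synthetic dynamic brain-perfusion phantom: label geometry, tissue
# time-enhancement curves from the indicator-dilution model, and the
# HU <-> attenuation conversion.

MU_WATER <- 0.239  # 1/cm at an effective energy of 46 keV (80 kVp)

# hematocrit correction and brain-tissue density used throughout
#' Physiological constants for perfusion quantification
#'
#' @return List with `rho` (brain tissue density, 1.04 g/mL) and `kH`
#'   (large-to-small-vessel hematocrit correction factor, 0.73).
#' @export
perfusion_constants <- function() list(rho = 1.04, kH = 0.73)

#' Specify a dynamic brain-perfusion phantom
#'
#' The phantom is a single axial slice with concentric skull, a CSF
#' ventricle pair, a cortical gray-matter band around deep white
#' matter, a vessel disc inside the arterial-input ROI, and optionally
#' a penumbra + ischemic-core lesion. Each tissue carries a baseline CT
#' number and ground-truth perfusion values from which dynamic
#' enhancement is synthesised.
#'
#' @param grid_size Pixels per side (default 256).
#' @param pixel_spacing Pixel spacing in mm (default 1).
#' @param n_frames Number of temporal frames (default 50).
#' @param dt Sampling interval in s (default 1); frame i is at
#'   t = (i-1)*dt.
#' @param tissue_table Data frame with columns `tissue`, `baseline_hu`,
#'   `cbf` (mL/100 g/min) and `cbv` (mL/100 g); non-perfused tissues
#'   have cbf = cbv = 0. Defaults: gray matter 60/4, white matter 25/2,
#'   blood vessel treated as an arterial sample.
#' @param lesion `NULL` for no lesion, or a list with `centre` (fraction
#'   of half-grid, x right / y up), `r_penumbra`, `r_core` (fractions of
#'   half-grid), and scale factors `cbf_penumbra`, `cbv_penumbra`,
#'   `cbf_core`, `cbv_core` applied to the white-matter values.
#' @param aif_params Gamma-variate arterial input: list with `amplitude`
#'   (peak enhancement, HU), `delay` (arrival time, s; default 9 so the
#'   first 8 one-second frames are pre-contrast baseline), `shape`,
#'   `scale` (s).
#' @param seed Integer seed (geometry is deterministic; kept for
#'   reproducibility bookkeeping of derived runs).
#' @return Object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_size = 64, n_frames = 40)
#' @export
phantom_spec <- function(grid_size = 256L, pixel_spacing = 1.0,
                         n_frames = 50L, dt = 1.0,
                         tissue_table = default_tissue_table(),
                         lesion = NULL,
                         aif_params = list(amplitude = 300, delay = 9,
                                           shape = 3, scale = 1.2),
                         seed = 1L) {
  stopifnot(grid_size >= 32L, n_frames >= 2L, dt > 0)
  need <- c("tissue", "baseline_hu", "cbf", "cbv")
  if (!all(need %in% names(tissue_table)))
    stop("tissue_table must have columns tissue, baseline_hu, cbf, cbv")
  perf <- tissue_table$cbf > 0 | tissue_table$cbv > 0
  if (any(tissue_table$cbf[perf] <= 0) || any(tissue_table$cbv[perf] <= 0))
    stop("perfused tissues need cbf > 0 and cbv > 0")
  if (!is.null(lesion)) {
    defaults <- list(centre = c(0.45, 0.15), r_penumbra = 0.28,
                     r_core = 0.13, cbf_penumbra = 0.4,
                     cbv_penumbra = 0.9, cbf_core = 0.15, cbv_core = 0.4)
    lesion <- utils::modifyList(defaults, lesion)
    if (lesion$r_core >= lesion$r_penumbra)
      stop("core must lie strictly inside the penumbra")
  }
  structure(list(grid_size = as.integer(grid_size),
                 pixel_spacing = pixel_spacing,
                 n_frames = as.integer(n_frames), dt = dt,
                 tissue_table = tissue_table, lesion = lesion,
                 aif_params = aif_params, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default per-tissue baseline CT numbers and perfusion values
#'
#' Gray matter 60 mL/100 g/min and 4 mL/100 g, white matter 25 and 2
#' (standard adult physiology); CSF and skull are non-perfused; the
#' vessel label carries the arterial input directly.
#'
#' @return Data frame with columns tissue, baseline_hu, cbf, cbv.
#' @export
default_tissue_table <- function() {
  data.frame(
    tissue = c("air", "skull", "csf", "gm", "wm", "vessel"),
    baseline_hu = c(-1000, 1000, 8, 40, 30, 45),
    cbf = c(0, 0, 0, 60, 25, 0),
    cbv = c(0, 0, 0, 4, 2, 0),
    stringsAsFactors = FALSE)
}

# label codes
LBL <- c(air = 0L, skull = 1L, csf = 2L, gm = 3L, wm = 4L, vessel = 5L,
         penumbra = 6L, core = 7L)

#' Build the phantom label map and named ROIs
#'
#' Deterministic given the spec: concentric skull annulus, brain disc
#' with a cortical gray-matter band and deep white matter, two CSF
#' ventricles, a vessel disc inside the arterial-input ROI, and (if
#' requested) disjoint penumbra/core discs inside the white matter.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `label_map`: integer `labels` matrix, logical
#'   `brain_mask`, and `rois` (logical masks: `ica`, `normal`, and with
#'   a lesion also `penumbra` and `core`).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  half <- n / 2
  cc <- (seq_len(n) - (n + 1) / 2) / half       # coords in [-1, 1]
  x <- matrix(cc, n, n)
  y <- matrix(cc, n, n, byrow = TRUE)
  r <- sqrt(x^2 + y^2)

  lab <- matrix(LBL["air"], n, n)
  lab[r < 0.92] <- LBL["skull"]
  brain <- r < 0.80
  lab[brain] <- LBL["gm"]
  lab[brain & r < 0.55] <- LBL["wm"]
  # paired CSF ventricles near the midline
  vent <- (sqrt(((x - 0.10) / 0.16)^2 + (y / 0.28)^2) < 1) |
          (sqrt(((x + 0.10) / 0.16)^2 + (y / 0.28)^2) < 1)
  lab[brain & vent] <- LBL["csf"]

  # arterial-input ROI: square (~20/256 of the grid) low in the slice,
  # with a vessel disc at its centre
  roi_w <- max(6L, round(20 / 256 * n))
  ica_centre <- c(0, -0.62)
  ica <- square_roi(n, ica_centre, roi_w, half)
  if (!any(ica & brain)) stop("arterial ROI falls outside the brain")
  vessel <- sqrt((x - ica_centre[1])^2 + (y - ica_centre[2])^2) <
    max(2.5, 0.015 * n) / half
  lab[vessel & brain] <- LBL["vessel"]

  rois <- list(ica = ica)
  if (!is.null(spec$lesion)) {
    le <- spec$lesion
    d <- sqrt((x - le$centre[1])^2 + (y - le$centre[2])^2)
    pen <- d < le$r_penumbra & lab == LBL["wm"]
    core <- d < le$r_core & lab == LBL["wm"]
    if (!any(pen & !core)) stop("lesion region outside the grid or brain")
    lab[pen] <- LBL["penumbra"]
    lab[core] <- LBL["core"]
    rois$penumbra <- lab == LBL["penumbra"]
    rois$core <- lab == LBL["core"]
    # contralateral normal ROI (~18/256 of the grid), mirrored in x
    norm_w <- max(5L, round(18 / 256 * n))
    rois$normal <- square_roi(n, c(-le$centre[1], le$centre[2]),
                              norm_w, half)
  } else {
    norm_w <- max(5L, round(18 / 256 * n))
    rois$normal <- square_roi(n, c(-0.45, 0.15), norm_w, half)
  }
  structure(list(labels = lab, brain_mask = brain, rois = rois,
                 grid_size = n), class = "label_map")
}

square_roi <- function(n, centre_frac, width_px, half) {
  ci <- round(centre_frac * half + (n + 1) / 2)
  h <- floor(width_px / 2)
  m <- matrix(FALSE, n, n)
  xs <- max(1, ci[1] - h):min(n, ci[1] + h)
  ys <- max(1, ci[2] - h):min(n, ci[2] + h)
  m[xs, ys] <- TRUE
  m
}

#' Gamma-variate arterial input function
#'
#' `C(t) = amplitude * ((t - delay)/(shape*scale))^shape *
#' exp(shape - (t - delay)/scale)` for `t > delay`, zero before; the
#' peak value equals `amplitude` at `t = delay + shape*scale`.
#'
#' @param t Time points in s.
#' @param params List with `amplitude` (HU), `delay` (s), `shape`,
#'   `scale` (s).
#' @return Enhancement curve in HU.
#' @export
gamma_variate_aif <- function(t, params) {
  tp <- params$shape * params$scale
  u <- (t - params$delay)
  out <- ifelse(u > 0,
                params$amplitude * (u / tp)^params$shape *
                  exp(params$shape - u / params$scale),
                0)
  out
}

#' Tissue contrast-enhancement curve from the indicator-dilution model
#'
#' Convolves the arterial input with a mono-exponential residue
#' function: `C(t) = (rho/kH) * CBF * sum_j AIF(t_j) R(t - t_j) dt`,
#' with `MTT = 60 * CBV / CBF` seconds. The residue is sampled as the
#' discrete-time exponential `R(i dt) = (1 - dt/MTT)^i`, which keeps
#' `R(0) = 1` (so CBF is the initial residue height) and makes the
#' rectangle-rule residue area exactly MTT, so the area ratio of the
#' output to the input recovers CBV exactly at any sampling interval
#' (central volume principle); the continuous-time sampled exponential
#' would bias the area by about `dt / (2 MTT)` at coarse sampling.
#'
#' @param cbf Cerebral blood flow, mL/100 g/min (> 0).
#' @param cbv Cerebral blood volume, mL/100 g (> 0).
#' @param aif Arterial enhancement per frame (HU), nonnegative.
#' @param dt Frame spacing in s; must be smaller than MTT.
#' @return Tissue enhancement per frame (HU).
#' @export
tissue_ce_curve <- function(cbf, cbv, aif, dt) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(cbf > 0, cbv > 0, all(aif >= -1e-12))
  pc <- perfusion_constants()
  mtt <- 60 * cbv / cbf                  # s
  if (dt >= mtt)
    stop("sampling interval must be below the tissue MTT")
  cbf_gs <- cbf / 6000                   # mL/100g/min -> mL/g/s
  nt <- length(aif)
  resid <- (1 - dt / mtt)^(seq_len(nt) - 1)
  # causal discrete convolution, rectangle rule
  ce <- numeric(nt)
  for (i in seq_len(nt))
    ce[i] <- sum(aif[seq_len(i)] * resid[i:1]) * dt
  (pc$rho / pc$kH) * cbf_gs * ce
}

#' Render the dynamic HU series of a phantom
#'
#' Each pixel takes its tissue's baseline CT number plus the tissue
#' enhancement curve; vessel pixels carry the arterial input itself.
#' With the default arrival delay of 9 s the first 8 frames (dt = 1 s)
#' are pre-contrast baseline.
#'
#' @param labelmap A [build_phantom()] result.
#' @param spec The matching [phantom_spec()].
#' @return Object of class `dynamic_series` (see [dynamic_series()]).
#' @export
render_dynamic_hu <- function(labelmap, spec) {
  stopifnot(inherits(labelmap, "label_map"), inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  nt <- spec$n_frames
  tt <- (seq_len(nt) - 1) * spec$dt
  aif <- gamma_variate_aif(tt, spec$aif_params)
  tab <- phantom_truth_table(spec)
  data <- array(0, dim = c(n, n, nt))
  base_img <- matrix(0, n, n)
  for (k in seq_len(nrow(tab))) {
    sel <- labelmap$labels == tab$label[k]
    if (!any(sel)) next
    base_img[sel] <- tab$baseline_hu[k]
    if (tab$tissue[k] == "vessel") {
      curve <- aif
    } else if (tab$cbf[k] > 0) {
      curve <- tissue_ce_curve(tab$cbf[k], tab$cbv[k], aif, spec$dt)
    } else {
      curve <- numeric(nt)
    }
    for (f in seq_len(nt))
      data[, , f][sel] <- tab$baseline_hu[k] + curve[f]
  }
  dynamic_series(data, dt = spec$dt)
}

# resolved per-label table including lesion labels scaled from WM
phantom_truth_table <- function(spec) {
  tab <- spec$tissue_table
  tab$label <- LBL[tab$tissue]
  if (!is.null(spec$lesion)) {
    wm <- tab[tab$tissue == "wm", ]
    le <- spec$lesion
    tab <- rbind(tab,
      data.frame(tissue = "penumbra", baseline_hu = wm$baseline_hu,
                 cbf = wm$cbf * le$cbf_penumbra,
                 cbv = wm$cbv * le$cbv_penumbra, label = LBL["penumbra"]),
      data.frame(tissue = "core", baseline_hu = wm$baseline_hu,
                 cbf = wm$cbf * le$cbf_core,
                 cbv = wm$cbv * le$cbv_core, label = LBL["core"]))
  }
  tab
}

#' Ground-truth perfusion maps of a phantom
#'
#' @param labelmap A [build_phantom()] result.
#' @param spec The matching [phantom_spec()].
#' @return A `perfusion_maps` object with the analytic CBF/CBV/MTT of
#'   every perfused pixel.
#' @export
phantom_truth_maps <- function(labelmap, spec) {
  n <- spec$grid_size
  cbf <- matrix(0, n, n); cbv <- matrix(0, n, n)
  tab <- phantom_truth_table(spec)
  for (k in seq_len(nrow(tab))) {
    sel <- labelmap$labels == tab$label[k]
    cbf[sel] <- tab$cbf[k]
    cbv[sel] <- tab$cbv[k]
  }
  mtt <- matrix(0, n, n)
  perf <- cbf > 0
  mtt[perf] <- 60 * cbv[perf] / cbf[perf]
  structure(list(cbf = cbf, cbv = cbv, mtt = mtt,
                 brain_mask = labelmap$brain_mask, perfused = perf),
            class = "perfusion_maps")
}

#' Construct a dynamic image series
#'
#' @param data 3-D array (x, y, frame), values in HU (or 1/cm when used
#'   internally in attenuation units).
#' @param dt Frame spacing in s.
#' @return Object of class `dynamic_series` with `data`, `dt`,
#'   `frame_times` (frame i at t = (i-1)*dt).
#' @export
dynamic_series <- function(data, dt) {
  stopifnot(length(dim(data)) == 3L, dt > 0)
  structure(list(data = data, dt = dt,
                 frame_times = (seq_len(dim(data)[3]) - 1) * dt),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("dynamic series: %d x %d px, %d frames at dt = %g s\n",
              d[1], d[2], d[3], x$dt))
  invisible(x)
}

#' Convert CT numbers to linear attenuation coefficients
#'
#' Affine calibration with air (-1000 HU) at 0 and water (0 HU) at
#' 0.239 1/cm; values below 0 are clipped.
#'
#' @param hu CT numbers (any shape).
#' @return Attenuation in 1/cm, same shape.
#' @export
hu_to_mu <- function(hu) {
  pmax(MU_WATER * (hu / 1000 + 1), 0)
}

#' Convert linear attenuation coefficients to CT numbers
#'
#' Inverse of [hu_to_mu()] for HU >= -1000.
#'
#' @param mu Attenuation in 1/cm.
#' @return CT numbers, same shape.
#' @export
mu_to_hu <- function(mu) {
  1000 * (mu / MU_WATER - 1)
}
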