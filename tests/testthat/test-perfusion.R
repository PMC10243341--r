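aif_default <- function(nt = 50, dt = 1)
  gamma_variate_aif((seq_len(nt) - 1) * dt,
                    list(amplitude = 300, delay = 9, shape = 3,
                         scale = 1.2))

test_that("contrast enhancement centres the baseline window", {
  st <- small_study(grid = 48, frames = 24)
  ce <- contrast_enhancement(st$series, 1:8)
  # baseline-window mean of CE is exactly zero
  expect_equal(max(abs(apply(ce$data[, , 1:8], c(1, 2), mean))), 0)
  # constant-in-time pixels (skull) have zero CE throughout
  sk <- which(st$lm$labels == 1L)[1]
  flat <- matrix(ce$data, ncol = 24)
  expect_equal(max(abs(flat[sk, ])), 0)
  expect_error(contrast_enhancement(st$series, integer(0)), "empty")
  expect_error(contrast_enhancement(st$series, 20:30), "outside")
})

test_that("fuzzy c-means AIF extraction separates the arterial curve", {
  # two-population ROI: a tall gamma-variate vs flat background
  nt <- 30
  tall <- gamma_variate_aif(0:(nt - 1),
                            list(amplitude = 200, delay = 5, shape = 3,
                                 scale = 1.5))
  dat <- array(0, c(10, 10, nt))
  set.seed(12)
  for (i in 1:10) for (j in 1:10) {
    dat[i, j, ] <- if (i <= 3) tall + rnorm(nt, sd = 2)
                   else rnorm(nt, sd = 2)
  }
  ser <- dynamic_series(dat, dt = 1)
  roi <- matrix(TRUE, 10, 10)
  aif <- extract_aif(ser, roi)
  expect_s3_class(aif, "aif_curve")
  expect_lt(max(abs(aif$values - tall)) / max(tall), 0.05)
  # determinism under the fixed seed
  expect_identical(extract_aif(ser, roi)$values, aif$values)
  # identical curves: returned unchanged regardless of clustering
  same <- dynamic_series(array(rep(tall, each = 100), c(10, 10, nt)), 1)
  expect_equal(extract_aif(same, roi)$values, tall)
  expect_error(extract_aif(ser, matrix(FALSE, 10, 10)), "smaller")
})

test_that("block-circulant deconvolution recovers CBF and is linear", {
  aif <- aif_default()
  ce <- tissue_ce_curve(60, 4, aif, dt = 1)
  r <- bsvd_deconvolve(ce, aif, threshold_frac = 1e-6, dt = 1)
  expect_equal(r$cbf, 60, tolerance = 0.05)
  # zero curve gives zero flow
  r0 <- bsvd_deconvolve(numeric(50), aif, dt = 1)
  expect_equal(r0$cbf, 0)
  expect_equal(max(abs(r0$k_curve)), 0)
  # linearity: doubling the curve doubles CBF
  r2 <- bsvd_deconvolve(2 * ce, aif, threshold_frac = 1e-6, dt = 1)
  expect_equal(r2$cbf, 2 * r$cbf, tolerance = 1e-6)
  expect_error(bsvd_deconvolve(ce, numeric(50), dt = 1), "flat")
})

test_that("deconvolution is delay-insensitive (block-circulant)", {
  aif <- aif_default()
  ce <- tissue_ce_curve(60, 4, aif, dt = 1)
  shifted <- c(numeric(2), ce[1:48])
  c1 <- bsvd_deconvolve(ce, aif, threshold_frac = 0.1, dt = 1)$cbf
  c2 <- bsvd_deconvolve(shifted, aif, threshold_frac = 0.1, dt = 1)$cbf
  expect_lt(abs(c2 - c1) / c1, 0.10)
})

test_that("CBV follows the area-ratio formula", {
  aif <- aif_default()
  pc <- perfusion_constants()
  # identical curves: the blood-pixel limit 100 * kH / rho
  expect_equal(compute_cbv(aif, aif), 100 * pc$kH / pc$rho)
  ce <- tissue_ce_curve(60, 4, aif, dt = 1)
  expect_equal(compute_cbv(ce, aif), 4, tolerance = 0.02 * 4)
  expect_equal(compute_cbv(2 * ce, aif), 2 * compute_cbv(ce, aif))
  expect_error(compute_cbv(ce, numeric(50)), "zero arterial")
})

test_that("noise-free phantom maps recover the ground truth", {
  spec <- phantom_spec(grid_size = 48, n_frames = 50, dt = 1,
                       pixel_spacing = 256 / 48)
  lm <- build_phantom(spec)
  ser <- render_dynamic_hu(lm, spec)
  ce <- contrast_enhancement(ser, 1:8)
  aif <- extract_aif(ce, lm$rois$ica)
  maps <- compute_maps(ce, aif, lm$brain_mask, threshold_frac = 1e-6)
  truth <- phantom_truth_maps(lm, spec)
  for (lab in c(gm = 3L, wm = 4L)) {
    sel <- lm$labels == lab
    expect_lt(abs(mean(maps$cbv[sel]) - truth$cbv[sel][1]) /
                truth$cbv[sel][1], 0.02)
    expect_lt(abs(mean(maps$cbf[sel]) - truth$cbf[sel][1]) /
                truth$cbf[sel][1], 0.05)
  }
  # central volume identity is exact wherever perfused
  sel <- maps$perfused
  expect_equal(maps$mtt[sel], 60 * maps$cbv[sel] / maps$cbf[sel])
  # pixels outside the mask are zero in all maps
  expect_true(all(maps$cbf[!maps$brain_mask] == 0))
  expect_true(all(maps$mtt[!maps$brain_mask] == 0))
})

test_that("recovery of a continuous-time curve improves with finer sampling", {
  # continuous-time tissue curve from a fine-grid quadrature oracle,
  # sampled at the frame grid: the deconvolution's discretisation
  # error must shrink with dt
  dtf <- 0.01
  ttf <- seq(0, 50 - dtf, by = dtf)
  pc <- perfusion_constants()
  par <- list(amplitude = 300, delay = 9, shape = 3, scale = 1.2)
  aif_f <- gamma_variate_aif(ttf, par)
  mtt <- 60 * 4 / 60
  ce_f <- stats::convolve(aif_f, rev(exp(-ttf / mtt)),
                          type = "open")[seq_along(ttf)] *
    dtf * (pc$rho / pc$kH) * (60 / 6000)
  err_at <- function(dt) {
    idx <- seq(1, length(ttf), by = round(dt / dtf))
    aif <- gamma_variate_aif(ttf[idx], par)
    abs(bsvd_deconvolve(ce_f[idx], aif, threshold_frac = 1e-6,
                        dt = dt)$cbf - 60)
  }
  expect_lt(err_at(0.5), err_at(1.0))
})
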