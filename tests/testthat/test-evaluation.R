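test_that("PSNR follows the definition and its arithmetic", {
  ref <- array(100, c(10, 10, 2))
  x <- ref + 1                         # MSE = 1, max(ref) = 100
  expect_equal(psnr(x, ref), 40)
  expect_equal(psnr(ref, ref), Inf)
  set.seed(51)
  noise <- array(rnorm(200), c(10, 10, 2))
  p1 <- psnr(ref + noise, ref)
  p2 <- psnr(ref + 2 * noise, ref)
  expect_equal(p1 - p2, 20 * log10(2), tolerance = 1e-10)
  expect_error(psnr(array(0, c(5, 5, 1)), array(0, c(4, 4, 1))),
               "mismatch")
})

test_that("SSIM matches a brute-force sliding-window oracle", {
  set.seed(52)
  x <- matrix(runif(196, 0, 50), 14, 14)
  r <- x + matrix(rnorm(196, sd = 5), 14, 14)
  got <- ssim_mean(array(x, c(14, 14, 1)), array(r, c(14, 14, 1)))
  expect_equal(got, oracle_ssim(x, r), tolerance = 1e-6)
  # identical series score exactly 1
  expect_equal(ssim_mean(array(r, c(14, 14, 1)), array(r, c(14, 14, 1))),
               1)
  # sign flip: the luminance factor turns negative, so SSIM drops
  # strictly below the perfect score even though structure is shared
  rr <- matrix(10 + rnorm(196, sd = 0.5), 14, 14)
  flipped <- ssim_mean(array(-rr, c(14, 14, 1)), array(rr, c(14, 14, 1)))
  expect_lt(flipped, 1)
  expect_lt(flipped, ssim_mean(array(rr, c(14, 14, 1)),
                               array(rr, c(14, 14, 1))))
})

test_that("PSNR and SSIM are invariant under joint spatial permutation", {
  set.seed(53)
  x <- array(runif(14 * 14 * 2, 0, 10), c(14, 14, 2))
  r <- x + array(rnorm(14 * 14 * 2), c(14, 14, 2))
  # joint transpose of both inputs (a spatial permutation)
  xt <- aperm(x, c(2, 1, 3)); rt <- aperm(r, c(2, 1, 3))
  expect_equal(psnr(x, r), psnr(xt, rt))
  expect_equal(ssim_mean(x, r), ssim_mean(xt, rt), tolerance = 1e-12)
})

test_that("map regression matches the closed-form normal equations", {
  set.seed(54)
  ref <- matrix(runif(400, 10, 80), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  r1 <- regress_maps(ref, ref, mask)
  expect_equal(r1$cc, 1)
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0, tolerance = 1e-10)
  r2 <- regress_maps(2 * ref + 3, ref, mask)
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 3)
  expect_equal(r2$cc, 1)
  # closed-form oracle on noisy data
  y <- 1.5 * ref + matrix(rnorm(400, sd = 4), 20, 20)
  rr <- regress_maps(y, ref, mask)
  xv <- as.vector(ref); yv <- as.vector(y)
  slope_or <- (mean(xv * yv) - mean(xv) * mean(yv)) /
    (mean(xv^2) - mean(xv)^2)
  expect_equal(rr$slope, slope_or, tolerance = 1e-10)
  expect_equal(rr$intercept, mean(yv) - slope_or * mean(xv),
               tolerance = 1e-10)
  expect_error(regress_maps(y, ref * 0 + 1, mask), "variance")
})

test_that("ROI statistics use the population standard deviation", {
  maps <- structure(list(cbf = matrix(1:16, 4), cbv = matrix(2, 4, 4),
                         mtt = matrix(0, 4, 4),
                         brain_mask = matrix(TRUE, 4, 4),
                         perfused = matrix(TRUE, 4, 4)),
                    class = "perfusion_maps")
  roi2 <- matrix(FALSE, 4, 4); roi2[c(1, 3)] <- TRUE   # values 1 and 3
  st <- roi_stats(maps, list(pair = roi2))
  expect_equal(st$mean[st$parameter == "cbf"], 2)
  expect_equal(st$sd[st$parameter == "cbf"], 1)
  expect_equal(st$sd[st$parameter == "cbv"], 0)
  # streaming two-pass oracle on random data
  set.seed(55)
  maps$cbf <- matrix(rnorm(16, 50, 10), 4)
  roi <- matrix(c(TRUE, FALSE), 4, 4)
  st2 <- roi_stats(maps, list(r = roi))
  v <- maps$cbf[roi]
  expect_equal(st2$mean[st2$parameter == "cbf"], sum(v) / length(v))
  expect_equal(st2$sd[st2$parameter == "cbf"],
               sqrt(sum((v - mean(v))^2) / length(v)))
  expect_error(roi_stats(maps, list(none = matrix(FALSE, 4, 4))),
               "empty")
})

test_that("parameter_sweep emits tidy deterministic rows", {
  fx_spec <- phantom_spec(grid_size = 32, n_frames = 10,
                          pixel_spacing = 8)
  lm <- build_phantom(fx_spec)
  ser <- render_dynamic_hu(lm, fx_spec)
  geom <- scan_geometry(n_views = 60, n_detectors = 48, grid_size = 32,
                        pixel_spacing = 8)
  sino0 <- lowdose_from_series(ser, geom)
  sino <- add_counting_noise(sino0, noise_model(seed = 2))
  ref <- fbp_series(sino0, geom)
  cfg_fn <- function(m, a) regularizer_config(m, alpha = a, n_max = 15)
  tb <- parameter_sweep(sino, geom, ref, methods = "tv",
                        alphas = c(1e-3, 5e-3), config_fn = cfg_fn)
  expect_s3_class(tb, "tbl_df")
  expect_setequal(names(tb), c("method", "alpha", "metric", "roi",
                               "value"))
  expect_equal(sum(tb$metric == "psnr"), 2)
  # identical data: rows differ only through alpha-dependent values
  tb2 <- parameter_sweep(sino, geom, ref, methods = "tv",
                         alphas = c(1e-3, 5e-3), config_fn = cfg_fn)
  expect_identical(tb$value, tb2$value)
})
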