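test_that("siddon_trace reproduces analytic intersection lengths", {
  # axis-aligned ray through one full row of a 10 x 10 grid, 1 mm px
  tr <- siddon_trace(c(-100, 0.5), c(100, 0.5), grid_size = 10)
  expect_equal(nrow(tr), 10)
  expect_equal(tr$length_cm, rep(0.1, 10))
  # ray missing the grid
  expect_equal(nrow(siddon_trace(c(-100, 200), c(100, 200), 10)), 0)
  # 45-degree diagonal through a single 1 mm pixel grid
  tr <- siddon_trace(c(-10, -10), c(10, 10), grid_size = 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$length_cm, sqrt(2) * 0.1)
  expect_error(siddon_trace(c(1, 1), c(1, 1), 10), "degenerate")
})

test_that("siddon_trace length sums equal the grid chord length", {
  set.seed(11)
  for (k in 1:50) {
    ang <- runif(1, 0, 2 * pi); off <- runif(1, -4.5, 4.5)
    u <- c(cos(ang), sin(ang)); v <- c(-u[2], u[1])
    p0 <- u * 60 + v * off; p1 <- -u * 60 + v * off
    tr <- siddon_trace(p0, p1, grid_size = 10)
    d <- p1 - p0; tmin <- 0; tmax <- 1
    for (ax in 1:2) {
      a <- (-5 - p0[ax]) / d[ax]; b <- (5 - p0[ax]) / d[ax]
      tmin <- max(tmin, min(a, b)); tmax <- min(tmax, max(a, b))
    }
    chord <- max(0, tmax - tmin) * sqrt(sum(d^2)) / 10
    expect_equal(sum(tr$length_cm), chord, tolerance = 1e-9)
  }
})

test_that("forward projection matches the dense oracle system matrix", {
  geom <- scan_geometry(n_views = 12, n_detectors = 16, grid_size = 16,
                        pixel_spacing = 2)
  Aor <- oracle_system_matrix(geom)
  A <- system_matrix(geom)
  expect_lt(max(abs(as.matrix(A) - Aor)), 1e-9)
  set.seed(4)
  mu <- matrix(runif(256, 0, 0.3), 16, 16)
  s1 <- forward_project(mu, geom)
  s2 <- matrix(Aor %*% as.vector(mu), geom$n_detectors, geom$n_views)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("forward projection is linear and handles the uniform disc", {
  geom <- scan_geometry(n_views = 36, n_detectors = 64, grid_size = 64)
  expect_equal(forward_project(matrix(0, 64, 64), geom),
               matrix(0, geom$n_detectors, geom$n_views))
  cc <- seq_len(64) - 32.5
  r <- sqrt(outer(cc^2, cc^2, "+"))
  mu <- 0.2 * (r < 24)
  s <- forward_project(mu, geom)
  # homogeneity
  expect_equal(forward_project(3 * mu, geom), 3 * s, tolerance = 1e-12)
  # central ray through a 48 mm diameter disc: 0.2 * 4.8 cm
  centre <- (geom$n_detectors + 1) / 2
  mid <- mean(s[floor(centre):ceiling(centre), 1])
  expect_equal(mid, 0.2 * 4.8, tolerance = 0.02)
  expect_error(forward_project(mu * NA, geom), "finite")
})

test_that("back projection is the exact adjoint of forward projection", {
  geom <- scan_geometry(n_views = 20, n_detectors = 24, grid_size = 24,
                        pixel_spacing = 2)
  expect_equal(back_project(matrix(0, 24, 20), geom), matrix(0, 24, 24))
  set.seed(5)
  for (k in 1:5) {
    x <- matrix(rnorm(24 * 24), 24, 24)
    y <- matrix(rnorm(24 * 20), 24, 20)
    lhs <- sum(forward_project(x, geom) * y)
    rhs <- sum(x * back_project(y, geom))
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
  # a single sinogram bin back-projects onto exactly that ray's pixels
  y <- matrix(0, 24, 20); y[7, 3] <- 1
  img <- back_project(y, geom)
  ep <- perfct:::ray_endpoints(geom)
  tr <- siddon_trace(c(ep$sx[3], ep$sy[3]), c(ep$det_x[7, 3], ep$det_y[7, 3]),
                     24, 2)
  expect_equal(sort(which(img != 0)), sort(tr$pixel))
})

test_that("counting noise is unbiased, seeded, and clamps counts", {
  nm <- noise_model(I0 = 2.5e5, seed = 9)
  # Monte-Carlo oracle: mean of the noisy line integral at P = 2
  P <- matrix(2, 200, 500)
  Phat <- add_counting_noise(P, nm)
  se <- stats::sd(Phat) / sqrt(length(Phat))
  expect_lt(abs(mean(Phat) - 2), 3 * se)
  # reproducibility
  expect_identical(add_counting_noise(P, nm), Phat)
  # different frames get different draws
  expect_false(identical(add_counting_noise(P, nm, frame = 2), Phat))
  # clamping: enormous attenuation drives counts to the floor, so the
  # output equals log(I0 / clamp_floor)
  nm2 <- noise_model(I0 = 10, readout_variance = 0, seed = 1)
  big <- add_counting_noise(matrix(50, 10, 10), nm2)
  expect_true(all(big == log(10)))
  expect_error(noise_model(I0 = -1), "positive")
})

test_that("noise variance of the log sinogram scales like 1/I0", {
  # linearised Poisson: var(log I) ~ 1/I = e^P / I0
  P <- matrix(1, 100, 400)
  v1 <- stats::var(as.vector(add_counting_noise(
    P, noise_model(I0 = 1e5, readout_variance = 0, seed = 3))))
  v2 <- stats::var(as.vector(add_counting_noise(
    P, noise_model(I0 = 4e5, readout_variance = 0, seed = 3))))
  expect_equal(v1 / v2, 4, tolerance = 0.3)
})
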