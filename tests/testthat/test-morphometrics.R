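test_that("binarize separates two-level images, handles polarity and noise", {
  fx <- make_sinusoidal_suture(fixture_spec(ny = 120, nx = 96, width = 5,
                                            amplitude = 8, wavelength = 40))
  m <- binarize(fx$image)
  expect_identical(m, fx$truth$mask)
  expect_identical(binarize(fx$image, darker_is_suture = FALSE), !m)

  fxn <- make_sinusoidal_suture(fixture_spec(ny = 120, nx = 96, width = 5,
                                             amplitude = 8, wavelength = 40,
                                             noise_sd = 10, seed = 5))
  mn <- binarize(fxn$image)
  expect_gte(mean(mn == fxn$truth$mask), 0.99)

  expect_error(binarize(matrix(7, 10, 10)), "manual")
  expect_silent(binarize(matrix(7, 10, 10), method = "manual", threshold = 10))
})

test_that("profile_plot: constant images, dip position and width at half depth", {
  img <- specimen_image(matrix(80, 40, 60), 0.1)
  expect_true(all(profile_plot(img)$intensity == 80))

  fx <- make_sinusoidal_suture(fixture_spec(ny = 160, nx = 100, center = 40,
                                            width = 9, amplitude = 0))
  pr <- profile_plot(fx$image)
  dip <- which(pr$intensity < (20 + 200) / 2)
  expect_equal(mean(dip), 40, tolerance = 0.51)
  expect_lt(abs(length(dip) - 9) * fx$image$pixel_size, 2 * fx$image$pixel_size + 1e-9)

  expect_error(profile_plot(img, band = integer(0)), "band")
})

test_that("suture_width counts transect pixels with physical calibration", {
  mask <- matrix(FALSE, 30, 40); mask[, 17:23] <- TRUE
  w <- suture_width(mask, pixel_size = 0.05)
  expect_equal(w$width_per_transect, rep(0.35, 30))
  expect_equal(w$width_mean, 0.35)
  expect_equal(w$width_max, 0.35)
  expect_equal(w$n_transects, 30)

  # sinusoidal band of fixed along-x width w: every transect still w
  fx <- make_sinusoidal_suture(fixture_spec(ny = 128, nx = 96, width = 5,
                                            amplitude = 10, wavelength = 64))
  ws <- suture_width(fx$truth$mask, 1)
  expect_gte(ws$width_mean, 5 - 1)

  # transpose invariance when suture_axis is updated
  wt <- suture_width(t(fx$truth$mask), 1, suture_axis = "x")
  expect_identical(ws, wt)
  expect_error(suture_width(matrix(FALSE, 4, 4)), "empty")
})

test_that("centerline: straight, symmetric-sinusoid, and tilted bands", {
  mask <- matrix(FALSE, 50, 128); mask[, 62:66] <- TRUE
  cl <- centerline(mask)
  expect_true(all(abs(cl$midpoint - 64) <= 0.5))

  fx <- make_sinusoidal_suture(fixture_spec(ny = 128, nx = 96, center = 48,
                                            width = 5, amplitude = 10,
                                            wavelength = 32))
  cls <- centerline(fx$truth$mask)
  expect_lt(abs(cls$fit["intercept"] + cls$fit["slope"] * 64 - 48), 0.5)

  drift <- 0.2
  y <- 1:100
  tilted <- abs(outer(rep(1, 100), 1:80) - (20 + drift * y)) <= 2.5
  clt <- centerline(tilted)
  expect_lt(abs(clt$fit["slope"] - drift) / drift, 0.05)
})

test_that("max_amplitude measures deviation from the fitted centerline", {
  ps <- 0.05
  mask <- matrix(FALSE, 50, 128); mask[, 62:68] <- TRUE   # straight, w = 7
  expect_lt(abs(max_amplitude(mask, ps) - ps * 7 / 2), ps * 1)

  mk <- function(A) make_sinusoidal_suture(
    fixture_spec(ny = 128, nx = 128, width = 5, amplitude = A,
                 wavelength = 64, pixel_size = ps))$truth$mask
  a10 <- max_amplitude(mk(10), ps)
  expect_lt(abs(a10 - ps * (10 + 5 / 2)), ps * 1)
  a20 <- max_amplitude(mk(20), ps)
  expect_lt(abs((a20 - a10) - ps * 10), ps * 1.5)

  # centerline amplitude excludes the half-width offset
  expect_lt(centerline_amplitude(mask, ps), ps * 0.6)
  expect_gt(centerline_amplitude(mk(10), ps), ps * 8)
})

test_that("skeletonization: straight-band count, arc-length recovery, scaling", {
  mask <- matrix(FALSE, 60, 40); mask[, 19:23] <- TRUE
  sk <- skeleton_length(mask, 1)
  expect_lte(abs(sk$skeleton_pixel_count - 60), 2)
  expect_true(all(colSums(sk$skeleton)[c(1:17, 25:40)] == 0))

  fx <- make_sinusoidal_suture(fixture_spec(ny = 200, nx = 128, width = 5,
                                            amplitude = 10, wavelength = 64))
  skl <- skeleton_length(fx$truth$mask, 1)
  expect_lt(abs(skl$skeleton_length - fx$truth$arc_length_px) /
              fx$truth$arc_length_px, 0.10)

  # doubling raster resolution ~doubles the skeleton (physical length is
  # calibration-invariant); the raw pixel count is algorithm-noisier
  fx2 <- make_sinusoidal_suture(fixture_spec(ny = 400, nx = 256, width = 10,
                                             amplitude = 20, wavelength = 128))
  sk2 <- skeleton_length(fx2$truth$mask, 1)
  expect_lt(abs(sk2$skeleton_length / skl$skeleton_length - 2), 0.1)
  expect_lt(abs(sk2$skeleton_pixel_count / skl$skeleton_pixel_count - 2), 0.3)
})

test_that("measurements scale linearly with pixel_size and transpose cleanly", {
  fx <- make_sinusoidal_suture(fixture_spec(ny = 128, nx = 96, width = 5,
                                            amplitude = 10, wavelength = 64))
  m1 <- measure_suture(fx$truth$mask, 1)
  m2 <- measure_suture(fx$truth$mask, 0.02)
  for (f in c("width_mean", "width_max", "max_amplitude", "skeleton_length"))
    expect_equal(m2[[f]], 0.02 * m1[[f]], tolerance = 1e-12)
  mt <- measure_suture(t(fx$truth$mask), 1, suture_axis = "x")
  expect_equal(mt$width_mean, m1$width_mean)
  expect_equal(mt$max_amplitude, m1$max_amplitude)
})

test_that("pixel widths agree with interpolated interface spans (cross-oracle)", {
  # two-crossing wavy phase field: pixel counting vs u = 0.5 interpolation
  p <- suture_params(nx = 96, ny = 64, t_end = 100)
  xc <- (seq_len(p$nx) - 0.5) * p$dx
  yc <- seq_len(p$ny)
  ctr <- p$nx * p$dx / 2
  xL <- ctr - 250 + 60 * sin(2 * pi * yc / 32)
  xR <- ctr + 250 + 60 * sin(2 * pi * yc / 32 + 1)
  u <- matrix(0, p$ny, p$nx)
  for (i in seq_len(p$ny))
    u[i, ] <- 1 - (1 + tanh((xc - xL[i]) / p$eps)) / 2 +
      (1 + tanh((xc - xR[i]) / p$eps)) / 2
  u <- pmin(pmax(u, 0), 1)
  wpx <- suture_width(u < 0.5, p$dx)$width_per_transect
  span <- interface_span(extract_interface(u, p$dx))
  expect_true(all(abs(wpx - span) <= p$dx))
})

test_that("group comparison and correlation behave as standard statistics", {
  a <- c(1.2, 1.4, 1.1, 1.3)
  expect_equal(compare_groups(a, a)$t, 0)
  expect_equal(correlate(a, 2 * a + 1)$r_squared, 1)
  expect_error(correlate(a, rep(1, 4)), "variance")

  # power: N(0,1) vs N(1,1), n = 100 rejects at 0.05 essentially always
  set.seed(42)
  rej <- mean(replicate(300, {
    compare_groups(rnorm(100), rnorm(100, 1))$p_value < 0.05
  }))
  expect_gte(rej, 0.99)
})
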