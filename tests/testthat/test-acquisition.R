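# Forward simulator: projections, propagation, noise, scan assembly,
# vertical series.

test_that("beam model derives the wavelength and enforces the hutch limit", {
  b <- beam_model(energy_keV = 85)
  expect_equal(b$wavelength_m, 12.398 / 85 * 1e-10)
  expect_error(beam_model(propagation_m = 4), "3.5")
})

test_that("projecting an empty phantom gives zero A and Phi", {
  ph <- build_jar_phantom(c(32, 32, 4), 50, jar_radius_um = 700)
  ph$labels$data[] <- 0L   # all air
  g <- scan_geometry("centered", 32, 2, 50, 4)
  fp <- forward_project(ph, 30, g, beam_model(propagation_m = 1))
  expect_equal(max(abs(fp$A)), 0)
  expect_equal(max(abs(fp$Phi)), 0)
})

test_that("the central chord of a uniform cylinder is 2 R mu", {
  ph <- build_jar_phantom(c(128, 128, 4), 50, jar_radius_um = 2500,
                          jar_wall_um = 1)   # negligible wall
  g <- scan_geometry("centered", 128, 2, 50, 4)
  fp <- forward_project(ph, 0, g, beam_model(propagation_m = 0))
  expected <- 2 * 2.5 * 0.018                # path mm x mu 1/mm
  expect_lt(abs(mean(fp$A[, 64:65]) / expected - 1), 0.005)
})

test_that("projections are 360-degree periodic", {
  ph <- build_jar_phantom(c(48, 48, 4), 50, jar_radius_um = 1000)
  g <- scan_geometry("centered", 48, 2, 50, 4)
  b <- beam_model(propagation_m = 0)
  f1 <- forward_project(ph, 17, g, b)
  f2 <- forward_project(ph, 377, g, b)
  expect_lt(max(abs(f1$A - f2$A)), 1e-10)
})

test_that("Fresnel propagation: contact plane, constancy, fringe scaling", {
  lam <- xray_wavelength(85)
  A <- matrix(runif(16 * 32, 0, 0.5), 16, 32)
  expect_equal(fresnel_propagate(A, 0 * A, lam, 0, 25), exp(-A))
  # constant A and Phi stay constant under propagation
  Ac <- matrix(0.2, 16, 64); Pc <- matrix(1.3, 16, 64)
  I <- fresnel_propagate(Ac, Pc, lam, 1, 10)
  expect_lt(diff(range(I)), 1e-6)
  expect_lt(abs(mean(I) - exp(-0.2)), 1e-6)
  # edge fringe position scales as sqrt(lambda D)
  n <- 1024; px <- 0.5
  Phi <- matrix(rep(c(rep(0, n / 2), rep(0.5, n / 2)), each = 4), 4, n)
  off <- vapply(c(0.5, 1, 2), function(D) {
    I <- fresnel_propagate(matrix(0, 4, n), Phi, lam, D, px)
    prof <- colMeans(I)
    win <- (n / 2 + 2):(n / 2 + 60)
    pk <- win[which.max(prof[win])]
    y <- prof[(pk - 1):(pk + 1)]
    (pk + 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3]) -
       (n / 2 + 0.5)) * px
  }, numeric(1))
  ratio <- off / sqrt(lam * c(0.5, 1, 2) * 1e12)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.15)
})

test_that("beam profiles and noise behave as specified", {
  b <- beam_model(flux = 5e3, read_noise_sd = 1,
                  horizontal_profile = list(amplitude = 1.4,
                                            centre_px = 10, sigma_px = 6),
                  vertical_profile = c(0.9, 1.1))
  I <- matrix(0.8, 2, 20)
  # noise off: counts/flux = I h v exactly
  expected <- apply_beam_and_noise(I, b, noise = FALSE)
  h <- hiptomo:::beam_h_profile(b, 20)
  v <- hiptomo:::beam_v_profile(b, 2)
  expect_equal(expected, 5e3 * I * outer(v, h))
  # same seed twice -> identical frames
  f1 <- apply_beam_and_noise(I, b, seed = 31)
  f2 <- apply_beam_and_noise(I, b, seed = 31)
  expect_identical(f1, f2)
  # Monte-Carlo mean of many flat draws within 3 sigma
  flat <- matrix(1, 1, 4)
  draws <- vapply(seq_len(10000), function(k)
    apply_beam_and_noise(flat, b, seed = k)[1, 1], numeric(1))
  mu <- 5e3 * h[1] * v[1]
  expect_lt(abs(mean(draws) - mu), 3 * sqrt(mu + 1) / sqrt(10000))
})

test_that("sub-frame accumulation reduces noise as 1/sqrt(n)", {
  b <- beam_model(flux = 1e3, read_noise_sd = 0)
  I <- matrix(1, 1, 64)
  sds <- vapply(c(1, 4, 16), function(n) {
    means <- vapply(seq_len(400), function(k) {
      subs <- vapply(seq_len(n), function(s)
        apply_beam_and_noise(I, b, seed = 7919 * k + s)[1, 1], numeric(1))
      mean(subs)
    }, numeric(1))
    sd(means)
  }, numeric(1))
  expect_lt(abs(sds[1] / sds[2] / 2 - 1), 0.1)
  expect_lt(abs(sds[1] / sds[3] / 4 - 1), 0.15)
})

test_that("identical sample and reference jars give unit ratio frames", {
  ph <- build_jar_phantom(c(64, 64, 4), 50, jar_radius_um = 1400)
  g <- scan_geometry("centered", 64, 2, 50, 8)
  ps <- simulate_scan(ph, beam_model(propagation_m = 0, flux = 2e4), g,
                      seed = 3, noise = TRUE)
  acc <- hiptomo:::accumulate_pset(ps)
  ratio <- acc / ps$reference_frames
  expect_lt(abs(mean(ratio) - 1), 0.01)
})

test_that("opposing angles mirror in centered parallel-beam geometry", {
  ph <- build_kidney_phantom(c(64, 64, 8), 50, 1500, 1300, 300, 20,
                             90, 200, seed = 2)
  g <- scan_geometry("centered", 64, 2, 50, 4, angular_range = 360)
  b <- beam_model(propagation_m = 0)
  f0 <- forward_project(ph, 40, g, b)
  f180 <- forward_project(ph, 220, g, b)
  # detector centre is at column (W+1)/2 = 32.5: mirror about it
  # (equal up to the bilinear ray-sampling accuracy)
  expect_lt(max(abs(f0$A - f180$A[, 64:1])), 1e-3 * max(f0$A))
})

test_that("simulate_scan is reproducible under a fixed seed", {
  ph <- build_jar_phantom(c(32, 32, 4), 50, jar_radius_um = 700)
  g <- scan_geometry("centered", 32, 2, 50, 6, n_subframes = 2)
  b <- beam_model(propagation_m = 0, flux = 1e3)
  s1 <- simulate_scan(ph, b, g, seed = 77)
  s2 <- simulate_scan(ph, b, g, seed = 77)
  expect_identical(s1$frames, s2$frames)
  expect_identical(s1$reference_frames, s2$reference_frames)
})

test_that("lateral truncation is flagged for local-tomography scans", {
  ph <- build_jar_phantom(c(128, 128, 4), 50, jar_radius_um = 2800)
  g <- scan_geometry("centered", 48, 2, 50, 4)  # FOV smaller than jar
  fp <- forward_project(ph, 0, g, beam_model(propagation_m = 0))
  expect_true(fp$truncated)
})

test_that("vertical series planning matches the protocol arithmetic", {
  p <- plan_vertical_series(10, 2.6, 2.2)
  expect_equal(p$overlap_percent, 18)
  expect_equal(length(p$z_positions_mm), ceiling((10 - 2.6) / 2.2) + 1)
  expect_equal(plan_vertical_series(10, 2.6, 2.6)$overlap_percent, 0)
  expect_error(plan_vertical_series(10, 2.2, 2.6), "gap")
})

test_that("half-mode geometry preconditions hold", {
  expect_error(scan_geometry("half", 100, 2, 50, 10, angular_range = 180,
                             cor_offset_px = 20), "360")
  expect_error(scan_geometry("half", 100, 2, 50, 10, angular_range = 360,
                             cor_offset_px = 60), "cor_offset")
})
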