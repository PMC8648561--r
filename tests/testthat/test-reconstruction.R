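# Reconstruction chain operators.

test_that("accumulation averages and flags saturation", {
  f <- matrix(runif(12), 3, 4)
  acc <- accumulate(list(f, f, f))
  expect_equal(acc$frame, f)
  expect_false(any(acc$saturated))
  # one saturated sub-frame: flagged, value from the remaining ones
  f2 <- f; f2[2, 2] <- 70000
  acc2 <- accumulate(list(f, f2, f), full_well = 65000)
  expect_true(acc2$saturated[2, 2])
  expect_equal(acc2$frame[2, 2], f[2, 2])
  expect_equal(acc2$frame[1, 1], f[1, 1])
  expect_error(accumulate(list()), "sub-frame")
})

test_that("variance of the accumulated mean scales as sigma^2/n", {
  set.seed(10)
  n <- 10
  means <- vapply(seq_len(2000), function(k) {
    subs <- array(rnorm(4 * 4 * n, 100, 5), c(4, 4, n))
    accumulate(subs)$frame[1, 1]
  }, numeric(1))
  expect_lt(abs(var(means) / (25 / n) - 1), 0.1)
})

test_that("reference flat-fielding has the stated degenerate behaviours", {
  set.seed(1)
  d <- c(2, 8, 40)
  base <- array(rep(100 * (1 + 0.1 * sin(seq_len(d[2]) / 3)),
                    each = d[1]), d)
  dark <- matrix(2, d[1], d[2])
  # sample identical to reference, noise off -> output exactly 1
  out <- reference_flatfield(base, base, dark, window = 10)
  expect_lt(max(abs(out - 1)), 1e-12)
  # time-constant beam: centred window equals the classical flat division
  flats <- array(base[, , 1], c(d[1], d[2], 3))
  cls <- classical_flatfield(base, flats, dark)
  expect_lt(max(abs(out - cls)), 1e-12)
  # non-positive reference errors
  expect_error(reference_flatfield(base, 0 * base, dark), "non-positive")
})

test_that("windowed references remove most of a linear beam drift", {
  d <- c(2, 8, 120)
  profile <- matrix(100, d[1], d[2])
  drift <- 1 + 0.2 * (seq_len(d[3]) - 1) / (d[3] - 1)  # +20% over the scan
  proj <- array(0, d); ref <- array(0, d)
  for (a in seq_len(d[3])) {
    proj[, , a] <- profile * drift[a]
    ref[, , a] <- profile * drift[a]   # reference sees the same drift
  }
  dark <- matrix(0, d[1], d[2])
  out <- reference_flatfield(proj, ref, dark, window = 10)
  resid <- diff(range(apply(out, 3, mean)))
  uncorrected <- diff(range(drift))
  expect_lt(resid / uncorrected, 0.10)
})

test_that("vertical residual subtraction removes injected row offsets", {
  set.seed(6)
  d <- c(8, 16, 30)
  clean <- array(rnorm(prod(d), 1, 0.001), d)
  offs <- rnorm(d[1], 0, 0.2)
  dirty <- sweep(clean, 1, offs, "+")
  fixed <- subtract_vertical_residual(dirty)
  resid <- vapply(seq_len(d[1]), function(r)
    mean(fixed[r, , ]) - mean(clean), numeric(1))
  expect_lt(max(abs(resid - mean(offs))) / sd(offs), 0.05)
  expect_lt(abs(mean(fixed) - mean(dirty)), 1e-6)   # mean preserved
  # zero-residual input is unchanged
  flat <- array(1, d)
  expect_lt(max(abs(subtract_vertical_residual(flat) - flat)), 1e-6)
})

test_that("phase retrieval obeys its closed-form limits", {
  rp0 <- retrieval_params(propagation_m = 0, pixel_size_um = 2.5)
  I <- matrix(exp(-abs(rnorm(32 * 32))), 32)
  expect_equal(paganin_retrieve(I, rp0), -log(I))
  rp <- retrieval_params(delta_beta = 1000, propagation_m = 1,
                         energy_keV = 85, pixel_size_um = 2.5)
  Iu <- matrix(exp(-0.3), 40, 40)
  expect_lt(max(abs(paganin_retrieve(Iu, rp) - 0.3)), 1e-12)
  expect_error(paganin_retrieve(I - 1, rp), "positive")
})

test_that("phase retrieval matches a direct DFT oracle on 64x64", {
  rp <- retrieval_params(delta_beta = 1000, propagation_m = 1,
                         energy_keV = 85, pixel_size_um = 2.5)
  g <- outer(dnorm(1:64, 32, 6), dnorm(1:64, 32, 6))
  I <- exp(-g / max(g) * 0.5)
  t1 <- paganin_retrieve(I, rp, pad_frac = 0)
  u <- hiptomo:::fft_freq(64, 2.5e-6)
  den <- 1 + pi * rp$wavelength_m * 1 * 1000 * outer(u^2, u^2, "+")
  t2 <- -log(Re(stats::fft(stats::fft(I) / den, inverse = TRUE)) / 64^2)
  expect_lt(max(abs(t1 - t2)), 1e-6)
})

test_that("unsharp mask: identity, constancy, convolution oracle", {
  m <- matrix(rnorm(30 * 20), 30, 20)
  expect_identical(unsharp_mask(m, 2, 0), m)
  cst <- matrix(3, 10, 10)
  expect_lt(max(abs(unsharp_mask(cst, 2, 1) - 3)), 1e-12)
  # 1D step edge overshoot equals the direct convolution oracle
  step <- matrix(rep(c(rep(0, 16), rep(1, 16)), each = 8), 8, 32)
  out <- unsharp_mask(step, 2, 1)
  k <- hiptomo:::gauss_kernel(2)
  blur_row <- conv1d_oracle(step[1, ], k)
  oracle <- step[1, ] + 1 * (step[1, ] - blur_row)
  expect_lt(max(abs(out[4, ] - oracle)), 1e-9)
})

test_that("half-acquisition stitching is consistent and degenerates", {
  # constant sinogram stays constant through the blend (weights sum to 1)
  na <- 20; W <- 24; o <- 4
  s360 <- sinogram(matrix(5, na, W), seq(0, 360, length.out = na + 1)[1:na],
                   50, cor_column = (W + 1) / 2 + o)
  st <- build_half_sinogram(s360, o)
  expect_equal(dim(st$data)[2], W + 2 * o)
  expect_lt(max(abs(st$data - 5)), 1e-12)
  expect_equal(length(st$angles), na / 2)
  # o = 0 degenerates to the mean of the two half-turns
  x <- matrix(rnorm(na * W), na, W)
  s0 <- sinogram(x, seq(0, 360, length.out = na + 1)[1:na], 50)
  st0 <- build_half_sinogram(s0, 0)
  manual <- (x[1:(na / 2), ] + x[(na / 2 + 1):na, W:1]) / 2
  expect_lt(max(abs(st0$data[, , 1] - manual)), 1e-12)
  expect_error(build_half_sinogram(s360, W / 2), "cor_offset")
})

test_that("half-acquisition chain equals the wide-detector oracle", {
  vx <- 50
  ph <- build_kidney_phantom(c(128, 128, 8), vx, 2900, 2500, 800, 25,
                             unit_radius_um = 180,
                             min_separation_um = 450, seed = 11)
  beam <- beam_model(propagation_m = 0, flux = 2e4)
  gw <- scan_geometry("centered", 144, 2, vx, 180)
  pw <- simulate_scan(ph, beam, gw, seed = 1, noise = FALSE,
                      reference_phantom = FALSE)
  rw <- reconstruct_scan(pw, flatfield = "classical")
  gh <- scan_geometry("half", 104, 2, vx, 360, angular_range = 360,
                      cor_offset_px = 20)
  phh <- simulate_scan(ph, beam, gh, seed = 1, noise = FALSE,
                       reference_phantom = FALSE)
  rh <- reconstruct_scan(phh, flatfield = "classical")
  expect_equal(dim(rh$data), dim(rw$data))
  expect_gt(ssim(rw$data[, , 1], rh$data[, , 1]), 0.95)
  expect_lt(sqrt(mean((rw$data - rh$data)^2)) / diff(range(rw$data)), 0.01)
})

test_that("quarter stitching calibrates grey levels and blends", {
  # identical data in the overlap -> gain 1 and seamless output
  na <- 12; Wi <- 20; Wo <- 32
  ang <- seq(0, 180, length.out = na + 1)[1:na]
  base <- matrix(rnorm(na * Wo, 10), na, Wo)
  inner <- sinogram(base[, 7:26], ang, 50)
  outer_s <- sinogram(base, ang, 50)
  st <- stitch_quarter(inner, outer_s, overlap_px = 4)
  expect_lt(max(abs(st$data[, , 1] - base)), 1e-9)
  expect_true(any(grepl("gain=1.0000", st$provenance)))
  # a pre-scaled annular scan has its gain recovered
  outer_sc <- sinogram(base / 1.25, ang, 50)
  st2 <- stitch_quarter(inner, outer_sc, overlap_px = 4)
  g <- as.numeric(sub(".*gain=([0-9.]+).*", "\\1",
                      st2$provenance[grepl("gain", st2$provenance)]))
  expect_lt(abs(g - 1.25), 1e-3)
  expect_error(stitch_quarter(inner, outer_s, 0), "overlap")
})

test_that("quarter-stitched reconstruction matches the wide-scan oracle", {
  fx <- scan_fixture()
  # wide sinogram from the fixture scan; fake an annular acquisition by
  # splitting it into a central band and the full-width scan
  proj <- hiptomo:::accumulate_pset(fx$pset)
  norm <- classical_flatfield(proj, fx$pset$flats, fx$pset$darks)
  tm <- -log(norm)
  W <- dim(tm)[2]
  sino <- sinogram(aperm(tm, c(3, 2, 1))[, , 1, drop = FALSE],
                   fx$pset$angles, fx$geometry$pixel_size_um)
  rec_wide <- fbp(sino)
  inner_cols <- 33:96
  inner <- sinogram(sino$data[, inner_cols, 1], sino$angles, 50)
  st <- stitch_quarter(inner, sino, overlap_px = 8)
  rec_st <- fbp(st)
  expect_gt(ssim(rec_wide$data[, , 1], rec_st$data[, , 1]), 0.95)
})

test_that("FBP recovers a uniform disc and is projection-count stable", {
  fx <- scan_fixture()
  rec <- reconstruct_scan(fx$pset, flatfield = "classical",
                          filter = "ramp")
  mu <- phantom_property_volume(fx$phantom, "mu")
  truth <- mu$data[, , 3:4]
  expect_lt(sqrt(mean((rec$data - truth)^2)) / diff(range(truth)), 0.02)
  # zero sinogram reconstructs to zero
  z <- sinogram(matrix(0, 90, 32), seq(0, 179, 2), 50)
  expect_equal(max(abs(fbp(z)$data)), 0)
  # doubling the projection count barely moves the interior mean
  g2 <- scan_geometry("centered", 128, 2, 50, 720)
  p2 <- simulate_scan(fx$phantom, fx$beam, g2, seed = 1, noise = FALSE,
                      reference_phantom = FALSE)
  r2 <- reconstruct_scan(p2, flatfield = "classical", filter = "ramp")
  inner <- rec$data[55:75, 55:75, 1]
  inner2 <- r2$data[55:75, 55:75, 1]
  expect_lt(abs(mean(inner) - mean(inner2)) / mean(inner), 0.001)
  # angular span check
  short <- sinogram(matrix(1, 10, 16), seq(0, 90, length.out = 10), 50)
  expect_error(fbp(short), "170")
})

test_that("local reconstruction degenerates to FBP for complete data", {
  fx <- scan_fixture()
  rec <- reconstruct_scan(fx$pset, flatfield = "classical")
  loc <- reconstruct_scan(fx$pset, flatfield = "classical", local = TRUE)
  n <- dim(rec$data)[1]
  cx <- (n + 1) / 2
  rr <- sqrt(outer((1:n - cx)^2, (1:n - cx)^2, "+"))
  inside <- rr < n / 2 - 4
  expect_lt(max(abs(rec$data[, , 1][inside] - loc$data[, , 1][inside])),
            1e-6)
})

test_that("vertical concatenation recovers injected shifts and blends", {
  set.seed(13)
  base <- array(rnorm(16 * 16 * 40), c(16, 16, 40))
  vx <- 50
  # A = slices 1..24, B = slices 16..40 => nominal overlap 9 with shift +2
  A <- volume3d(base[, , 1:24], vx)
  B <- volume3d(base[, , 18:40], vx)   # actually starts 2 later
  out <- concat_vertical(list(A, B), overlaps = 9)
  expect_equal(attr(out, "shifts"), 2L)
  expect_equal(dim(out$data)[3], 40)
  expect_lt(max(abs(out$data - base)), 1e-9)
  # zero overlap stacks plainly
  out0 <- concat_vertical(list(A, volume3d(base[, , 25:40], vx)),
                          overlaps = 0)
  expect_equal(dim(out0$data)[3], 40)
  expect_lt(max(abs(out0$data - base)), 1e-12)
  # constant overlap slices blend to the same constant (weights sum to 1)
  C1 <- volume3d(array(4, c(4, 4, 10)), vx)
  C2 <- volume3d(array(4, c(4, 4, 10)), vx)
  expect_warning(cc <- concat_vertical(list(C1, C2), overlaps = 4),
                 "threshold")
  expect_lt(max(abs(cc$data - 4)), 1e-12)
})

test_that("16-bit conversion windows, clips and round-trips", {
  x <- volume3d(array(runif(10^3, -1, 1), c(10, 10, 10)), 1)
  u <- to_uint16(x, c(0, 100))
  expect_equal(min(u$data), 0)
  expect_equal(max(u$data), 65535)
  expect_lte(max(abs(physical_values(u) - x$data)), u$scale[2] / 2 + 1e-12)
  cst <- to_uint16(volume3d(array(7, c(4, 4, 4)), 1))
  expect_true(all(cst$data == 32768))
  expect_equal(physical_values(cst)[1], 7)
  bad <- volume3d(array(c(NA, rep(1, 7)), c(2, 2, 2)), 1)
  expect_error(to_uint16(bad), "finite")
})

test_that("ring correction removes injected rings and spares clean slices", {
  n <- 128
  cx <- (n + 1) / 2
  rr <- sqrt(outer((1:n - cx)^2, (1:n - cx)^2, "+"))
  smooth <- exp(-rr^2 / (2 * 40^2))           # smooth radial phantom
  a <- 0.2
  ring <- a * exp(-(rr - 30)^2 / 2)           # concentric ring artefact
  fixed <- remove_rings(smooth + ring)
  resid <- fixed - smooth
  band <- rr > 27 & rr < 33
  expect_lt(max(abs(resid[band])), 0.15 * a)
  expect_lt(abs(mean(fixed) - mean(smooth + ring)) /
              abs(mean(smooth + ring)), 0.001)
  # near-identity on a ring-free slice
  fixed2 <- remove_rings(smooth)
  expect_lt(max(abs(fixed2 - smooth)) / diff(range(smooth)), 0.01)
})

test_that("stripe correction removes plane offsets and is idempotent", {
  set.seed(4)
  # z-stationary structure + voxel noise: slices share their mean level
  pat <- outer(sin((1:12) / 2), cos((1:12) / 3))
  base <- array(rnorm(12 * 12 * 24, 0, 0.005), c(12, 12, 24)) +
    array(rep(pat, 24), c(12, 12, 24)) + 10
  # isolated bright/dark planes, the signature of residual stripes
  a <- 0.5
  offs <- numeric(24)
  offs[c(5, 11, 17)] <- c(a, -a, a)
  dirty <- volume3d(sweep(base, 3, offs, "+"), 1)
  fixed <- remove_stripes(dirty)
  resid <- apply(fixed$data - base, 3, mean)
  expect_lt(max(abs(resid[c(5, 11, 17)])) / a, 0.10)
  clean <- volume3d(base, 1)
  expect_lt(max(abs(remove_stripes(clean)$data - base)) /
              diff(range(base)), 0.01)
  twice <- remove_stripes(fixed)
  expect_lt(max(abs(twice$data - fixed$data)) / diff(range(fixed$data)),
            0.01)
  expect_error(remove_stripes(volume3d(array(0, c(4, 4, 4)), 1)), "8")
})

test_that("the pipeline records provenance and reruns bit-identically", {
  fx <- scan_fixture()
  r1 <- reconstruct_scan(fx$pset, flatfield = "classical")
  expect_true(any(grepl("accumulate", attr(r1, "provenance"))))
  expect_true(any(grepl("fbp", attr(r1, "provenance"))))
  ps2 <- simulate_scan(fx$phantom, fx$beam, fx$geometry, seed = 42,
                       noise = FALSE, reference_phantom = FALSE)
  r2 <- reconstruct_scan(ps2, flatfield = "classical")
  expect_identical(r1$data, r2$data)
})
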