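# FSC, resolution protocol, SNR, SSIM, histogram statistics.

test_that("FSC of a volume with itself is one on every shell", {
  set.seed(21)
  a <- array(rnorm(32^3), c(32, 32, 32))
  fc <- fsc(a, a)
  expect_lt(max(abs(fc$fsc - 1)), 1e-9)
  expect_true(all(diff(fc$shell_radii) > 0))
})

test_that("FSC is symmetric, bounded, and near zero for independent noise", {
  set.seed(22)
  a <- array(rnorm(64^3), c(64, 64, 64))
  b <- array(rnorm(64^3), c(64, 64, 64))
  f1 <- fsc(a, b); f2 <- fsc(b, a)
  expect_equal(f1$fsc, f2$fsc, tolerance = 1e-12)
  expect_lt(max(abs(f1$fsc)), 1 + 1e-9)
  expect_lt(abs(mean(f1$fsc)), 0.05)
  expect_error(fsc(a, array(0, c(32, 32, 32))), "identical shapes")
})

test_that("an injected band limit is recovered by the FSC crossing", {
  set.seed(23)
  base <- array(rnorm(64^3), c(64, 64, 64))
  FF <- stats::fft(base)
  fr <- hiptomo:::fft_freq(64, 1)
  R <- sqrt(outer(outer(fr^2, fr^2, "+"), fr^2, "+"))
  FF[R > 0.25] <- 0
  sig <- Re(stats::fft(FF, inverse = TRUE)) / 64^3
  v1 <- sig + 0.05 * sd(sig) * array(rnorm(64^3), c(64, 64, 64))
  v2 <- sig + 0.05 * sd(sig) * array(rnorm(64^3), c(64, 64, 64))
  res <- resolution_from_fsc(fsc(v1, v2, window = "none"), 1)
  expect_lt(abs(attr(res, "crossing_freq") - 0.25) / 0.25, 0.10)
})

test_that("the 1/2-bit threshold has its closed-form limits", {
  expect_equal(half_bit_curve(1), 1.0)
  expect_lt(abs(half_bit_curve(1e14) - 0.2071 / 1.2071), 1e-6)
  n <- c(1, 2, 5, 10, 100, 1e4, 1e8)
  expect_true(all(diff(half_bit_curve(n)) < 0))
})

test_that("resolution reporting follows the crossing convention", {
  curve <- structure(list(shell_radii = c(0.1, 0.2, 0.3),
                          fsc = c(0.9, 0.3, 0.1),
                          half_bit_threshold = c(0.2, 0.2, 0.2)),
                     class = "fsc_curve")
  # crossing interpolates to 0.25 cycles/voxel; 2.5 um voxels -> 10 um
  r <- resolution_from_fsc(curve, 2.5)
  expect_equal(attr(r, "crossing_freq"), 0.25)
  expect_equal(as.numeric(r), 10)
  # halving the voxel size halves the resolution
  expect_equal(as.numeric(resolution_from_fsc(curve, 1.25)), 5)
  # identical volumes -> sentinel
  set.seed(2)
  a <- array(rnorm(16^3), c(16, 16, 16))
  s <- resolution_from_fsc(fsc(a, a), 1)
  expect_true(is.na(s))
  expect_equal(attr(s, "sentinel"), "beyond_nyquist")
})

test_that("the subvolume protocol is seeded and stable", {
  set.seed(24)
  base <- array(rnorm(96^3), c(96, 96, 96))
  FF <- stats::fft(base)
  fr <- hiptomo:::fft_freq(96, 1)
  R <- sqrt(outer(outer(fr^2, fr^2, "+"), fr^2, "+"))
  FF[R > 0.2] <- 0
  sig <- Re(stats::fft(FF, inverse = TRUE)) / 96^3
  v1 <- sig + 0.3 * sd(sig) * array(rnorm(96^3), c(96, 96, 96))
  v2 <- sig + 0.3 * sd(sig) * array(rnorm(96^3), c(96, 96, 96))
  p1 <- fsc_resolution_protocol(v1, v2, voxel_size = 1, n_sub = 9,
                                sizes = c(32, 48, 64), seed = 5)
  p2 <- fsc_resolution_protocol(v1, v2, voxel_size = 1, n_sub = 9,
                                sizes = c(32, 48, 64), seed = 5)
  expect_identical(p1$resolutions, p2$resolutions)
  expect_lt(p1$sd / p1$mean, 0.3)
  # identical volumes: every subvolume is a sentinel, aggregate empty
  expect_warning(
    p0 <- fsc_resolution_protocol(v1, v1, 1, n_sub = 3,
                                  sizes = 32, seed = 1),
    "without threshold")
  expect_equal(p0$n_excluded, 3)
  expect_true(is.na(p0$mean))
})

test_that("SNR follows its definition and affine invariance", {
  set.seed(25)
  vol <- array(rnorm(12^3), c(12, 12, 12))
  ft <- array(FALSE, dim(vol)); ft[1:4, , ] <- TRUE
  bg <- array(FALSE, dim(vol)); bg[9:12, , ] <- TRUE
  flatft <- vol; flatft[ft] <- mean(flatft[bg])   # mu_ft == mu_bg -> 0
  expect_equal(snr(flatft, ft, bg), 0)
  vol2 <- vol
  vol2[ft] <- vol2[ft] - mean(vol2[ft]) + mean(vol2[bg]) +
    6 * sd(vol2[bg])
  expect_lt(abs(snr(vol2, ft, bg) - 6), 0.01)
  expect_equal(snr(3 * vol2 + 2, ft, bg), snr(vol2, ft, bg),
               tolerance = 1e-12)
  expect_error(snr(vol, ft, array(FALSE, dim(vol))), "2 voxels")
  flat <- vol; flat[bg] <- 1
  expect_error(snr(flat, ft, bg), "zero variance")
})

test_that("SSIM behaves on identity and monotone degradation", {
  set.seed(26)
  x <- matrix(rnorm(48^2), 48)
  expect_equal(ssim(x, x), 1, tolerance = 1e-9)
  weak <- ssim(x, x + 0.1 * matrix(rnorm(48^2), 48))
  strong <- ssim(x, x + matrix(rnorm(48^2), 48))
  expect_gt(weak, strong)
})

test_that("SSIM group comparison is null for identical volumes", {
  set.seed(27)
  v <- array(rnorm(16 * 16 * 12), c(16, 16, 12))
  # paired-slice groups drawn from one volume are indistinguishable:
  # the ANOVA should be non-significant in nearly all seeded repetitions
  ps <- vapply(seq_len(100), function(s)
    ssim_pairs(v, v, n_pairs = 20, seed = s)$anova$p, numeric(1))
  expect_gte(mean(ps > 0.05), 0.95)
  sp <- ssim_pairs(v, v, n_pairs = 25, seed = 3)
  expect_s3_class(sp$pairs, "tbl_df")
  expect_equal(nrow(sp$pairs), 100)
  expect_setequal(unique(sp$pairs$group), c("1-1", "2-2", "1-2", "2-1"))
  g <- glance(sp)
  expect_true(all(c("median_ssim", "F", "p") %in% names(g)))
})

test_that("histogram statistics match known moments and intersections", {
  set.seed(28)
  x <- array(rnorm(1e6), c(100, 100, 100))
  h <- histogram_stats(x, 0.001)
  expect_lt(abs(h$skew), 0.02)
  expect_lt(abs(h$kurtosis_excess), 0.05)
  expect_lt(abs(h$mean - mean(x)), 1e-12)
  expect_equal(histogram_intersection(h, h), 100)
  h2 <- histogram_stats(x + 50, 0.001)
  expect_equal(histogram_intersection(h, h2), 0)
  h3 <- histogram_stats(x, 0.002)
  expect_error(histogram_intersection(h, h3), "bin width")
  # overlapping but different distributions land strictly between
  h4 <- histogram_stats(x + 0.5, 0.001)
  mid <- histogram_intersection(h, h4)
  expect_gt(mid, 50); expect_lt(mid, 95)
})

test_that("tidiers and autoplot return well-formed objects", {
  set.seed(29)
  a <- array(rnorm(24^3), c(24, 24, 24))
  b <- a + 0.5 * array(rnorm(24^3), c(24, 24, 24))
  fc <- fsc(a, b)
  td <- tidy(fc)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), length(fc$fsc))
  p <- autoplot(fc)
  expect_s3_class(p, "ggplot")
})
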