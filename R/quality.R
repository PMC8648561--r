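# Image-quality metrics: Fourier shell correlation with the 1/2-bit
# resolution criterion and the random-subvolume protocol, SNR, structural
# similarity with group resampling, and histogram statistics.

as_vol_array <- function(x) {
  if (inherits(x, "volume3d")) physical_values(x) else x
}

hann_3d <- function(n) {
  w1 <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  outer(outer(w1, w1), w1)
}

#' Fourier shell correlation of two volumes
#'
#' Per-shell normalised cross-correlation of the 3D spectra,
#' `Re( sum F_A conj(F_B) ) / sqrt( sum |F_A|^2 sum |F_B|^2 )`, with shells
#' one frequency voxel wide up to the Nyquist frequency (0.5 cycles/voxel).
#' A 3D Hann window (default) reduces spectral leakage from the subvolume
#' edges; the effective number of independent voxels per shell used for the
#' 1/2-bit threshold accounts for both Hermitian symmetry and the window.
#'
#' @param volA,volB equally sized cubic volumes ([volume3d()] or arrays).
#' @param window `"hann"` or `"none"`.
#' @return an `fsc_curve`: list with `shell_radii` (cycles/voxel), `fsc`,
#'   `n_voxels_per_shell`, `n_eff`, `half_bit_threshold`, `window`.
#' @export
fsc <- function(volA, volB, window = c("hann", "none")) {
  window <- match.arg(window)
  a <- as_vol_array(volA); b <- as_vol_array(volB)
  if (!identical(dim(a), dim(b)))
    stop("volumes must have identical shapes", call. = FALSE)
  n <- dim(a)[1]
  if (!all(dim(a) == n)) stop("volumes must be cubic", call. = FALSE)
  weff <- 1
  if (window == "hann") {
    w <- hann_3d(n)
    weff <- sum(w)^2 / (length(w) * sum(w^2))
    a <- a * w; b <- b * w
  }
  FA <- stats::fft(a); FB <- stats::fft(b)
  f1 <- fft_freq(n, 1)
  r <- sqrt(outer(outer(f1^2, f1^2, "+"), f1^2, "+"))
  shell <- floor(r * n) + 1L            # shells one frequency voxel wide
  keep <- r <= 0.5 + 1e-12
  ns <- max(shell[keep])
  idx <- shell[keep]
  num <- as.vector(tapply(Re(FA[keep] * Conj(FB[keep])), idx, sum))
  pa <- as.vector(tapply(Mod(FA[keep])^2, idx, sum))
  pb <- as.vector(tapply(Mod(FB[keep])^2, idx, sum))
  counts <- as.vector(table(idx))
  fsc_v <- num / sqrt(pa * pb)
  fsc_v[!is.finite(fsc_v)] <- 0
  n_eff <- pmax(1, counts / 2 * weff)
  structure(list(shell_radii = (seq_len(ns) - 0.5) / n,
                 fsc = fsc_v,
                 n_voxels_per_shell = counts,
                 n_eff = n_eff,
                 half_bit_threshold = half_bit_curve(n_eff),
                 window = window),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells, window %s; fsc range [%.3f, %.3f]\n",
              length(x$fsc), x$window, min(x$fsc), max(x$fsc)))
  invisible(x)
}

#' 1/2-bit information threshold curve
#'
#' `T(n) = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 / sqrt(n))` with
#' `n` the effective number of independent voxels in the shell: 1 at
#' `n = 1`, decreasing towards `0.2071 / 1.2071 ~= 0.1716` for large shells.
#'
#' @param n_eff effective voxels per shell (>= 1).
#' @return threshold per shell.
#' @export
half_bit_curve <- function(n_eff) {
  stopifnot(all(n_eff >= 1))
  s <- sqrt(n_eff)
  (0.2071 + 1.9102 / s) / (1.2071 + 0.9102 / s)
}

#' Resolution from an FSC curve
#'
#' Locates the first crossing of the FSC below its 1/2-bit threshold by
#' linear interpolation between shells and reports
#' `resolution = voxel_size / crossing_frequency` (µm; the half-period
#' convention in which a crossing at 0.25 cycles/voxel with 2.5 µm voxels
#' gives 10 µm). Returns `NA` with attribute `sentinel =
#' "beyond_nyquist"` when the curve never crosses.
#'
#' @param curve an `fsc_curve`.
#' @param voxel_size voxel size, µm.
#' @return resolution in µm (NA if no crossing), with attribute
#'   `crossing_freq` (cycles/voxel).
#' @export
resolution_from_fsc <- function(curve, voxel_size) {
  d <- curve$fsc - curve$half_bit_threshold
  below <- which(d < 0)
  # the zero-frequency shell is a single coefficient (the volume mean) and
  # carries no resolution information; never report a crossing there
  below <- below[below > 1]
  if (!length(below)) {
    out <- NA_real_
    attr(out, "sentinel") <- "beyond_nyquist"
    return(out)
  }
  i <- below[1]
  if (i == 1 || d[i - 1] <= 0) {
    q <- curve$shell_radii[i]
  } else {
    f0 <- curve$shell_radii[i - 1]; f1 <- curve$shell_radii[i]
    q <- f0 + (f1 - f0) * d[i - 1] / (d[i - 1] - d[i])
  }
  out <- voxel_size / q
  attr(out, "crossing_freq") <- q
  out
}

#' Random-subvolume FSC resolution protocol
#'
#' Draws `n_sub` random cubic subvolumes (identical positions in both
#' volumes), computes the FSC of each, and aggregates the 1/2-bit crossing
#' resolutions to mean and standard deviation. Subvolumes without a
#' crossing are excluded with a warning and reported in the result.
#'
#' @param volA,volB aligned volumes of the same size.
#' @param voxel_size voxel size, µm.
#' @param n_sub number of subvolumes (default 9).
#' @param sizes candidate cube edge lengths, voxels; each draw picks one at
#'   random (sizes larger than the volume are clamped).
#' @param seed RNG seed.
#' @param window FSC window.
#' @return list with `resolutions` (µm per subvolume, NA = excluded),
#'   `mean`, `sd`, `n_excluded`, `draws` (tibble of positions and sizes).
#' @export
fsc_resolution_protocol <- function(volA, volB, voxel_size, n_sub = 9,
                                    sizes = c(200, 500, 1000), seed = NULL,
                                    window = "hann") {
  a <- as_vol_array(volA); b <- as_vol_array(volB)
  stopifnot(identical(dim(a), dim(b)))
  d <- dim(a)
  if (min(d) < 8)
    stop("volumes too small for the subvolume protocol (need >= 8 voxels ",
         "along every axis)", call. = FALSE)
  sizes <- pmin(sizes, min(d))
  sizes <- unique(pmax(sizes, 8))
  draws <- with_seed(seed, {
    sz <- sample(sizes, n_sub, replace = TRUE)
    pos <- vapply(sz, function(s)
      vapply(d, function(dd) sample.int(dd - s + 1, 1), integer(1)),
      integer(3))
    list(sz = sz, pos = t(pos))
  })
  res <- rep(NA_real_, n_sub)
  for (k in seq_len(n_sub)) {
    s <- draws$sz[k]; p <- draws$pos[k, ]
    ia <- a[p[1] + seq_len(s) - 1, p[2] + seq_len(s) - 1,
            p[3] + seq_len(s) - 1]
    ib <- b[p[1] + seq_len(s) - 1, p[2] + seq_len(s) - 1,
            p[3] + seq_len(s) - 1]
    res[k] <- resolution_from_fsc(fsc(ia, ib, window), voxel_size)
  }
  n_exc <- sum(is.na(res))
  if (n_exc > 0)
    warning(sprintf("%d subvolume(s) without threshold crossing excluded",
                    n_exc))
  ok <- res[!is.na(res)]
  list(resolutions = res,
       mean = if (length(ok)) mean(ok) else NA_real_,
       sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
       n_excluded = n_exc,
       draws = tibble::tibble(size = draws$sz,
                              x = draws$pos[, 1], y = draws$pos[, 2],
                              z = draws$pos[, 3], resolution_um = res))
}

#' Signal-to-noise ratio between a feature and a background ROI
#'
#' `(mu_ft - mu_bg) / sigma_bg`; the convention used for tubule walls
#' against the open tubule lumen. Invariant under affine intensity maps.
#'
#' @param vol a [volume3d()] or array.
#' @param feature logical mask (or index vector) of the feature ROI.
#' @param background logical mask (or index vector) of the background ROI;
#'   must be disjoint from the feature and contain at least 2 voxels.
#' @return SNR (dimensionless).
#' @export
snr <- function(vol, feature, background) {
  x <- as_vol_array(vol)
  xf <- x[feature]; xb <- x[background]
  if (length(xb) < 2) stop("background ROI needs >= 2 voxels", call. = FALSE)
  if (is.logical(feature) && is.logical(background) &&
      any(feature & background))
    stop("feature and background ROIs must be disjoint", call. = FALSE)
  s <- stats::sd(xb)
  if (s == 0) stop("background ROI has zero variance", call. = FALSE)
  (mean(xf) - mean(xb)) / s
}

#' Structural similarity index of two images
#'
#' Standard SSIM with a Gaussian weighting window (sigma 1.5), constants
#' `K1 = 0.01`, `K2 = 0.03`, and the dynamic range taken from the data
#' (0.1/99.9 percentiles of both images) unless supplied.
#'
#' @param a,b numeric matrices of identical size.
#' @param sigma Gaussian window sigma, px.
#' @param K1,K2 stability constants.
#' @param dynamic_range grey-value range `L`; default from data.
#' @return mean SSIM over the map.
#' @export
ssim <- function(a, b, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 dynamic_range = NULL) {
  stopifnot(identical(dim(a), dim(b)))
  if (is.null(dynamic_range)) {
    q <- stats::quantile(c(a, b), c(0.001, 0.999), names = FALSE)
    dynamic_range <- max(q[2] - q[1], .Machine$double.eps)
  }
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  mu_a <- gauss_blur2d(a, sigma)
  mu_b <- gauss_blur2d(b, sigma)
  va <- gauss_blur2d(a * a, sigma) - mu_a^2
  vb <- gauss_blur2d(b * b, sigma) - mu_b^2
  cab <- gauss_blur2d(a * b, sigma) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(map)
}

#' Grouped SSIM comparison of two subvolumes
#'
#' Randomly samples `n_pairs` slice pairs per group — within volume 1
#' (`1-1`), within volume 2 (`2-2`) and across (`1-2`, `2-1`) — computes
#' SSIM for each pair and summarises the four distributions with a one-way
#' ANOVA. Used to show two reconstructions are statistically
#' indistinguishable in quality.
#'
#' @param vol1,vol2 volumes with identical slice shapes.
#' @param n_pairs pairs per group (default 200). If a volume has fewer
#'   slices than needed the sampling is with replacement (noted).
#' @param seed RNG seed.
#' @param ... passed to [ssim()].
#' @return object of class `ssim_comparison`: `pairs` tibble
#'   (group, slice_i, slice_j, ssim) and `anova` tibble (F, p).
#' @export
ssim_pairs <- function(vol1, vol2, n_pairs = 200, seed = NULL, ...) {
  a <- as_vol_array(vol1); b <- as_vol_array(vol2)
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop("slice shapes must match", call. = FALSE)
  n1 <- dim(a)[3]; n2 <- dim(b)[3]
  if (n1 < 2 || n2 < 2) stop("need >= 2 slices per volume", call. = FALSE)
  groups <- c("1-1", "2-2", "1-2", "2-1")
  res <- with_seed(seed, {
    out <- list()
    for (g in groups) {
      src <- if (g %in% c("1-1", "1-2")) n1 else n2
      dst <- if (g %in% c("1-1", "2-1")) n1 else n2
      i <- sample.int(src, n_pairs, replace = TRUE)
      j <- sample.int(dst, n_pairs, replace = TRUE)
      # never pair a slice number with itself: within one volume that is a
      # degenerate self-comparison, and excluding it in every group keeps
      # the four groups exchangeable when the volumes coincide
      same <- i == j
      j[same] <- (j[same] %% dst) + 1L
      out[[g]] <- cbind(i, j)
    }
    out
  })
  rows <- list()
  for (g in groups) {
    va <- if (g %in% c("1-1", "1-2")) a else b
    vb <- if (g %in% c("1-1", "2-1")) a else b
    ij <- res[[g]]
    sv <- vapply(seq_len(nrow(ij)), function(k)
      ssim(va[, , ij[k, 1]], vb[, , ij[k, 2]], ...), numeric(1))
    rows[[g]] <- tibble::tibble(group = g, slice_i = ij[, 1],
                                slice_j = ij[, 2], ssim = sv)
  }
  pairs <- do.call(rbind, rows)
  if (stats::var(pairs$ssim) < 1e-14) {
    an <- tibble::tibble(F = 0, p = 1)
  } else {
    fit <- stats::aov(ssim ~ group, data = pairs)
    s <- summary(fit)[[1]]
    an <- tibble::tibble(F = s[["F value"]][1], p = s[["Pr(>F)"]][1])
  }
  structure(list(pairs = pairs, anova = an), class = "ssim_comparison")
}

#' @export
print.ssim_comparison <- function(x, ...) {
  med <- tapply(x$pairs$ssim, x$pairs$group, stats::median)
  cat("<ssim_comparison> medians:",
      paste(sprintf("%s %.3f", names(med), med), collapse = ", "), "\n")
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.3g\n",
              x$anova$F, x$anova$p))
  invisible(x)
}

#' Histogram statistics of a volume
#'
#' Fixed-bin-width histogram (bins anchored at integer multiples of
#' `bin_width`) plus mean, skewness and excess kurtosis of the raw voxel
#' values.
#'
#' @param vol a [volume3d()] or array.
#' @param bin_width histogram bin width in grey-value units.
#' @return object of class `volume_histogram`: `mids`, `counts`, `density`
#'   (probability per bin), `bin_width`, `mean`, `skew`, `kurtosis_excess`.
#' @export
histogram_stats <- function(vol, bin_width = 0.001) {
  stopifnot(bin_width > 0)
  x <- as.vector(as_vol_array(vol))
  lo <- floor(min(x) / bin_width)
  hi <- ceiling(max(x) / bin_width + 1e-9)
  if (hi == lo) hi <- lo + 1
  breaks <- seq(lo, hi) * bin_width
  counts <- tabulate(pmin(pmax(floor(x / bin_width) - lo + 1, 1), hi - lo),
                     nbins = hi - lo)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  structure(list(mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, density = counts / sum(counts),
                 bin_width = bin_width, first_bin = lo,
                 mean = m,
                 skew = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0,
                 kurtosis_excess = if (m2 > 0) mean((x - m)^4) / m2^2 - 3
                                   else 0),
            class = "volume_histogram")
}

#' Histogram intersection (percentage)
#'
#' `100 * sum min(p_A, p_B)` over the shared binning grid of the two
#' normalised histograms; 100 for identical volumes, 0 for disjoint
#' supports. The histograms must share bin width and bin alignment.
#'
#' @param hA,hB `volume_histogram` objects.
#' @return intersection percentage.
#' @export
histogram_intersection <- function(hA, hB) {
  if (abs(hA$bin_width - hB$bin_width) > 1e-12 * hA$bin_width)
    stop("histograms use different bin widths", call. = FALSE)
  lo <- min(hA$first_bin, hB$first_bin)
  hi <- max(hA$first_bin + length(hA$counts),
            hB$first_bin + length(hB$counts))
  pa <- numeric(hi - lo); pb <- numeric(hi - lo)
  pa[hA$first_bin - lo + seq_along(hA$counts)] <- hA$density
  pb[hB$first_bin - lo + seq_along(hB$counts)] <- hB$density
  100 * sum(pmin(pa, pb))
}
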