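# Forward simulator: parallel-beam, effective-monochromatic scans of a
# phantom. Line integrals of mu and delta per projection, Fresnel free-space
# propagation to the detector, multiplicative beam profiles, Poisson +
# Gaussian detector noise, sub-frame accumulation, centered / half /
# quarter-annular geometries and reference-jar scans.

#' Beam model
#'
#' Effective monochromatic beam at `energy_keV` with propagation distance
#' `propagation_m` (the experimental hutch limits this to 3.5 m), photon
#' `flux` per pixel per sub-frame, an optional horizontal Gaussian intensity
#' profile and an optional per-row vertical profile (both multiplicative,
#' strictly positive).
#'
#' @param energy_keV effective photon energy, keV.
#' @param propagation_m sample-detector distance, m, in `[0, 3.5]`.
#' @param flux photons per pixel per sub-frame in the unattenuated beam.
#' @param horizontal_profile `NULL` or `list(amplitude, centre_px, sigma_px)`
#'   describing `1 + (amplitude - 1) * exp(-(x - centre)^2 / (2 sigma^2))`
#'   (so values stay positive for amplitude > 0).
#' @param vertical_profile `NULL` or a positive numeric vector recycled over
#'   detector rows.
#' @param read_noise_sd additive Gaussian read noise, counts.
#' @param dark_level constant dark offset, counts.
#' @return object of class `beam_model` with derived `wavelength_m`.
#' @export
beam_model <- function(energy_keV = 85, propagation_m = 1, flux = 2e4,
                       horizontal_profile = NULL, vertical_profile = NULL,
                       read_noise_sd = 1, dark_level = 0) {
  if (propagation_m < 0 || propagation_m > 3.5)
    stop("propagation distance must lie in [0, 3.5] m", call. = FALSE)
  stopifnot(flux > 0, read_noise_sd >= 0)
  if (!is.null(vertical_profile) && any(vertical_profile <= 0))
    stop("vertical profile must be strictly positive", call. = FALSE)
  structure(list(energy_keV = energy_keV,
                 wavelength_m = xray_wavelength(energy_keV),
                 propagation_m = propagation_m, flux = flux,
                 horizontal_profile = horizontal_profile,
                 vertical_profile = vertical_profile,
                 read_noise_sd = read_noise_sd, dark_level = dark_level),
            class = "beam_model")
}

#' Scan geometry
#'
#' @param mode `"centered"`, `"half"` (360 degrees, rotation centre shifted
#'   by `cor_offset_px` towards one detector edge) or `"quarter_annular"`.
#' @param detector_width,detector_height detector size, px.
#' @param pixel_size_um detector pixel size, µm.
#' @param n_projections number of projection angles.
#' @param angular_range degrees; 180 for centered, must be 360 for half.
#' @param cor_offset_px signed rotation-centre offset from the detector
#'   centre, px. Half mode requires `0 < cor_offset_px < detector_width/2`.
#' @param n_subframes detector accumulation sub-frames per projection.
#' @param vertical_step_mm,beam_height_mm vertical series parameters
#'   (`beam_height_mm >= vertical_step_mm`).
#' @param sample_offset_um lateral (x, y) offset of the rotation axis inside
#'   the phantom, µm, relative to the grid centre; used for off-axis local
#'   tomography of interior volumes of interest.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(mode = c("centered", "half", "quarter_annular"),
                          detector_width, detector_height,
                          pixel_size_um, n_projections,
                          angular_range = if (mode == "centered") 180 else 360,
                          cor_offset_px = 0, n_subframes = 1,
                          vertical_step_mm = 2.2, beam_height_mm = 2.6,
                          sample_offset_um = c(0, 0)) {
  mode <- match.arg(mode)
  if (mode %in% c("half", "quarter_annular")) {
    if (angular_range != 360)
      stop("half/quarter acquisition requires a 360 degree range",
           call. = FALSE)
    if (cor_offset_px <= 0 || cor_offset_px >= detector_width / 2)
      stop("half mode needs 0 < cor_offset_px < detector_width/2",
           call. = FALSE)
  }
  stopifnot(n_subframes >= 1, detector_width >= 2, detector_height >= 1,
            pixel_size_um > 0, n_projections >= 2)
  if (beam_height_mm < vertical_step_mm)
    stop("beam height below the vertical step leaves gaps", call. = FALSE)
  structure(list(mode = mode, detector_width = as.integer(detector_width),
                 detector_height = as.integer(detector_height),
                 pixel_size_um = pixel_size_um,
                 n_projections = as.integer(n_projections),
                 angular_range = angular_range,
                 cor_offset_px = cor_offset_px,
                 n_subframes = as.integer(n_subframes),
                 vertical_step_mm = vertical_step_mm,
                 beam_height_mm = beam_height_mm,
                 sample_offset_um = as.numeric(sample_offset_um)),
            class = "scan_geometry")
}

scan_angles <- function(geometry) {
  seq(0, geometry$angular_range, length.out = geometry$n_projections + 1L)[
    seq_len(geometry$n_projections)]
}

beam_h_profile <- function(beam, W) {
  hp <- beam$horizontal_profile
  if (is.null(hp)) return(rep(1, W))
  x <- seq_len(W)
  v <- 1 + (hp$amplitude - 1) * exp(-(x - hp$centre_px)^2 / (2 * hp$sigma_px^2))
  if (any(v <= 0)) stop("horizontal profile must stay positive", call. = FALSE)
  v
}

beam_v_profile <- function(beam, H) {
  vp <- beam$vertical_profile
  if (is.null(vp)) return(rep(1, H))
  rep_len(vp, H)
}

#' Line integrals of a phantom at one projection angle
#'
#' Computes, per detector pixel, the attenuation path integral
#' `A = integral mu ds` (dimensionless) and the phase
#' `Phi = -(2 pi / lambda) integral delta ds` for a parallel beam rotated
#' about the z axis. The rotation axis passes through the grid centre plus
#' `geometry$sample_offset_um`; detector columns are spaced
#' `pixel_size_um` with the rotation centre at column
#' `(W + 1)/2 + cor_offset_px`.
#'
#' @param phantom a `phantom`.
#' @param angle_deg projection angle, degrees.
#' @param geometry a [scan_geometry()].
#' @param beam a [beam_model()] (supplies the wavelength for Phi).
#' @param slice_range integer z-slice indices imaged onto detector rows;
#'   defaults to `detector_height` central slices.
#' @param step_voxel ray sampling step in voxel units.
#' @return list with matrices `A`, `Phi` (rows = detector rows, cols =
#'   detector columns) and logical `truncated` (object extends beyond the
#'   lateral field of view; expected for local tomography).
#' @export
forward_project <- function(phantom, angle_deg, geometry, beam,
                            slice_range = NULL, step_voxel = 0.5) {
  vol_mu <- phantom_property_volume(phantom, "mu")
  vol_de <- phantom_property_volume(phantom, "delta")
  fp_project(vol_mu, vol_de, angle_deg, geometry, beam, slice_range,
             step_voxel)
}

# internal worker taking precomputed property volumes (avoids re-deriving
# them for every angle of a scan)
fp_project <- function(vol_mu, vol_de, angle_deg, geometry, beam,
                       slice_range = NULL, step_voxel = 0.5) {
  d <- dim(vol_mu$data)
  vx <- vol_mu$voxel_size
  if (is.null(slice_range)) {
    mid <- (d[3] + 1) / 2
    h <- geometry$detector_height
    slice_range <- round(mid - (h - 1) / 2) + seq_len(h) - 1L
  }
  if (any(slice_range < 1 | slice_range > d[3]))
    stop("slice_range outside the phantom grid", call. = FALSE)
  W <- geometry$detector_width
  px_vox <- geometry$pixel_size_um / vx
  cor_col <- (W + 1) / 2 + geometry$cor_offset_px
  tvals <- (seq_len(W) - cor_col) * px_vox     # voxel units
  cx <- (d[1] + 1) / 2 + geometry$sample_offset_um[1] / vx
  cy <- (d[2] + 1) / 2 + geometry$sample_offset_um[2] / vx
  th <- angle_deg * pi / 180
  nr <- length(slice_range)
  A <- matrix(0, nr, W); Phi <- matrix(0, nr, W)
  need_phi <- beam$propagation_m > 0
  for (i in seq_len(nr)) {
    mu_sl <- vol_mu$data[, , slice_range[i]]
    pa <- radon_cpp(mu_sl, th, tvals, cx, cy, step_voxel)
    A[i, ] <- pa[1, ] * vx * 1e-3             # mu in 1/mm, path in mm
    if (need_phi) {                           # contact plane needs no phase
      de_sl <- vol_de$data[, , slice_range[i]]
      pd <- radon_cpp(de_sl, th, tvals, cx, cy, step_voxel)
      Phi[i, ] <- -(2 * pi / beam$wavelength_m) * pd[1, ] * vx * 1e-6
    }
  }
  truncated <- any(A[, 1] > 1e-6) || any(A[, W] > 1e-6)
  list(A = A, Phi = Phi, truncated = truncated)
}

#' Fresnel free-space propagation to the detector plane
#'
#' Propagates the exit wave `exp(-A/2 + i Phi)` over distance `D` with the
#' Fresnel transfer function `H = exp(-i pi lambda D (u^2 + v^2))`
#' (`u`, `v` in cycles per metre) and returns the detector intensity
#' `I = |F^-1[F[psi] H]|^2`. `D = 0` returns `exp(-A)` exactly. The field is
#' edge-padded symmetrically before the FFT to suppress wrap-around.
#'
#' @param A,Phi matrices from [forward_project()].
#' @param wavelength_m beam wavelength, m.
#' @param D_m propagation distance, m.
#' @param pixel_size_um detector pixel size, µm.
#' @param pad_frac padding per edge as a fraction of each dimension
#'   (default 1/4; 0 gives a plain periodic transform).
#' @return intensity matrix of the same size as `A`.
#' @export
fresnel_propagate <- function(A, Phi, wavelength_m, D_m, pixel_size_um,
                              pad_frac = 0.25) {
  if (D_m < 0) stop("propagation distance must be >= 0", call. = FALSE)
  if (D_m == 0) return(exp(-A))
  px_m <- pixel_size_um * 1e-6
  if (wavelength_m * D_m > px_m^2 * max(dim(A)))
    warning("propagation beyond the near-field validity of the sampling")
  pad <- ceiling(pad_frac * dim(A))
  psi <- exp(-A / 2 + 1i * Phi)
  psi_p <- pad_edge(psi, pad)
  dp <- dim(psi_p)
  u <- fft_freq(dp[1], px_m)
  v <- fft_freq(dp[2], px_m)
  H <- exp(-1i * pi * wavelength_m * D_m * outer(u^2, v^2, "+"))
  out <- stats::fft(stats::fft(psi_p) * H, inverse = TRUE) / prod(dp)
  I <- Mod(out)^2
  unpad_edge(I, pad, dim(A))
}

# frequency axis in cycles per unit (fftfreq convention)
fft_freq <- function(n, d) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * d)
}

# symmetric (replicate-edge) padding of a matrix
pad_edge <- function(m, pad) {
  i <- c(rep(1L, pad[1]), seq_len(nrow(m)), rep(nrow(m), pad[1]))
  j <- c(rep(1L, pad[2]), seq_len(ncol(m)), rep(ncol(m), pad[2]))
  m[i, j, drop = FALSE]
}

unpad_edge <- function(m, pad, dims) {
  m[pad[1] + seq_len(dims[1]), pad[2] + seq_len(dims[2]), drop = FALSE]
}

#' Apply beam profiles and detector noise to an intensity pattern
#'
#' Counts are `Poisson(flux * I * h(x) * v(y) * g(x))` plus Gaussian read
#' noise and the dark level, where `h` is the horizontal Gaussian beam
#' profile, `v` the vertical profile and `g` an optional fixed per-column
#' gain-error field (the driver of ring artefacts). Deterministic given
#' `seed`; with `noise = FALSE` the expectation is returned.
#'
#' @param I intensity matrix (rows = detector rows).
#' @param beam a [beam_model()].
#' @param seed RNG seed.
#' @param gain_error `NULL` or per-column multiplicative gains.
#' @param noise logical; disable to get the noise-free expectation.
#' @return matrix of detector counts.
#' @export
apply_beam_and_noise <- function(I, beam, seed = NULL, gain_error = NULL,
                                 noise = TRUE) {
  h <- beam_h_profile(beam, ncol(I))
  v <- beam_v_profile(beam, nrow(I))
  expect <- beam$flux * I * outer(v, h)
  if (!is.null(gain_error))
    expect <- sweep(expect, 2, gain_error, "*")
  if (!noise) return(expect + beam$dark_level)
  with_seed(seed, {
    counts <- matrix(stats::rpois(length(expect), lambda = expect),
                     nrow(expect), ncol(expect))
    counts + beam$dark_level +
      matrix(stats::rnorm(length(expect), 0, beam$read_noise_sd),
             nrow(expect), ncol(expect))
  })
}

#' Simulate a complete scan
#'
#' Produces sample frames (with `n_subframes` accumulation sub-frames),
#' flats, darks and reference-jar frames on the same angular grid, emulating
#' the two-jar holder in which the reference container of mounting medium
#' rides above the sample and is scanned for flat-field references. The
#' reference phantom defaults to the jar-only twin of the sample and is
#' simulated in identical geometry with an independent noise stream.
#'
#' @param phantom sample `phantom`.
#' @param beam a [beam_model()].
#' @param geometry a [scan_geometry()].
#' @param seed RNG seed (all sub-streams derive from it).
#' @param reference_phantom `NULL` for the automatic jar twin, `FALSE` for
#'   no reference frames, or an explicit `phantom`.
#' @param noise logical.
#' @param slice_range z slices imaged (see [forward_project()]).
#' @param n_flats,n_darks number of flat/dark frames.
#' @param gain_error optional fixed per-column gain-error field.
#' @return object of class `projection_set`: frames
#'   `[row, col, angle, subframe]`, `angles`, `flats`, `darks`,
#'   `reference_frames` `[row, col, angle]` (sub-frame averaged) or `NULL`,
#'   `geometry`, `beam`, `truncated` per angle.
#' @export
simulate_scan <- function(phantom, beam, geometry, seed = NULL,
                          reference_phantom = NULL, noise = TRUE,
                          slice_range = NULL, n_flats = 8, n_darks = 8,
                          gain_error = NULL) {
  angles <- scan_angles(geometry)
  W <- geometry$detector_width
  vol_mu <- phantom_property_volume(phantom, "mu")
  vol_de <- if (beam$propagation_m > 0)
    phantom_property_volume(phantom, "delta") else vol_mu
  nr <- if (is.null(slice_range)) geometry$detector_height
        else length(slice_range)
  seeds <- if (is.null(seed)) rep(list(NULL), 4)
           else as.list(seed * 8L + 0:3)
  frames <- array(0, c(nr, W, length(angles), geometry$n_subframes))
  truncated <- logical(length(angles))
  for (a in seq_along(angles)) {
    pr <- fp_project(vol_mu, vol_de, angles[a], geometry, beam, slice_range)
    I <- fresnel_propagate(pr$A, pr$Phi, beam$wavelength_m,
                           beam$propagation_m, geometry$pixel_size_um)
    truncated[a] <- pr$truncated
    for (s in seq_len(geometry$n_subframes)) {
      sub_seed <- if (is.null(seeds[[1]])) NULL
                  else (seeds[[1]] + 7L * (a * geometry$n_subframes + s)) %% 2147483647L
      frames[, , a, s] <- apply_beam_and_noise(I, beam, sub_seed,
                                               gain_error, noise)
    }
  }
  flat_I <- matrix(1, nr, W)
  flats <- array(0, c(nr, W, n_flats))
  for (k in seq_len(n_flats)) {
    fs <- if (is.null(seeds[[2]])) NULL else (seeds[[2]] + 13L * k) %% 2147483647L
    flats[, , k] <- apply_beam_and_noise(flat_I, beam, fs, gain_error, noise)
  }
  darks <- array(0, c(nr, W, n_darks))
  if (noise) {
    darks[] <- with_seed(seeds[[3]],
      stats::rnorm(length(darks), beam$dark_level, beam$read_noise_sd))
  } else {
    darks[] <- beam$dark_level
  }
  reference_frames <- NULL
  if (!isFALSE(reference_phantom)) {
    ref <- if (is.null(reference_phantom)) reference_twin(phantom)
           else reference_phantom
    ref_mu <- phantom_property_volume(ref, "mu")
    ref_de <- if (beam$propagation_m > 0)
      phantom_property_volume(ref, "delta") else ref_mu
    reference_frames <- array(0, c(nr, W, length(angles)))
    for (a in seq_along(angles)) {
      pr <- fp_project(ref_mu, ref_de, angles[a], geometry, beam, slice_range)
      I <- fresnel_propagate(pr$A, pr$Phi, beam$wavelength_m,
                             beam$propagation_m, geometry$pixel_size_um)
      acc <- 0
      for (s in seq_len(geometry$n_subframes)) {
        rs <- if (is.null(seeds[[4]])) NULL
              else (seeds[[4]] + 11L * (a * geometry$n_subframes + s)) %% 2147483647L
        acc <- acc + apply_beam_and_noise(I, beam, rs, gain_error, noise)
      }
      reference_frames[, , a] <- acc / geometry$n_subframes
    }
  }
  structure(list(frames = frames, angles = angles, flats = flats,
                 darks = darks, reference_frames = reference_frames,
                 geometry = geometry, beam = beam, truncated = truncated,
                 seed = seed),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<projection_set> %d rows x %d cols, %d angles (%s, %g deg), %d subframe(s)\n",
    d[1], d[2], d[3], x$geometry$mode, x$geometry$angular_range, d[4]))
  cat(sprintf("  reference frames: %s; truncated projections: %d/%d\n",
              if (is.null(x$reference_frames)) "none" else "yes",
              sum(x$truncated), d[3]))
  invisible(x)
}

#' Plan a vertical scan series
#'
#' Greedy coverage of the organ height by beam-height windows advanced in
#' steps of `step_mm`, with the overlap between consecutive windows reported
#' as a percentage of the step (`100 (beam - step) / step`, rounded to the
#' nearest integer).
#'
#' @param organ_height_mm organ extent to cover, mm.
#' @param beam_height_mm vertical beam size, mm.
#' @param step_mm vertical sampling step, mm (must not exceed the beam
#'   height, else coverage has gaps).
#' @return list with `z_positions_mm` (window starts) and
#'   `overlap_percent`.
#' @export
plan_vertical_series <- function(organ_height_mm, beam_height_mm, step_mm) {
  if (step_mm <= 0 || beam_height_mm <= 0)
    stop("step and beam height must be positive", call. = FALSE)
  if (step_mm > beam_height_mm)
    stop("step larger than the beam height leaves vertical gaps",
         call. = FALSE)
  if (beam_height_mm > organ_height_mm)
    stop("beam height exceeds the organ height", call. = FALSE)
  n <- ceiling((organ_height_mm - beam_height_mm) / step_mm) + 1
  list(z_positions_mm = step_mm * (seq_len(n) - 1),
       overlap_percent = round(100 * (beam_height_mm - step_mm) / step_mm))
}
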