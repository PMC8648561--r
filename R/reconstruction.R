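# Reconstruction chain: accumulation, reference flat-fielding with angular
# windows, vertical-profile residual subtraction, single-distance phase
# retrieval + unsharp mask, extended-FOV sinogram assembly, filtered
# back-projection, local (truncated) reconstruction, ponderate vertical
# concatenation, 16-bit conversion and ring/stripe artefact correction.

#' Sinogram container
#'
#' Per-slice projection data ready for filtered back-projection:
#' `data[angle, column, slice]`, strictly increasing `angles` (degrees), the
#' rotation-centre column after assembly, the detector pixel size and an
#' append-only provenance record of applied corrections.
#'
#' @param data numeric array `[angle, column, slice]` (a matrix is promoted
#'   to one slice).
#' @param angles projection angles, degrees, strictly increasing.
#' @param pixel_size_um detector pixel size, µm.
#' @param cor_column rotation-centre column (may be fractional).
#' @param provenance character vector of applied processing steps.
#' @return object of class `sinogram`.
#' @export
sinogram <- function(data, angles, pixel_size_um,
                     cor_column = (dim(data)[2] + 1) / 2,
                     provenance = character()) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(angles))
  if (any(diff(angles) <= 0))
    stop("angles must be strictly increasing", call. = FALSE)
  structure(list(data = data, angles = angles,
                 pixel_size_um = pixel_size_um, cor_column = cor_column,
                 provenance = provenance),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram> %d angles x %d columns x %d slice(s), cor %.1f\n",
              d[1], d[2], d[3], x$cor_column))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

add_provenance <- function(obj, step) {
  obj$provenance <- c(obj$provenance, step)
  obj
}

#' Accumulate detector sub-frames
#'
#' Arithmetic mean of the sub-frames (keeping the grey scale independent of
#' the accumulation count). Pixels reaching `full_well` in any sub-frame are
#' flagged as saturated and their value comes from the remaining sub-frames
#' only.
#'
#' @param subframes array `[row, col, subframe]` or list of matrices.
#' @param full_well saturation threshold in counts (default `Inf`).
#' @return list with `frame` (mean) and `saturated` (logical matrix).
#' @export
accumulate <- function(subframes, full_well = Inf) {
  if (is.list(subframes)) {
    if (length(subframes) < 1)
      stop("need at least one sub-frame", call. = FALSE)
    subframes <- array(unlist(subframes),
                       c(dim(subframes[[1]]), length(subframes)))
  }
  if (length(dim(subframes)) == 2L)
    dim(subframes) <- c(dim(subframes), 1L)
  if (dim(subframes)[3] < 1) stop("no sub-frames", call. = FALSE)
  sat <- subframes >= full_well
  any_sat <- apply(sat, c(1, 2), any)
  good <- !sat
  n_good <- apply(good, c(1, 2), sum)
  ssum <- apply(subframes * good, c(1, 2), sum)
  frame <- ifelse(n_good > 0, ssum / pmax(n_good, 1),
                  apply(subframes, c(1, 2), mean))
  list(frame = frame, saturated = any_sat)
}

accumulate_pset <- function(pset, full_well = Inf) {
  d <- dim(pset$frames)
  out <- array(0, d[1:3])
  for (a in seq_len(d[3])) {
    sub <- array(pset$frames[, , a, ], c(d[1], d[2], d[4]))
    out[, , a] <- accumulate(sub, full_well)$frame
  }
  out
}

#' Reference-jar flat-field correction
#'
#' Normalises each projection by an angularly local average of the
#' reference-jar frames: for projection `i` the reference is the mean of the
#' reference frames inside a window of `window` projections centred on `i`
#' (clamped at the scan ends, since the window tracks the beam in time),
#' or — with `mode = "piecewise"` — the mean
#' over the block of `window` projections containing `i`. Output is
#' `(I - dark) / (R_i - dark)`. Because the reference jar mimics the bulk
#' absorption of the mounted sample, this directly removes most of the
#' low-frequency background of off-centre local tomography.
#'
#' @param projections array `[row, col, angle]` of accumulated frames.
#' @param reference_frames array `[row, col, angle]` on the same grid.
#' @param darks dark frames (`[row, col, k]` array or matrix), averaged.
#' @param window angular window width in projections (default 100).
#' @param mode `"centred"` (sliding window) or `"piecewise"` (reference
#'   updated every `window` projections).
#' @return normalised projection array `[row, col, angle]`.
#' @export
reference_flatfield <- function(projections, reference_frames, darks,
                                window = 100, mode = c("centred",
                                                       "piecewise")) {
  mode <- match.arg(mode)
  d <- dim(projections)
  stopifnot(identical(dim(reference_frames), d))
  dark <- if (length(dim(darks)) == 3L) apply(darks, c(1, 2), mean)
          else darks
  na <- d[3]
  window <- min(window, na)
  M <- matrix(reference_frames, d[1] * d[2], na)
  if (mode == "centred") {
    # centred window, clamped (not wrapped) at the scan ends: the window
    # tracks the beam in time, and the first and last projections are the
    # furthest apart in time even though they coincide in angle
    w2 <- floor(window / 2)
    R <- matrix(0, d[1] * d[2], na)
    for (i in seq_len(na)) {
      lo <- max(1L, i - w2)
      hi <- min(na, lo + window - 1L)
      lo <- max(1L, hi - window + 1L)
      R[, i] <- rowMeans(M[, lo:hi, drop = FALSE])
    }
  } else {
    blk <- ((seq_len(na) - 1) %/% window)
    R <- matrix(0, d[1] * d[2], na)
    for (b in unique(blk)) {
      cols <- which(blk == b)
      R[, cols] <- rowMeans(M[, cols, drop = FALSE])
    }
  }
  R <- array(R, d)
  denom <- R - as.vector(dark)
  if (any(denom <= 0))
    stop("reference minus dark is non-positive; flat-fielding undefined",
         call. = FALSE)
  (projections - as.vector(dark)) / denom
}

#' Classical flat-field correction
#'
#' `(I - dark) / (flat - dark)` with the time-averaged empty-beam flat;
#' the baseline the reference-jar scheme is compared against.
#'
#' @param projections array `[row, col, angle]`.
#' @param flats array `[row, col, k]` of empty-beam frames.
#' @param darks dark frames, averaged.
#' @return normalised projection array.
#' @export
classical_flatfield <- function(projections, flats, darks) {
  flat <- apply(flats, c(1, 2), mean)
  dark <- if (length(dim(darks)) == 3L) apply(darks, c(1, 2), mean)
          else darks
  denom <- flat - dark
  if (any(denom <= 0))
    stop("flat minus dark is non-positive", call. = FALSE)
  sweep(sweep(projections, c(1, 2), dark, "-"), c(1, 2), denom, "/")
}

#' Subtract the residual vertical beam profile
#'
#' Attenuation-dominated scans keep a residual vertical profile of the beam
#' after flat-fielding which prints as regular horizontal lines in the
#' reconstruction. The per-detector-row median over all angles and columns
#' of the log-domain projections (optionally smoothed along rows) is
#' subtracted from every projection row; the global mean of the set is
#' preserved.
#'
#' @param logproj array `[row, col, angle]` of log-domain projections.
#' @param smooth_span odd running-mean span over rows applied to the row
#'   medians (1 = no smoothing).
#' @return corrected array of the same shape.
#' @export
subtract_vertical_residual <- function(logproj, smooth_span = 1) {
  d <- dim(logproj)
  v <- vapply(seq_len(d[1]), function(r) stats::median(logproj[r, , ]),
              numeric(1))
  if (smooth_span > 1) v <- running_mean(v, smooth_span)
  corr <- v - mean(v)
  sweep(logproj, 1, corr, "-")
}

running_mean <- function(x, span) {
  r <- (span - 1) %/% 2
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  as.vector(stats::filter(xp, rep(1 / span, span), sides = 2))[
    r + seq_along(x)]
}

running_median <- function(x, span) {
  r <- (span - 1) %/% 2
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  vapply(seq_along(x), function(i) stats::median(xp[i:(i + 2 * r)]),
         numeric(1))
}

#' Single-distance phase-retrieval parameters
#'
#' @param delta_beta homogeneous-object delta/beta ratio (> 0).
#' @param propagation_m propagation distance, m.
#' @param energy_keV effective energy (sets the wavelength).
#' @param pixel_size_um detector pixel size, µm.
#' @param unsharp_sigma,unsharp_amount 2D unsharp-mask defaults applied on
#'   retrieved projections by the pipeline.
#' @return object of class `retrieval_params`.
#' @export
retrieval_params <- function(delta_beta = 1000, propagation_m = 1,
                             energy_keV = 85, pixel_size_um = 25,
                             unsharp_sigma = 2, unsharp_amount = 1) {
  stopifnot(delta_beta > 0, unsharp_amount >= 0, unsharp_sigma > 0)
  structure(list(delta_beta = delta_beta, propagation_m = propagation_m,
                 wavelength_m = xray_wavelength(energy_keV),
                 pixel_size_um = pixel_size_um,
                 unsharp_sigma = unsharp_sigma,
                 unsharp_amount = unsharp_amount),
            class = "retrieval_params")
}

#' Single-distance (homogeneous-object) phase retrieval
#'
#' Applies the low-pass retrieval filter to a flat-fielded propagation image
#' and returns the thickness-like map
#' `t = -ln( F^-1[ F[I] / (1 + pi lambda D (delta/beta) (u^2 + v^2)) ] )`
#' with `u, v` in cycles per metre. `D = 0` (or a vanishing delta/beta)
#' reduces exactly to `-ln I`. The image is edge-padded before the FFT;
#' non-positive filter output is clipped at `eps` and counted in the
#' `"clipped"` attribute.
#'
#' @param I flat-fielded projection matrix, strictly positive.
#' @param params a [retrieval_params()].
#' @param pad_frac edge padding fraction per side (0 = periodic transform).
#' @param eps clipping floor for the logarithm argument.
#' @return thickness-like matrix, same size as `I`.
#' @export
paganin_retrieve <- function(I, params, pad_frac = 0.25, eps = 1e-8) {
  if (any(I <= 0))
    stop("flat-fielded intensity must be strictly positive", call. = FALSE)
  D <- params$propagation_m
  if (D == 0) return(-log(I))
  px_m <- params$pixel_size_um * 1e-6
  pad <- ceiling(pad_frac * dim(I))
  Ip <- pad_edge(I, pad)
  dp <- dim(Ip)
  u <- fft_freq(dp[1], px_m)
  v <- fft_freq(dp[2], px_m)
  denom <- 1 + pi * params$wavelength_m * D * params$delta_beta *
    outer(u^2, v^2, "+")
  sm <- Re(stats::fft(stats::fft(Ip) / denom, inverse = TRUE) / prod(dp))
  sm <- unpad_edge(sm, pad, dim(I))
  n_clip <- sum(sm <= 0)
  if (n_clip > 0) {
    warning(sprintf("%d non-positive pixels clipped before log", n_clip))
    sm[sm <= 0] <- eps
  }
  out <- -log(sm)
  attr(out, "clipped") <- n_clip
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

conv1d_replicate <- function(x, k) {
  r <- (length(k) - 1) %/% 2
  xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
  as.vector(stats::filter(xp, k, sides = 2))[r + seq_along(x)]
}

gauss_blur2d <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  m <- apply(m, 2, conv1d_replicate, k = k)
  t(apply(m, 1, conv1d_replicate, k = k))
}

#' 2D unsharp mask
#'
#' `out = map + amount * (map - G_sigma * map)` with a replicate-edge
#' Gaussian blur; `amount = 0` is the identity and a constant map is
#' unchanged.
#'
#' @param map numeric matrix.
#' @param sigma Gaussian blur sigma, px (> 0).
#' @param amount overshoot amount (>= 0).
#' @return sharpened matrix.
#' @export
unsharp_mask <- function(map, sigma = 2, amount = 1) {
  stopifnot(sigma > 0, amount >= 0)
  if (amount == 0) return(map)
  map + amount * (map - gauss_blur2d(map, sigma))
}

#' Assemble an extended-FOV sinogram from a half-acquisition scan
#'
#' A 360-degree scan with the rotation centre moved `cor_offset_px` columns
#' off the detector centre covers each lateral position twice: once at angle
#' `theta` and once mirrored at `theta + 180`. Each output row concatenates
#' the two, blending the doubly-covered band (width `W - 2 o`) with linear
#' ramp weights that sum to one, yielding an effective width `W + 2 o` over
#' 180 degrees.
#'
#' @param sino a [sinogram()] spanning 360 degrees with
#'   `cor_column = (W + 1)/2 + o`.
#' @param cor_offset_px the offset `o` in pixels (integer,
#'   `0 <= o < W/2`); `o = 0` degenerates to averaging the two half-turns.
#' @return a [sinogram()] of width `W + 2 o` spanning 180 degrees with
#'   `cor_column` at its centre.
#' @export
build_half_sinogram <- function(sino, cor_offset_px) {
  o <- as.integer(round(cor_offset_px))
  d <- dim(sino$data)
  W <- d[2]
  if (o < 0 || o >= W / 2)
    stop("need 0 <= cor_offset_px < detector_width / 2", call. = FALSE)
  na <- d[1]
  if (na %% 2 != 0)
    stop("360-degree scan must have an even number of projections",
         call. = FALSE)
  if (max(sino$angles) < 340)
    stop("half-acquisition stitching needs a 360-degree scan", call. = FALSE)
  nh <- na %/% 2
  Wo <- W + 2L * o
  out <- array(0, c(nh, Wo, d[3]))
  ov_cols <- (2L * o + 1L):W                 # overlap band in output columns
  q <- length(ov_cols)
  w_a <- if (q == 1) 0.5 else (W - ov_cols) / (W - (2 * o + 1))
  if (o == 0) w_a <- rep(0.5, q)             # degenerate: plain average
  for (s in seq_len(d[3])) {
    for (a in seq_len(nh)) {
      row_a <- sino$data[a, , s]
      row_b <- rev(sino$data[a + nh, , s])
      out_row <- numeric(Wo)
      out_row[seq_len(W)] <- row_a
      out_row[(2L * o + 1L):(W + 2L * o)] <- row_b
      out_row[ov_cols] <- w_a * row_a[ov_cols] +
        (1 - w_a) * row_b[ov_cols - 2L * o]
      out[a, , s] <- out_row
    }
  }
  sinogram(out, sino$angles[seq_len(nh)], sino$pixel_size_um,
           cor_column = (Wo + 1) / 2,
           provenance = c(sino$provenance,
                          sprintf("half_stitch(o=%d)", o)))
}

#' Concatenate a central and an annular sinogram (quarter acquisition)
#'
#' Extends the field of view beyond half acquisition: the annular scan's
#' grey levels are first normalised by the ratio of means in the common
#' (overlap) bands, then the two sinograms are blended with a linear
#' transition across each overlap band.
#'
#' @param inner the central (already half-stitched) [sinogram()].
#' @param outer_sino a wider [sinogram()] on the same angular grid whose
#'   outer bands are valid; both must share `cor_column` alignment (the
#'   inner sinogram sits centred inside the outer one).
#' @param overlap_px width of the calibration/blend band at each edge of
#'   the inner sinogram, px (> 0).
#' @return a [sinogram()] of the outer width; provenance records the gain.
#' @export
stitch_quarter <- function(inner, outer_sino, overlap_px) {
  di <- dim(inner$data); do <- dim(outer_sino$data)
  if (do[2] <= di[2])
    stop("outer sinogram must be wider than the inner one", call. = FALSE)
  if (di[1] != do[1] || di[3] != do[3])
    stop("sinograms must share angles and slices", call. = FALSE)
  overlap_px <- as.integer(overlap_px)
  if (overlap_px < 1) stop("empty overlap band", call. = FALSE)
  off <- (do[2] - di[2]) %/% 2               # inner cols offset inside outer
  in_cols <- off + seq_len(di[2])
  left_ov <- seq_len(overlap_px)                      # inner-local indices
  right_ov <- di[2] - overlap_px + seq_len(overlap_px)
  ov_inner <- c(inner$data[, left_ov, , drop = FALSE],
                inner$data[, right_ov, , drop = FALSE])
  ov_outer <- c(outer_sino$data[, in_cols[left_ov], , drop = FALSE],
                outer_sino$data[, in_cols[right_ov], , drop = FALSE])
  gain <- mean(ov_inner) / mean(ov_outer)
  if (gain < 0.5 || gain > 2)
    warning(sprintf("grey-level gain %.3f outside [0.5, 2]", gain))
  out <- outer_sino$data * gain
  # paste the inner sinogram, ramping across the overlap bands
  w <- rep(1, di[2])
  w[left_ov] <- (left_ov - 1) / overlap_px            # 0 -> outer at edge
  w[right_ov] <- rev(left_ov - 1) / overlap_px
  for (s in seq_len(di[3]))
    out[, in_cols, s] <- t(w * t(inner$data[, , s])) +
      t((1 - w) * t(out[, in_cols, s]))
  sinogram(out, outer_sino$angles, outer_sino$pixel_size_um,
           cor_column = outer_sino$cor_column,
           provenance = c(inner$provenance,
                          sprintf("quarter_stitch(gain=%.4f)", gain)))
}

ramp_filter_response <- function(np, dt, window = c("hann", "ramp")) {
  window <- match.arg(window)
  # discrete ramp kernel (Kak & Slaney), wrap-around layout
  n <- c(0:(np / 2), (-(np / 2 - 1)):-1)
  h <- numeric(np)
  h[n == 0] <- 1 / (4 * dt^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2 * dt^2)
  H <- Re(stats::fft(h))
  if (window == "hann") {
    f <- fft_freq(np, 1)                      # cycles/sample in [-0.5, 0.5)
    H <- H * (0.5 * (1 + cos(2 * pi * f)))
  }
  H
}

#' Filtered back-projection
#'
#' Standard parallel-beam FBP with a ramp filter (Hann-apodised by default)
#' and linear interpolation, reconstructing about the sinogram's rotation
#' centre. Output grey levels are in attenuation units of 1/mm when the
#' sinogram holds dimensionless path integrals (`mu` in 1/mm times path in
#' mm).
#'
#' @param sino a [sinogram()] spanning approximately 180 degrees.
#' @param filter `"hann"` or `"ramp"`.
#' @param output_size reconstructed slice size in px (default: sinogram
#'   width).
#' @param circle zero the region outside the inscribed field-of-view
#'   circle, which the projections do not determine (default `TRUE`).
#' @return a [volume3d()] (one slice per sinogram slice) with voxel size
#'   equal to the detector pixel size; provenance is carried in the
#'   `"provenance"` attribute.
#' @export
fbp <- function(sino, filter = c("hann", "ramp"), output_size = NULL,
                circle = TRUE) {
  filter <- match.arg(filter)
  d <- dim(sino$data)
  if (d[1] < 2) stop("need at least 2 angles", call. = FALSE)
  span <- max(sino$angles) - min(sino$angles)
  span <- span * d[1] / (d[1] - 1)           # closed span of the sampling
  if (span < 170)
    stop("angular span below 170 degrees cannot be reconstructed",
         call. = FALSE)
  n <- if (is.null(output_size)) d[2] else as.integer(output_size)
  dt <- sino$pixel_size_um
  np <- 2^ceiling(log2(2 * d[2]))
  H <- ramp_filter_response(np, dt, filter)
  th <- sino$angles * pi / 180
  dth <- span / d[1] * pi / 180
  out <- array(0, c(n, n, d[3]))
  for (s in seq_len(d[3])) {
    P <- sino$data[, , s]
    Pp <- matrix(0, d[1], np)
    Pp[, seq_len(d[2])] <- P
    Q <- t(apply(Pp, 1, function(row)
      Re(stats::fft(stats::fft(row) * H, inverse = TRUE) / np)))
    Q <- Q[, seq_len(d[2]), drop = FALSE] * dt
    cx <- (n + 1) / 2
    sl <- backproject_cpp(Q, th, sino$cor_column, n, n, cx, cx, 1)
    out[, , s] <- sl * dth * 1e3             # 1/um -> 1/mm
  }
  if (circle) {
    cx <- (n + 1) / 2
    r2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")
    disc <- r2 <= (min(n, d[2]) / 2)^2
    for (s in seq_len(d[3])) out[, , s] <- out[, , s] * disc
  }
  vol <- volume3d(out, dt)
  attr(vol, "provenance") <- c(sino$provenance, sprintf("fbp(%s)", filter))
  vol
}

#' Local-tomography reconstruction of truncated projections
#'
#' For interior (zoom) scans the sinogram is laterally truncated. Before
#' filtering, each row is extended by a smooth cosine decay of the edge
#' value over `pad_px` columns (default a quarter of the width) — a
#' conservative padding on top of the reference flat-fielding that carries
#' most of the correction — and the reconstruction is restricted to the
#' field-of-view disc.
#'
#' @param sino a [sinogram()] (reference-flat-fielded, log domain).
#' @param pad_px extrapolation width per side, px.
#' @param filter FBP filter window.
#' @return a [volume3d()] slice restricted to the FOV disc (outside = 0).
#' @export
reconstruct_local <- function(sino, pad_px = NULL,
                              filter = c("hann", "ramp")) {
  filter <- match.arg(filter)
  d <- dim(sino$data)
  W <- d[2]
  if (is.null(pad_px)) pad_px <- ceiling(W / 4)
  taper <- 0.5 * (1 + cos(pi * seq_len(pad_px) / pad_px))
  ext <- array(0, c(d[1], W + 2 * pad_px, d[3]))
  for (s in seq_len(d[3])) {
    P <- sino$data[, , s]
    left <- P[, 1] %o% rev(taper)
    right <- P[, W] %o% taper
    ext[, , s] <- cbind(left, P, right)
  }
  es <- sinogram(ext, sino$angles, sino$pixel_size_um,
                 cor_column = sino$cor_column + pad_px,
                 provenance = c(sino$provenance,
                                sprintf("truncation_pad(%d)", pad_px)))
  vol <- fbp(es, filter, output_size = W)
  # mask to the FOV disc
  n <- dim(vol$data)[1]
  cx <- (n + 1) / 2
  r2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, "+")
  disc <- r2 <= (W / 2 - 1)^2
  for (s in seq_len(dim(vol$data)[3]))
    vol$data[, , s] <- vol$data[, , s] * disc
  attr(vol, "provenance") <- c(attr(vol, "provenance"), "fov_disc_mask")
  vol
}

#' Vertical concatenation with ponderate averaging
#'
#' Estimates an integer z-shift at every junction by cross-correlating the
#' nominally overlapping slices (search window `search` slices), then blends
#' the overlap with linear ("ponderate") weights summing to one. A
#' correlation peak below `min_cor` falls back to the nominal overlap with a
#' warning.
#'
#' @param subvolumes list of [volume3d()] with identical x/y dimensions.
#' @param overlaps integer vector (length `length(subvolumes) - 1`) of
#'   nominal overlap slices per junction.
#' @param search maximum |shift| explored, slices.
#' @param min_cor correlation threshold for accepting the estimated shift.
#' @return a [volume3d()]; attribute `"shifts"` records the per-junction
#'   estimated shifts.
#' @export
concat_vertical <- function(subvolumes, overlaps, search = 5,
                            min_cor = 0.5) {
  stopifnot(length(subvolumes) >= 1)
  if (length(subvolumes) == 1) return(subvolumes[[1]])
  stopifnot(length(overlaps) == length(subvolumes) - 1)
  acc <- subvolumes[[1]]$data
  shifts <- integer(0)
  for (k in seq_along(overlaps)) {
    B <- subvolumes[[k + 1]]$data
    ov <- overlaps[k]
    if (ov == 0) {
      acc <- array(c(acc, B), c(dim(acc)[1:2], dim(acc)[3] + dim(B)[3]))
      shifts <- c(shifts, 0L)
      next
    }
    nA <- dim(acc)[3]
    best_s <- 0L; best_c <- -Inf
    for (s in (-search):search) {
      p <- nA - ov + 1 + s                    # A-slice matching B slice 1
      jmax <- min(nA - p + 1, dim(B)[3], ov)
      if (p < 1 || jmax < 1) next
      a_v <- as.vector(acc[, , p:(p + jmax - 1)])
      b_v <- as.vector(B[, , seq_len(jmax)])
      if (stats::sd(a_v) == 0 || stats::sd(b_v) == 0) next
      cc <- stats::cor(a_v, b_v)
      if (cc > best_c) { best_c <- cc; best_s <- s }
    }
    if (best_c < min_cor) {
      warning("correlation peak below threshold; using nominal overlap")
      best_s <- 0L
    }
    shifts <- c(shifts, best_s)
    p <- nA - ov + 1 + best_s
    q <- nA - p + 1                           # realised overlap
    w_b <- seq_len(q) / (q + 1)
    blended <- array(0, c(dim(acc)[1:2], q))
    for (j in seq_len(q))
      blended[, , j] <- (1 - w_b[j]) * acc[, , p + j - 1] + w_b[j] * B[, , j]
    head_a <- if (p > 1) acc[, , seq_len(p - 1), drop = FALSE] else NULL
    tail_b <- if (q < dim(B)[3]) B[, , (q + 1):dim(B)[3], drop = FALSE]
              else NULL
    nz <- (p - 1) + q + (dim(B)[3] - q)
    acc <- array(c(head_a, blended, tail_b), c(dim(acc)[1:2], nz))
  }
  out <- volume3d(acc, subvolumes[[1]]$voxel_size, subvolumes[[1]]$origin)
  attr(out, "shifts") <- shifts
  out
}

#' Convert a float volume to 16-bit with a percentile window
#'
#' Maps the `[p_lo, p_hi]` percentile window linearly to `[0, 65535]`,
#' clipping outside; the affine scale is recorded so physical values are
#' recoverable. A constant volume maps to the midpoint 32768 (documented
#' convention).
#'
#' @param vol a float [volume3d()] with finite data.
#' @param probs percentile window, default `c(0.1, 99.9)` (percent).
#' @return a `uint16` [volume3d()] with `scale = c(offset, slope)`.
#' @export
to_uint16 <- function(vol, probs = c(0.1, 99.9)) {
  x <- vol$data
  if (any(!is.finite(x)))
    stop("volume contains non-finite values", call. = FALSE)
  qs <- stats::quantile(x, probs / 100, names = FALSE)
  lo <- qs[1]; hi <- qs[2]
  if (hi <= lo) {
    stored <- array(32768, dim(x))
    return(volume3d(stored, vol$voxel_size, vol$origin, "uint16",
                    scale = c(lo - 32768, 1)))
  }
  slope <- (hi - lo) / 65535
  stored <- round((x - lo) / slope)
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  volume3d(stored, vol$voxel_size, vol$origin, "uint16",
           scale = c(lo, slope))
}

#' Ring-artefact correction on a reconstructed slice
#'
#' Resamples the slice about the rotation centre on a polar grid, takes the
#' angular median per radius, splits off its low-frequency (genuine radial
#' structure) component with a running median, and subtracts the remaining
#' radial artefact profile — smoothed — from the slice. The slice mean is
#' preserved.
#'
#' @param slice numeric matrix.
#' @param cor rotation centre `c(x, y)` in pixels (default image centre).
#' @param background_span running-median span (px) separating genuine
#'   radial structure from ring artefacts.
#' @param profile_span optional running-mean span smoothing the artefact
#'   profile (1 = none; smoothing trades residual ring amplitude for
#'   robustness to noise in the angular median).
#' @param n_theta angular samples for the polar transform.
#' @return corrected matrix.
#' @export
remove_rings <- function(slice, cor = NULL, background_span = 25,
                         profile_span = 1, n_theta = NULL) {
  d <- dim(slice)
  if (is.null(cor)) cor <- (d + 1) / 2
  rmax <- floor(min(cor[1] - 1, d[1] - cor[1], cor[2] - 1, d[2] - cor[2]))
  # polar view without resampling blur: bin the pixels themselves by
  # radius (half-pixel bins) and take the angular median per radius bin
  rx <- sqrt(outer((seq_len(d[1]) - cor[1])^2,
                   (seq_len(d[2]) - cor[2])^2, "+"))
  step <- 0.5
  bin <- pmin(as.integer(round(rx / step)), as.integer(rmax / step)) + 1L
  inside <- rx <= rmax
  n_bins <- max(bin[inside])
  m <- rep(NA_real_, n_bins)
  med <- tapply(slice[inside], bin[inside], stats::median)
  m[as.integer(names(med))] <- med
  m[is.na(m)] <- stats::approx(which(!is.na(m)), m[!is.na(m)],
                               xout = which(is.na(m)), rule = 2)$y
  span <- min(2 * background_span + 1, n_bins)
  if (span %% 2 == 0) span <- span - 1
  bg0 <- running_median(m, span)
  # refine: flag ring bins, re-estimate the background by interpolating
  # the genuine radial structure across them (a curved background would
  # otherwise leak into the ring profile)
  dev <- m - bg0
  madev <- stats::median(abs(dev))
  ringbin <- abs(dev) > 3 * madev
  if (any(ringbin)) {
    ringbin <- ringbin |
      c(ringbin[-1], FALSE) | c(FALSE, ringbin[-n_bins]) |
      c(ringbin[-(1:2)], FALSE, FALSE) | c(FALSE, FALSE,
                                           ringbin[-((n_bins - 1):n_bins)])
  }
  bg <- m
  if (any(ringbin) && any(!ringbin))
    bg[ringbin] <- stats::approx(which(!ringbin), m[!ringbin],
                                 xout = which(ringbin), rule = 2)$y
  ring <- m - bg
  if (profile_span > 1) ring <- running_mean(ring, profile_span)
  radii <- (seq_len(n_bins) - 1L) * step
  corr <- matrix(stats::approx(radii, ring, xout = pmin(rx, max(radii)),
                               rule = 2)$y, d[1], d[2])
  corr[!inside] <- 0
  corr <- corr - mean(corr)
  slice - corr
}

bilinear_sample <- function(m, xs, ys) {
  d <- dim(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 < d[1] & y0 >= 1 & y0 < d[2]
  out <- rep(NA_real_, length(xs))
  i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
  i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
  out[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * m[i00] +
    fx[ok] * (1 - fy[ok]) * m[i10] +
    (1 - fx[ok]) * fy[ok] * m[i01] + fx[ok] * fy[ok] * m[i11]
  out
}

#' Horizontal-stripe correction on a reconstructed volume
#'
#' Removes constant-z plane offsets (horizontal stripes after vertical
#' reslicing): the per-slice mean profile along z is split into a
#' low-frequency trend (running median) and a stripe component, and the
#' stripe component is subtracted from each slice. Approximately idempotent.
#'
#' @param vol a [volume3d()] with at least 8 slices.
#' @param trend_span running-median span along z.
#' @return corrected [volume3d()].
#' @export
remove_stripes <- function(vol, trend_span = 9) {
  d <- dim(vol$data)
  if (d[3] < 8) stop("need at least 8 slices", call. = FALSE)
  m <- apply(vol$data, 3, mean)
  trend <- running_median(m, min(trend_span, d[3] - (1 - d[3] %% 2)))
  corr <- m - trend
  out <- vol
  out$data <- sweep(vol$data, 3, corr, "-")
  attr(out, "provenance") <- c(attr(vol, "provenance"), "remove_stripes")
  out
}
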