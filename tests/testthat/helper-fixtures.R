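# Shared fixtures for the suite. Digitised solids are generated on odd
# grids with the centre on a voxel so analytic oracles apply cleanly.

mk_ball <- function(n, r, centre = rep((n + 1) / 2, 3)) {
  x <- seq_len(n)
  outer(outer((x - centre[1])^2, (x - centre[2])^2, "+"),
        (x - centre[3])^2, "+") <= r^2
}

mk_torus <- function(n = 40, R = 10, a = 4) {
  x <- seq_len(n); cc <- (n + 1) / 2
  g <- expand.grid(x = x, y = x, z = x)
  rho <- sqrt((g$x - cc)^2 + (g$y - cc)^2)
  array((rho - R)^2 + (g$z - cc)^2 <= a^2, c(n, n, n))
}

# small centered jar scan reused by several reconstruction tests;
# built once per test run
scan_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    vx <- 50
    ph <- build_jar_phantom(c(128, 128, 6), vx, jar_radius_um = 2800,
                            jar_wall_um = 200)
    beam <- beam_model(propagation_m = 0, flux = 2e4)
    geom <- scan_geometry("centered", detector_width = 128,
                          detector_height = 2, pixel_size_um = vx,
                          n_projections = 360)
    pset <- simulate_scan(ph, beam, geom, seed = 42, noise = FALSE,
                          reference_phantom = FALSE)
    cache <<- list(phantom = ph, beam = beam, geometry = geom, pset = pset)
    cache
  }
})

# brute-force 1D convolution with replicate padding (independent oracle
# for the Gaussian-blur based operations)
conv1d_oracle <- function(x, k) {
  r <- (length(k) - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- pmin(pmax(i + (-r):r, 1), n)
    sum(x[idx] * k)
  }, numeric(1))
}
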