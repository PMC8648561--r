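# X-ray material model at an effective monochromatic energy.
# The complex refractive index is n = 1 - delta + i*beta; the linear
# attenuation coefficient is mu = 4*pi*beta/lambda. Phase contrast strength
# is governed by delta, absorption by beta/mu.

#' X-ray wavelength from photon energy
#'
#' `lambda[A] = 12.398 / E[keV]`.
#'
#' @param energy_keV photon energy in keV.
#' @return wavelength in metres.
#' @export
xray_wavelength <- function(energy_keV) {
  stopifnot(energy_keV > 0)
  12.398 / energy_keV * 1e-10
}

#' Define an imaging material
#'
#' Materials carry a linear attenuation coefficient `mu` (1/mm) at the
#' effective beam energy together with the refractive-index decrements
#' `delta` (real part) and `beta` (imaginary part). `beta` is derived from
#' `mu` through `mu = 4*pi*beta/lambda`, and `delta` from the requested
#' `delta/beta` ratio unless given explicitly, so the three are always
#' mutually consistent.
#'
#' @param name material name.
#' @param mu linear attenuation coefficient, 1/mm (>= 0).
#' @param energy_keV effective beam energy used to convert mu to beta.
#' @param delta_beta delta/beta ratio (used when `delta` is NULL).
#' @param delta refractive-index decrement; overrides `delta_beta`.
#' @return an object of class `material`.
#' @export
material <- function(name, mu, energy_keV = 85, delta_beta = 1000,
                     delta = NULL) {
  stopifnot(mu >= 0, delta_beta > 0)
  lambda_mm <- xray_wavelength(energy_keV) * 1e3
  beta <- mu * lambda_mm / (4 * pi)
  if (is.null(delta)) delta <- delta_beta * beta
  stopifnot(delta >= 0)
  structure(list(name = name, mu = mu, delta = delta, beta = beta,
                 energy_keV = energy_keV),
            class = "material")
}

#' Default phantom material table
#'
#' Scenario defaults at an effective energy of 85 keV, chosen to mimic a
#' formalin-fixed, ethanol-equilibrated organ in an agar-ethanol mounting
#' medium inside a plastic jar: weak absorption contrast between tissue and
#' mounting medium, strong phase contrast (delta/beta of order 10^3). These
#' are plausible placeholders, not measured values; real fixed-tissue
#' optical constants are not tabulated for this preparation.
#'
#' Labels: 0 exterior air, 1 jar wall, 2 agar-ethanol, 3 soft tissue
#' (parenchyma / septal tissue), 4 dense functional unit (glomerulus-like),
#' 5 consolidation (fluid/cell-filled airspace).
#'
#' @param energy_keV effective beam energy in keV.
#' @return named list of [material()] entries, names are label numbers.
#' @export
default_materials <- function(energy_keV = 85) {
  list(
    "0" = material("air",           0.0,    energy_keV),
    "1" = material("jar_wall",      0.035,  energy_keV, delta_beta = 800),
    "2" = material("agar_ethanol",  0.018,  energy_keV, delta_beta = 1000),
    "3" = material("soft_tissue",   0.022,  energy_keV, delta_beta = 1000),
    "4" = material("dense_unit",    0.026,  energy_keV, delta_beta = 1000),
    "5" = material("consolidation", 0.024,  energy_keV, delta_beta = 1000)
  )
}

material_property <- function(materials, what) {
  vapply(materials, function(m) m[[what]], numeric(1))
}

#' Attenuation / phase-decrement volume of a phantom
#'
#' Maps phantom labels to the per-material `mu` (1/mm) or `delta`
#' (dimensionless) values. Material interfaces are smoothed with a small
#' Gaussian (`edge_sigma_voxel`, default 1 voxel): fixed organs
#' equilibrated in ethanol-agar have no sub-voxel-sharp density steps and
#' the detector optics have a finite point-spread, so hard label edges
#' would put non-physical above-Nyquist content into the simulated
#' projections. Set `edge_sigma_voxel = 0` for raw binary interfaces.
#'
#' @param phantom a `phantom` object.
#' @param what `"mu"` or `"delta"`.
#' @param edge_sigma_voxel Gaussian interface smoothing, voxels.
#' @return a float32 [volume3d()].
#' @export
phantom_property_volume <- function(phantom, what = c("mu", "delta"),
                                    edge_sigma_voxel = 1) {
  what <- match.arg(what)
  key <- sprintf("%s_%g", what, edge_sigma_voxel)
  if (!is.null(phantom$cache) && !is.null(phantom$cache[[key]]))
    return(phantom$cache[[key]])
  labs <- phantom$labels
  vals <- material_property(phantom$materials, what)
  arr <- array(0, dim(labs$data))
  for (nm in names(phantom$materials)) {
    v <- vals[[nm]]
    if (v != 0) arr[labs$data == as.integer(nm)] <- v
  }
  if (edge_sigma_voxel > 0) arr <- gauss_blur3d(arr, edge_sigma_voxel)
  out <- volume3d(arr, labs$voxel_size, labs$origin)
  if (!is.null(phantom$cache)) phantom$cache[[key]] <- out
  out
}

# separable 3D Gaussian blur with replicate edges, via banded smoothing
# matrices (fast for desk-scale grids)
blur_matrix <- function(n, k) {
  r <- (length(k) - 1) %/% 2
  S <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(n) + o, 1), n)
    S[cbind(seq_len(n), idx)] <- S[cbind(seq_len(n), idx)] + k[o + r + 1]
  }
  S
}

gauss_blur3d <- function(arr, sigma) {
  k <- gauss_kernel(sigma)
  d <- dim(arr)
  for (ax in 1:3) {
    if (d[ax] > 1) {
      S <- blur_matrix(d[ax], k)
      perm <- c(ax, setdiff(1:3, ax))
      m <- S %*% matrix(aperm(arr, perm), d[ax])
      arr <- aperm(array(m, d[perm]), order(perm))
    }
  }
  arr
}
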