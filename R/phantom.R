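# Seeded synthetic phantoms: a cylindrical mounting jar with agar-ethanol
# interior, a kidney-like phantom with glomerulus-like spheres packed in a
# parenchyma shell, and a thin-walled alveolar foam with an optional
# consolidated fraction. Every generator is pure given (spec, seed) and
# records enough ground truth to recompute any reported summary.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(seed)
    return(force(code))
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

new_phantom <- function(labels, materials, truth) {
  structure(list(labels = labels, materials = materials, truth = truth,
                 cache = new.env(parent = emptyenv())),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  d <- dim(x$labels$data)
  cat(sprintf("<phantom:%s> %d x %d x %d voxels @ %.4g um/voxel\n",
              x$truth$kind, d[1], d[2], d[3], x$labels$voxel_size))
  tab <- table(x$labels$data)
  nm <- vapply(x$materials, `[[`, "", "name")
  for (lb in names(tab))
    cat(sprintf("  label %s (%s): %d voxels\n", lb,
                if (lb %in% names(nm)) nm[[lb]] else "?", tab[[lb]]))
  invisible(x)
}

# squared radial distance (um^2) from a jar axis parallel to z
radial_sq <- function(shape, voxel_size, centre_xy) {
  x <- voxel_size * (seq_len(shape[1]) - 1)
  y <- voxel_size * (seq_len(shape[2]) - 1)
  outer((x - centre_xy[1])^2, (y - centre_xy[2])^2, "+")
}

#' Cylindrical jar phantom (mounting reference geometry)
#'
#' Concentric regions per axial slice: exterior air, jar wall, agar-ethanol
#' interior. With no tissue features this is exactly the reference jar used
#' for local-tomography flat-fielding.
#'
#' @param shape grid dimensions `c(nx, ny, nz)` in voxels.
#' @param voxel_size voxel size, µm.
#' @param jar_radius_um outer jar radius, µm.
#' @param jar_wall_um jar wall thickness, µm.
#' @param materials material table (label -> [material()]).
#' @param centre_xy jar axis position (µm, in-grid); default grid centre.
#' @param seed unused for the jar itself (deterministic); kept for API
#'   uniformity.
#' @return a `phantom`.
#' @export
build_jar_phantom <- function(shape, voxel_size, jar_radius_um,
                              jar_wall_um = 0.06 * jar_radius_um,
                              materials = default_materials(),
                              centre_xy = NULL, seed = NULL) {
  shape <- as.integer(shape)
  half_extent <- min(shape[1], shape[2]) / 2 * voxel_size
  if (is.null(centre_xy))
    centre_xy <- voxel_size * (shape[1:2] - 1) / 2
  if (jar_radius_um > half_extent)
    stop("jar radius exceeds half the grid extent", call. = FALSE)
  r2 <- radial_sq(shape, voxel_size, centre_xy)
  slice <- matrix(0L, shape[1], shape[2])
  slice[r2 <= jar_radius_um^2] <- 1L
  slice[r2 <= (jar_radius_um - jar_wall_um)^2] <- 2L
  labels <- array(slice, shape)
  new_phantom(
    volume3d(labels, voxel_size),
    materials,
    list(kind = "jar",
         jar = list(radius_um = jar_radius_um, wall_um = jar_wall_um,
                    centre_xy = centre_xy)))
}

# uniform sample inside a spherical shell r in [r0, r1]
sample_shell <- function(n, r0, r1) {
  u <- stats::runif(n)
  r <- (r0^3 + u * (r1^3 - r0^3))^(1 / 3)
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(r * s * cos(phi), r * s * sin(phi), r * z)
}

#' Kidney-like phantom: spheres packed in a parenchyma shell
#'
#' A jar phantom containing a spherical parenchyma shell (label 3) centred
#' in the jar, studded with exactly `n_units` non-overlapping
#' glomerulus-like spheres (label 4) whose centres are uniform in the shell.
#' Ground truth lists every centre and radius plus the shell geometry, so
#' stereological estimates can be checked against the generator.
#'
#' @param shape,voxel_size,jar_radius_um,jar_wall_um,materials,centre_xy
#'   as in [build_jar_phantom()].
#' @param shell_outer_um,shell_inner_um parenchyma shell radii, µm.
#' @param n_units number of spheres to place.
#' @param unit_radius_um scalar radius, or `c(mean, sd)` of a normal
#'   truncated at `mean ± 2 sd` (and at > 0), µm.
#' @param min_separation_um minimum centre-to-centre distance, µm.
#' @param seed RNG seed.
#' @param max_tries bounded rejection retries before giving up.
#' @param voxelize if `FALSE`, spheres live only in the truth table (labels
#'   contain jar + shell); useful for large stereology runs.
#' @return a `phantom` whose `truth` holds `centres` (n x 3, µm, in the
#'   physical frame of the grid — same frame as [cylinder_roi()]),
#'   `radii_um`, and the shell spec.
#' @export
build_kidney_phantom <- function(shape, voxel_size, jar_radius_um,
                                 shell_outer_um, shell_inner_um,
                                 n_units, unit_radius_um,
                                 min_separation_um,
                                 jar_wall_um = 0.06 * jar_radius_um,
                                 materials = default_materials(),
                                 centre_xy = NULL, seed = NULL,
                                 max_tries = 1e5, voxelize = TRUE) {
  stopifnot(shell_outer_um > shell_inner_um, shell_inner_um >= 0,
            n_units >= 0)
  base <- build_jar_phantom(shape, voxel_size, jar_radius_um, jar_wall_um,
                            materials, centre_xy)
  centre_xy <- base$truth$jar$centre_xy
  shape <- as.integer(shape)
  centre <- c(centre_xy, voxel_size * (shape[3] - 1) / 2)
  if (shell_outer_um > jar_radius_um - jar_wall_um)
    stop("parenchyma shell does not fit inside the jar", call. = FALSE)

  mean_r <- if (length(unit_radius_um) == 2) unit_radius_um[1] else unit_radius_um
  # keep whole spheres inside the shell
  r_lo <- shell_inner_um + mean_r
  r_hi <- shell_outer_um - mean_r
  if (r_hi <= r_lo) stop("shell too thin for the unit radius", call. = FALSE)

  centres <- matrix(numeric(0), 0, 3)
  radii <- numeric(0)
  with_seed(seed, {
    tries <- 0
    while (nrow(centres) < n_units && tries < max_tries) {
      m <- min(512L, max_tries - tries)
      tries <- tries + m
      cand <- sample_shell(m, r_lo, r_hi)
      for (i in seq_len(m)) {
        if (nrow(centres) >= n_units) break
        p <- cand[i, ]
        if (nrow(centres) == 0 ||
            min(rowSums(sweep(centres, 2, p)^2)) >= min_separation_um^2) {
          centres <- rbind(centres, p)
          radii <- c(radii,
                     if (length(unit_radius_um) == 2)
                       max(voxel_size / 2,
                           min(mean_r + 2 * unit_radius_um[2],
                               max(mean_r - 2 * unit_radius_um[2],
                                   stats::rnorm(1, mean_r, unit_radius_um[2]))))
                     else unit_radius_um)
        }
      }
    }
  })
  if (nrow(centres) < n_units)
    stop(sprintf(
      "sphere packing infeasible: placed %d of %d units within retry budget",
      nrow(centres), n_units), call. = FALSE)

  labels <- base$labels$data
  ax <- list(x = voxel_size * (seq_len(shape[1]) - 1) - centre[1],
             y = voxel_size * (seq_len(shape[2]) - 1) - centre[2],
             z = voxel_size * (seq_len(shape[3]) - 1) - centre[3])
  # parenchyma shell
  rr2 <- outer(outer(ax$x^2, ax$y^2, "+"), ax$z^2, "+")
  shell <- rr2 <= shell_outer_um^2 & rr2 >= shell_inner_um^2 & labels == 2L
  labels[shell] <- 3L
  if (voxelize && n_units > 0) {
    for (i in seq_len(nrow(centres))) {
      p <- centres[i, ]; r <- radii[i]
      ix <- which(abs(ax$x - p[1]) <= r)
      iy <- which(abs(ax$y - p[2]) <= r)
      iz <- which(abs(ax$z - p[3]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      d2 <- outer(outer((ax$x[ix] - p[1])^2, (ax$y[iy] - p[2])^2, "+"),
                  (ax$z[iz] - p[3])^2, "+")
      sub <- labels[ix, iy, iz, drop = FALSE]
      sub[d2 <= r^2] <- 4L
      labels[ix, iy, iz] <- sub
    }
  }
  dimnames(centres) <- NULL
  centres_abs <- sweep(centres, 2, centre, "+")   # physical frame of the grid
  new_phantom(
    volume3d(labels, voxel_size),
    materials,
    list(kind = "kidney", jar = base$truth$jar,
         shell = list(outer_um = shell_outer_um, inner_um = shell_inner_um,
                      centre = centre),
         centres = centres_abs, radii_um = radii, n_units = nrow(centres),
         min_separation_um = min_separation_um, seed = seed))
}

# Poisson-disk-ish dart throwing in a box [0, L]^3 (um)
poisson_disk <- function(extent, min_dist, max_attempts = 2e4) {
  pts <- matrix(numeric(0), 0, 3)
  att <- 0
  while (att < max_attempts) {
    att <- att + 1
    p <- stats::runif(3) * extent
    if (nrow(pts) == 0 ||
        min(rowSums(sweep(pts, 2, p)^2)) >= min_dist^2)
      pts <- rbind(pts, p)
  }
  pts
}

#' Alveolar foam phantom
#'
#' Voronoi-cell foam emulating lung parenchyma: seed points from a
#' Poisson-disk process define cells; voxels whose two nearest seeds are
#' nearly equidistant form tissue walls of thickness `wall_um`; cell
#' interiors are airspace. A uniformly random fraction `consolidation` of
#' cells is filled with consolidation material, emulating fluid/cellular
#' infiltration of alveoli.
#'
#' Labels: 0 airspace, 3 septal tissue, 5 consolidation.
#'
#' @param shape grid dimensions `c(nx, ny, nz)`.
#' @param voxel_size voxel size, µm.
#' @param cell_diameter_um mean alveolus (cell) diameter, µm.
#' @param wall_um septal wall thickness, µm (must be >= 1 voxel).
#' @param consolidation fraction of cells filled, in `[0, 1]`.
#' @param residual_pocket fraction of the cell diameter kept as a tiny
#'   unconnected residual air pocket at the centre of each consolidated
#'   cell (exudate rarely fills an alveolus completely; these pockets are
#'   what makes diseased airspace size distributions bimodal). 0 disables;
#'   the default 0.10 keeps the fully consolidated airspace below 1%.
#' @param seed RNG seed.
#' @return a `phantom`; truth records the seeds, wall thickness, the
#'   per-cell phase and the realised airspace fraction.
#' @export
build_alveolar_phantom <- function(shape, voxel_size, cell_diameter_um,
                                   wall_um, consolidation = 0,
                                   residual_pocket = 0.10, seed = NULL) {
  shape <- as.integer(shape)
  if (wall_um < voxel_size)
    stop("wall thickness below one voxel cannot be represented",
         call. = FALSE)
  stopifnot(consolidation >= 0, consolidation <= 1)
  extent <- voxel_size * shape
  res <- with_seed(seed, {
    seeds <- poisson_disk(extent, 0.8 * cell_diameter_um)
    n <- nrow(seeds)
    filled <- stats::runif(n) < consolidation
    list(seeds = seeds, filled = filled)
  })
  seeds <- res$seeds; filled <- res$filled
  n <- nrow(seeds)

  x <- voxel_size * (seq_len(shape[1]) - 1)
  y <- voxel_size * (seq_len(shape[2]) - 1)
  z <- voxel_size * (seq_len(shape[3]) - 1)
  d1 <- array(Inf, shape)   # nearest seed distance^2
  d2 <- array(Inf, shape)   # second nearest
  owner <- array(0L, shape)
  reach <- 2.5 * cell_diameter_um
  for (i in seq_len(n)) {
    p <- seeds[i, ]
    ix <- which(abs(x - p[1]) <= reach)
    iy <- which(abs(y - p[2]) <= reach)
    iz <- which(abs(z - p[3]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dd <- outer(outer((x[ix] - p[1])^2, (y[iy] - p[2])^2, "+"),
                (z[iz] - p[3])^2, "+")
    sub1 <- d1[ix, iy, iz, drop = FALSE]
    sub2 <- d2[ix, iy, iz, drop = FALSE]
    subo <- owner[ix, iy, iz, drop = FALSE]
    closer <- dd < sub1
    second <- !closer & dd < sub2
    sub2[second] <- dd[second]
    sub2[closer] <- sub1[closer]
    subo[closer] <- i
    sub1[closer] <- dd[closer]
    d1[ix, iy, iz] <- sub1
    d2[ix, iy, iz] <- sub2
    owner[ix, iy, iz] <- subo
  }
  # distance to the Voronoi boundary ~ (sqrt(d2) - sqrt(d1)) / 2
  wall <- (sqrt(d2) - sqrt(d1)) <= wall_um
  wall[!is.finite(d2)] <- TRUE
  labels <- array(0L, shape)
  labels[wall] <- 3L
  cons <- !wall & array(filled[pmax(owner, 1L)], shape) & owner > 0L
  labels[cons] <- 5L
  if (residual_pocket > 0 && any(filled)) {
    pr <- residual_pocket * cell_diameter_um
    for (i in which(filled)) {
      p <- seeds[i, ]
      ix <- which(abs(x - p[1]) <= pr)
      iy <- which(abs(y - p[2]) <= pr)
      iz <- which(abs(z - p[3]) <= pr)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dd <- outer(outer((x[ix] - p[1])^2, (y[iy] - p[2])^2, "+"),
                  (z[iz] - p[3])^2, "+")
      sub <- labels[ix, iy, iz, drop = FALSE]
      sub[dd <= pr^2 & sub == 5L] <- 0L
      labels[ix, iy, iz] <- sub
    }
  }
  airfrac <- mean(labels == 0L)
  new_phantom(
    volume3d(labels, voxel_size),
    default_materials(),
    list(kind = "alveolar", seeds = seeds, wall_um = wall_um,
         consolidation = consolidation, cell_filled = filled,
         residual_pocket = residual_pocket,
         cell_diameter_um = cell_diameter_um,
         airspace_fraction = airfrac, seed = seed))
}

#' Reference twin of a phantom
#'
#' The jar-only counterpart of a sample phantom: identical jar geometry and
#' materials, interior entirely mounting medium. Used to simulate the
#' reference scans that flat-field local-tomography acquisitions.
#'
#' @param phantom a `phantom` built by one of the jar-based generators.
#' @return a jar `phantom`.
#' @export
reference_twin <- function(phantom) {
  if (is.null(phantom$truth$jar))
    stop("phantom has no jar specification; supply a reference explicitly",
         call. = FALSE)
  d <- dim(phantom$labels$data)
  build_jar_phantom(d, phantom$labels$voxel_size,
                    phantom$truth$jar$radius_um, phantom$truth$jar$wall_um,
                    phantom$materials, phantom$truth$jar$centre_xy)
}
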