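# Thresholding, distance maps, thickness, surface area, connectivity,
# object morphometry, stereology, grouped comparison.

test_that("all automatic thresholds separate a two-value volume", {
  set.seed(31)
  x <- array(sample(c(rep(10, 200), rep(100, 800))), c(10, 10, 10))
  for (m in c("triangle", "yen", "otsu")) {
    b <- threshold_volume(volume3d(x, 1), m)
    expect_equal(sum(b$mask), sum(x == 100), info = m)
  }
  expect_error(threshold_volume(volume3d(array(5, c(4, 4, 4)), 1), "otsu"),
               "constant")
})

test_that("triangle threshold equals the exhaustive chord-distance search", {
  set.seed(32)
  x <- c(rexp(8000, 2), rnorm(1500, 6, 0.7))     # skewed + small mode
  v <- volume3d(array(x[1:9261], c(21, 21, 21)), 1)
  b <- threshold_volume(v, "triangle")
  h <- hiptomo:::threshold_hist(v$data)
  # brute force: distance of every bin to the peak-to-tail chord
  counts <- h$counts
  peak <- which.max(counts)
  nz <- which(counts > 0)
  endp <- if ((nz[length(nz)] - peak) >= (peak - nz[1])) nz[length(nz)]
          else nz[1]
  span <- min(peak, endp):max(peak, endp)
  d <- vapply(span, function(i) {
    x1 <- peak; y1 <- counts[peak]; x2 <- endp; y2 <- counts[endp]
    abs((y2 - y1) * i - (x2 - x1) * counts[i] + x2 * y1 - y2 * x1) /
      sqrt((x2 - x1)^2 + (y2 - y1)^2)
  }, numeric(1))
  expect_equal(attr(b, "threshold"), h$edges[span[which.max(d)]])
})

test_that("yen threshold equals the exhaustive criterion maximisation", {
  set.seed(33)
  x <- c(rnorm(6000, 2, 0.5), rnorm(4000, 7, 1.2))[1:9261]
  v <- volume3d(array(x, c(21, 21, 21)), 1)
  b <- threshold_volume(v, "yen")
  h <- hiptomo:::threshold_hist(v$data)
  p <- h$counts / sum(h$counts)
  crit <- vapply(seq_len(255), function(t) {
    P1 <- sum(p[1:t]); P1sq <- sum(p[1:t]^2); P2sq <- sum(p[(t + 1):256]^2)
    -log(max(P1sq * P2sq, 1e-300)) + 2 * log(max(P1 * (1 - P1), 1e-300))
  }, numeric(1))
  expect_equal(attr(b, "threshold"), h$edges[which.max(crit)])
})

test_that("chamfer distances are exact on lattice-aligned paths", {
  m <- array(TRUE, c(15, 7, 7))
  m[1, , ] <- FALSE                       # background wall at x = 1
  cd <- chamfer_distance(binary_volume(m, 1))
  for (k in 2:15) expect_equal(cd$data[k, 4, 4], k - 1)
  # face-adjacent voxel is at distance exactly 1
  one <- array(FALSE, c(5, 5, 5)); one[2:4, 2:4, 2:4] <- TRUE
  cd1 <- chamfer_distance(binary_volume(one, 1))
  expect_equal(cd1$data[2, 3, 3], 1)
  expect_error(chamfer_distance(binary_volume(array(TRUE, c(3, 3, 3)), 1)),
               "background")
})

test_that("chamfer stays within the (3,4,5,7) lattice bound of Euclidean", {
  set.seed(34)
  for (rep in 1:3) {
    m <- array(runif(32^3) < 0.6, c(32, 32, 32))
    if (!any(m) || all(m)) next
    b <- binary_volume(m, 1)
    cd <- chamfer_distance(b)$data
    ed <- euclidean_distance(b)$data
    fg <- m & ed > 0
    dev <- (cd[fg] - ed[fg]) / ed[fg]
    # continuum gauge bounds: -5.8% (edge directions), +5.5% ((3,1,0))
    expect_gte(min(dev), -0.06)
    expect_lte(max(dev), 0.06)
  }
})

test_that("local thickness matches slab, ball, and units", {
  slab <- array(FALSE, c(12, 12, 15)); slab[, , 7:9] <- TRUE
  th <- local_thickness(binary_volume(slab, 2.5))   # 2.5 um voxels
  expect_equal(th$data[6, 6, 8], 3 * 2.5)
  ball <- mk_ball(49, 20)
  thb <- local_thickness(binary_volume(ball, 1))
  expect_lte(abs(thb$data[25, 25, 25] - 40), 1)
  expect_error(local_thickness(binary_volume(array(FALSE, c(4, 4, 4)), 1)),
               "empty")
})

test_that("surface-area-to-volume matches analytic solids and scaling", {
  ball <- binary_volume(mk_ball(49, 20), 1)
  expect_lt(abs(surface_area_to_volume(ball) / (3 / 20) - 1), 0.05)
  box <- array(FALSE, c(30, 30, 30)); box[6:25, 6:25, 6:25] <- TRUE
  expect_lt(abs(surface_area_to_volume(binary_volume(box, 1)) / (6 / 20) - 1),
            0.05)
  # halving all linear dimensions doubles the ratio
  small <- binary_volume(mk_ball(25, 10), 1)
  expect_lt(abs(surface_area_to_volume(small) /
                  surface_area_to_volume(ball) - 2), 0.2)
  expect_error(surface_area_to_volume(
    binary_volume(array(FALSE, c(4, 4, 4)), 1)), "empty")
})

test_that("Euler connectivity distinguishes ball, torus, two balls", {
  ball <- connectivity(binary_volume(mk_ball(33, 12), 1))
  expect_equal(ball$euler, 1)
  expect_equal(ball$connectivity, 0)
  tor <- connectivity(binary_volume(mk_torus(), 1))
  expect_equal(tor$euler, 0)
  expect_equal(tor$connectivity, 1)
  two <- mk_ball(40, 6, c(12, 12, 12)) | mk_ball(40, 6, c(30, 30, 30))
  expect_equal(connectivity(binary_volume(two, 1))$euler, 2)
})

test_that("morphometric measures are invariant under axis permutation", {
  set.seed(35)
  ph <- build_alveolar_phantom(c(40, 40, 40), 10, 110, 20, 0, seed = 3)
  m <- ph$labels$data == 0L
  b1 <- binary_volume(m, 10)
  b2 <- binary_volume(aperm(m, c(3, 1, 2)), 10)
  expect_equal(surface_area_to_volume(b1), surface_area_to_volume(b2),
               tolerance = 1e-12)
  expect_equal(connectivity(b1)$euler, connectivity(b2)$euler)
  # sphere painting breaks ties in scan order, so thickness is invariant
  # up to a handful of tie voxels; distributions must agree closely
  t1 <- sort(local_thickness(b1)$data[b1$mask])
  t2 <- sort(local_thickness(b2)$data[b2$mask])
  expect_equal(mean(t1), mean(t2), tolerance = 5e-3)
  expect_lt(mean(abs(t1 - t2)) / mean(t1), 0.01)
})

test_that("object morphometry reports volume, surface and sphericity", {
  ball <- mk_ball(49, 20)
  lab <- label_components(binary_volume(ball, 1))
  om <- object_morphometry(lab)
  expect_equal(nrow(om), 1)
  expect_gte(om$sphericity, 0.97)
  expect_false(om$on_border)
  expect_lt(abs(om$volume_um3 / (4 / 3 * pi * 20^3) - 1), 0.02)
  # closed-form cube check of the sphericity formula itself
  s <- 10
  psi_cube <- pi^(1 / 3) * (6 * s^3)^(2 / 3) / (6 * s^2)
  expect_equal(round(psi_cube, 3), 0.806)
  # border-touching objects are flagged
  half <- mk_ball(20, 12, c(1, 10, 10))
  omb <- object_morphometry(label_components(binary_volume(half, 1)))
  expect_true(omb$on_border[1])
})

test_that("sphericity respects the isoperimetric bound on random blobs", {
  set.seed(36)
  m <- array(runif(24^3) < 0.45, c(24, 24, 24))
  # smooth into blobs: a couple of dilation/erosion-ish passes via blur
  sm <- hiptomo:::gauss_blur3d(m + 0, 1.5) > 0.5
  if (any(sm)) {
    lab <- label_components(binary_volume(sm, 1))
    om <- object_morphometry(lab)
    om <- om[om$n_voxels >= 30, ]
    if (nrow(om)) expect_true(all(om$sphericity <= 1.02))
  }
})

test_that("labelling respects the requested connectivity order", {
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE       # touch only diagonally
  l26 <- label_components(binary_volume(m, 1), 26)
  l6 <- label_components(binary_volume(m, 1), 6)
  expect_equal(max(l26$data), 1)
  expect_equal(max(l6$data), 2)
})

test_that("virtual biopsy counts and the extrapolation estimator agree", {
  expect_equal(
    virtual_biopsy(matrix(c(0, 0, 0.5), 1),
                   cylinder_roi(c(0, 0, 0), c(0, 0, 1), 1, 1))$count, 1)
  e <- estimate_total_units(10, 1, 100)
  expect_equal(e$n_total, 1000)
  expect_equal(e$se, sqrt(10) * 100)
  expect_equal(estimate_total_units(7, 5, 5)$n_total, 7)
  expect_error(estimate_total_units(2, 10, 5), "exceeds")
  td <- tidy(e)
  expect_equal(td$n_total, 1000)
})

test_that("grouped morphometry separates thin from thick walls", {
  vx <- 10
  mk_group <- function(tw, seeds) lapply(seeds, function(s)
    binary_volume(build_alveolar_phantom(c(56, 56, 56), vx, 150,
                                         tw * vx, 0, seed = s)$labels$data
                  == 0L, vx, "airspace"))
  vois <- c(mk_group(2, 1:6), mk_group(4, 7:12))
  groups <- rep(c("thin", "thick"), each = 6)
  rep_ <- morphometry_report(vois, groups)
  recs <- rep_$records
  expect_gt(mean(recs$mean_septal_thickness_um[recs$group == "thick"]),
            mean(recs$mean_septal_thickness_um[recs$group == "thin"]))
  expect_lt(mean(recs$surface_area_to_volume[recs$group == "thick"]),
            mean(recs$surface_area_to_volume[recs$group == "thin"]))
  tk <- rep_$tukey
  expect_lt(tk$p_adj[tk$measure == "mean_septal_thickness_um"][1], 0.01)
  expect_lt(tk$p_adj[tk$measure == "surface_area_to_volume"][1], 0.01)
})

test_that("identical VOIs across groups give null statistics", {
  vx <- 10
  ph <- build_alveolar_phantom(c(40, 40, 40), vx, 120, 2 * vx, 0, seed = 2)
  b <- binary_volume(ph$labels$data == 0L, vx, "airspace")
  rep_ <- morphometry_report(list(b, b, b, b), c("a", "a", "b", "b"))
  expect_true(all(rep_$anova$p > 0.99))
  expect_true(all(rep_$tukey$p_adj > 0.99))
  expect_error(morphometry_report(list(b, b), c("a", "b")), "2 VOIs")
})

test_that("consolidation makes the airspace size distribution bimodal", {
  # consolidated alveoli leave tiny unconnected residual pockets: the
  # per-airspace (connected component) equivalent-diameter distribution
  # gains a second, small-diameter mode absent in the open foam
  vx <- 10
  n_modes <- function(f) {
    ph <- build_alveolar_phantom(c(64, 64, 64), vx, 150, 2 * vx, f,
                                 seed = 5)
    air <- binary_volume(ph$labels$data == 0L, vx, "airspace")
    lab <- label_components(air, 6)
    sz <- table(lab$data[lab$data > 0])
    deq <- (6 * as.numeric(sz) * vx^3 / pi)^(1 / 3)
    cnt <- hist(deq, breaks = seq(0, 500, 25), plot = FALSE)$counts
    sum(diff(sign(diff(c(-1, cnt, -1)))) <= -2 & cnt[] > 2)
  }
  expect_equal(n_modes(0), 1)
  expect_gte(n_modes(0.5), 2)
})
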