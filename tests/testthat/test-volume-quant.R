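# 3D stack analysis: multi-Otsu, denoising, 3-class segmentation with
# watershed splitting, random-walker vasculature and proximity metrics.

sphere_mask <- function(dims, ctr, r, vs = c(1, 1, 1)) {
  co <- arrayInd(seq_len(prod(dims)), dims)
  phys <- sweep(co - 0.5, 2, vs, "*")
  array(sqrt(rowSums(sweep(phys, 2, ctr)^2)) <= r, dims)
}

test_that("multi-Otsu separates a trimodal histogram at the right cuts", {
  set.seed(1)
  x <- c(rnorm(3000, 100, 10), rnorm(3000, 500, 10), rnorm(3000, 900, 10))
  # the between-class variance is flat across the empty gaps, so any cut
  # outside the cluster cores is optimal; ties resolve to the first bin
  cuts <- multiOtsu(x)
  expect_gt(cuts[1], 130); expect_lt(cuts[1], 470)
  expect_gt(cuts[2], 530); expect_lt(cuts[2], 870)
  # brute-force oracle on a coarse histogram: exhaustive search over all
  # threshold pairs maximizing between-class variance
  xs <- sample(x, 400)
  cuts2 <- multiOtsu(xs, nbins = 32L)
  rng <- range(xs)
  edges <- rng[1] + (1:32) * diff(rng) / 32
  best <- -Inf; bf <- c(NA, NA)
  for (i in 1:30) for (j in (i + 1):31) {
    cls <- findInterval(xs, c(edges[i], edges[j])) + 1L
    if (length(unique(cls)) < 3L) next
    sb <- sum(tapply(xs, cls, length) / length(xs) *
              (tapply(xs, cls, mean) - mean(xs))^2)
    if (sb > best) { best <- sb; bf <- c(edges[i], edges[j]) }
  }
  expect_equal(cuts2, bf, tolerance = 1e-9)
  expect_error(multiOtsu(rep(3, 100)), "degenerate-histogram")
})

test_that("denoising removes flat and ramped backgrounds, keeping blobs", {
  flat <- array(100, c(40, 30, 2))
  expect_lt(max(denoiseStack(flat, 0, 10)), 1e-9)
  # blob on a linear ramp: the ramp goes, most blob contrast stays
  d <- c(60, 40, 1)
  ramp <- array(rep(seq(0, 200, length.out = 60), 40), d)
  blob <- sphere_mask(d, c(30, 20, 0.5), 5) * 1000
  out <- denoiseStack(ramp + blob, 0, 20)
  # oracle: explicit morphological opening (erode+dilate box) of the input
  inp <- (ramp + blob)[, , 1]
  bg <- mvnquant:::cpp_boxminmax2d(mvnquant:::cpp_boxminmax2d(inp, 20L, 0L),
                                   20L, 1L)
  expect_equal(out[, , 1], pmax(inp - bg, 0))
  expect_gt(max(out), 0.9 * 1000)
  expect_lt(mean(out[, , 1][blob[, , 1] == 0]), 30)
  # sigma 0, huge radius: output is about input minus its minimum
  x <- array(runif(200, 50, 60), c(20, 10, 1))
  out2 <- denoiseStack(x, 0, 1000)
  expect_equal(out2, x - min(x), tolerance = 1e-9)
})

test_that("3-class segmentation labels only the brightest population", {
  d <- c(50, 30, 10)
  a <- array(0.1, d)
  mid <- sphere_mask(d, c(12, 15, 5), 5); a[mid] <- 0.5
  hi1 <- sphere_mask(d, c(30, 10, 5), 4); a[hi1] <- 0.9
  hi2 <- sphere_mask(d, c(40, 22, 5), 4); a[hi2] <- 0.9
  ob <- segmentObjects3Class(a, "test", c(1, 1, 1), minVolume = 5)
  expect_equal(length(objectVolumes(ob)), 2L)
  lab <- objectLabels(ob)
  expect_true(all(lab[mid] == 0L))
  # the opening may shave boundary voxels; the sphere cores must be labeled
  expect_gt(mean(lab[hi1] > 0L), 0.85)
  expect_gt(lab[30, 10, 5], 0L)
  # two spheres fused at a thin neck split into 2 objects
  f <- (sphere_mask(c(40, 20, 20), c(13, 10, 10), 7) |
        sphere_mask(c(40, 20, 20), c(27, 10, 10), 7)) * 10
  ob2 <- segmentObjects3Class(f, "test", c(1, 1, 1), minVolume = 5)
  expect_equal(length(objectVolumes(ob2)), 2L)
  # empty foreground
  hollow <- array(rep(c(0.1, 0.5, 0.9), length.out = 27), c(3, 3, 3))
  ob3 <- segmentObjects3Class(hollow, "test", c(1, 1, 1), minVolume = 1e6)
  expect_length(objectVolumes(ob3), 0L)
})

test_that("random-walker segmentation recovers tubes and their diameter", {
  # analytic cylinder along x, isotropic voxels
  d <- c(60, 41, 41); r_true <- 10
  co <- arrayInd(seq_len(prod(d)), d)
  cyl <- array((co[, 2] - 21)^2 + (co[, 3] - 21)^2 <= r_true^2, d)
  img <- cyl * 1 + 0.05
  img[!cyl & (co[, 2] - 21)^2 + (co[, 3] - 21)^2 <= (r_true + 3)^2] <- 0.5
  vm <- segmentVasculatureRandomWalk(img, c(1, 1, 1))
  expect_gt(dice_coef(vesselMask(vm), cyl), 0.95)
  expect_lt(abs(meanDiameter(vm) - 2 * r_true) / (2 * r_true), 0.10)
  # mask contains all upper seeds, excludes all lower seeds
  cuts <- multiOtsu(img)
  expect_true(all(vesselMask(vm)[img > cuts[2]]))
  expect_false(any(vesselMask(vm)[img < cuts[1]]))
  # noise-free synthetic scene: Dice vs truth >= 0.95
  sc <- small_scene("control_D7", seed = 12, noise = noise_off)
  den <- denoiseStack(channelVoxels(sc, "endothelium"), 1, 40)
  vm2 <- segmentVasculatureRandomWalk(den, voxelSize(sc))
  expect_gt(dice_coef(vesselMask(vm2), sceneTruth(sc)$vesselMask), 0.95)
})

test_that("object counts on noise-free scenes equal the generator truth", {
  for (seed in c(2, 5)) {
    sc <- small_scene("control_D7", seed = seed, noise = noise_off,
                      dims = c(128L, 64L, 14L))
    vs <- voxelSize(sc); tr <- sceneTruth(sc)
    for (mk in c("pericyte", "astrocyte", "nuclei")) {
      ob <- segmentObjects3Class(denoiseStack(channelVoxels(sc, mk), 1, 40),
                                 mk, vs)
      truth_n <- if (mk == "nuclei") nrow(tr$nucleiTable) else
        sum(tr$bodyTable$type == mk)
      expect_equal(length(objectVolumes(ob)), truth_n,
                   label = paste(mk, "count, seed", seed))
    }
  }
})

test_that("dilation overlap matches a brute-force oracle and is monotone", {
  d <- c(18, 14, 12)
  vs <- c(1, 1, 1)
  ves <- array(FALSE, d); ves[2:5, , ] <- TRUE
  vobj <- new("VesselMask3D", mask = ves, voxelSize = vs, meanDiameter = 4,
              skeletonLength = 10)
  mk_obj <- function(mask) {
    lab <- array(0L, d); lab[mask] <- 1L
    new("ObjectLabels3D", labels = lab, marker = "t", voxelSize = vs,
        volumes = c(`1` = sum(mask)))
  }
  near <- sphere_mask(d, c(8.5, 7, 6), 2)    # abuts the dilated vessel
  farm <- array(FALSE, d); farm[16:17, 12:13, 10:11] <- TRUE  # ~10 px away
  inside <- array(FALSE, d); inside[3:4, 5:6, 5:6] <- TRUE
  ovl <- function(mask, dil) {
    # brute-force cubic dilation by index arithmetic
    bd <- function(m, r) {
      out <- array(FALSE, d)
      for (p in which(m)) {
        ci <- arrayInd(p, d)
        xs <- max(1, ci[1] - r):min(d[1], ci[1] + r)
        ys <- max(1, ci[2] - r):min(d[2], ci[2] + r)
        zs <- max(1, ci[3] - r):min(d[3], ci[3] + r)
        out[xs, ys, zs] <- TRUE
      }
      out
    }
    sum(bd(mask, dil) & bd(ves, dil))
  }
  for (case in list(list(m = near, name = "abutting"),
                    list(m = inside, name = "inside"),
                    list(m = farm, name = "far"))) {
    po3 <- proximityOverlap(mk_obj(case$m), vobj, 3L)
    expect_equal(po3$overlap_volume, ovl(case$m, 3L), label = case$name)
  }
  expect_equal(proximityOverlap(mk_obj(farm), vobj, 3L)$overlap_volume, 0)
  expect_gt(proximityOverlap(mk_obj(near), vobj, 3L)$overlap_volume, 0)
  expect_gte(proximityOverlap(mk_obj(inside), vobj, 3L)$overlap_volume,
             sum(inside))
  # monotone in the dilation radius
  o <- vapply(1:4, function(r)
    proximityOverlap(mk_obj(near), vobj, r)$overlap_volume, 0)
  expect_true(all(diff(o) >= 0))
})

test_that("surface distances match geometry and the exhaustive oracle", {
  d <- c(30, 12, 12); vs <- c(1, 1, 1)
  ves <- array(FALSE, d); ves[2:6, 4:8, 4:8] <- TRUE
  vobj <- new("VesselMask3D", mask = ves, voxelSize = vs, meanDiameter = 5,
              skeletonLength = 5)
  # a cube with a 4 µm face gap to the vessel cube
  cube <- array(FALSE, d); cube[11:15, 4:8, 4:8] <- TRUE
  lab <- array(0L, d); lab[cube] <- 1L
  obj <- new("ObjectLabels3D", labels = lab, marker = "t", voxelSize = vs,
             volumes = c(`1` = sum(cube)))
  res <- surfaceDistance(obj, vobj)
  expect_equal(res$records$surface_distance, 4, tolerance = 1)  # half-diagonal
  # touching object: 0 within half a voxel diagonal
  touch <- array(FALSE, d); touch[7:9, 4:8, 4:8] <- TRUE
  lab2 <- array(0L, d); lab2[touch] <- 1L
  obj2 <- new("ObjectLabels3D", labels = lab2, marker = "t", voxelSize = vs,
              volumes = c(`1` = sum(touch)))
  expect_lte(surfaceDistance(obj2, vobj)$records$surface_distance,
             sqrt(3) / 2)
  # exhaustive pairwise oracle on the same surfaces
  sp <- mvnquant:::.surface_points
  q <- sp(cube, vs); r <- sp(ves, vs)
  bf <- min(apply(q, 1, function(p) min(sqrt(colSums((t(r) - p)^2)))))
  expect_equal(res$records$surface_distance, bf, tolerance = 1e-9)
  # overlap > 0 implies distance below the dilation bound
  po <- proximityOverlap(obj2, vobj, 3L)
  if (po$overlap_volume > 0)
    expect_lte(surfaceDistance(obj2, vobj)$records$surface_distance,
               2 * 3 * max(vs))
})
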