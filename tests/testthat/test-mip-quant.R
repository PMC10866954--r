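# MIP morphometry: preprocessing, thresholds, nuclei, border assignment,
# coverage, ghost fraction and apoptosis co-localization.

test_that("normalize-and-smooth clips, rescales and median-filters", {
  expect_true(all(normalizeAndSmooth(matrix(40000, 4, 4),
                                     medianRadius = 0) == 1))
  # an isolated bright pixel is erased by a radius-3 (7x7) median
  img <- matrix(0, 15, 15); img[8, 8] <- 20000
  out <- normalizeAndSmooth(img, medianRadius = 3)
  expect_equal(out[8, 8], 0)
  # radius 0 is exactly clip + rescale
  img2 <- matrix(runif(64, 0, 3e4), 8, 8)
  expect_equal(normalizeAndSmooth(img2, medianRadius = 0),
               pmin(img2, 20000) / 20000)
  expect_error(normalizeAndSmooth(matrix(c(1, NA), 2, 2)), "non-finite")
})

test_that("marker thresholds follow the common fractional convention", {
  u <- matrix(0.30, 6, 6)
  expect_true(all(thresholdRegion(u, "EC")))          # 0.30 >= 0.25
  expect_false(any(thresholdRegion(u, "pericyte")))   # 0.30 < 0.40
  expect_false(any(thresholdRegion(u, "astrocyte")))
  chk <- matrix(rep(c(0, 1), 18), 6, 6)
  expect_equal(thresholdRegion(chk, "EC", ecmMedianRadius = 0), chk == 1)
  expect_error(thresholdRegion(u, "myelin"), "unknown marker")
  # lowering a threshold never shrinks the mask
  img <- matrix(runif(400), 20, 20)
  m_low <- img >= 0.2; m_high <- img >= 0.6
  expect_true(all(m_high <= m_low))
})

test_that("nuclei segmentation finds, splits and filters objects", {
  px <- c(1, 1)
  blob <- function(img, cx, cy, r) {
    for (x in seq_len(nrow(img))) for (y in seq_len(ncol(img)))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) img[x, y] <- 1
    img
  }
  img <- blob(blob(matrix(0, 60, 40), 15, 20, 6), 45, 20, 6)
  n2 <- segmentNuclei(img, px)
  expect_equal(nrow(nucleiTable(n2)), 2L)
  # two discs joined by a thin 2 px neck are split by the watershed
  img3 <- blob(blob(matrix(0, 60, 40), 22, 20, 7), 38, 20, 7)
  img3[29:31, 19:20] <- 1
  n3 <- segmentNuclei(img3, px)
  expect_equal(nrow(nucleiTable(n3)), 2L)
  expect_equal(nrow(nucleiTable(segmentNuclei(matrix(0, 30, 30), px))), 0L)
  # objects below the minimum area are removed
  tiny <- blob(matrix(0, 40, 40), 20, 20, 2)
  expect_equal(nrow(nucleiTable(segmentNuclei(tiny, px, minArea = 50))), 0L)
})

test_that("nuclei are assigned by physically dilated borders, non-exclusively", {
  px <- c(1, 1)
  ec <- matrix(FALSE, 40, 40); ec[1:18, ] <- TRUE
  peri <- matrix(FALSE, 40, 40); peri[24:40, ] <- TRUE
  regions <- RegionMaskSet(list(EC = ec, pericyte = peri), px)
  lab <- matrix(0L, 40, 40)
  lab[20:21, 10:11] <- 1L   # 2 µm beyond EC edge: inside the 3 µm EC border
  lab[22:23, 30:31] <- 2L   # 1-2 µm from pericyte: inside its 2 µm border
  nuc <- new("NucleiLabels", labels = lab,
             table = data.frame(id = 1:2, area_um2 = c(4, 4),
                                cx = c(20.5, 22.5), cy = c(10.5, 30.5),
                                apoptotic = NA),
             pixelSize = px)
  cnt <- assignNucleiToRegions(nuc, regions)
  expect_equal(unname(cnt["EC"]), 1L)          # nucleus 1 only
  expect_gte(unname(cnt["pericyte"]), 1L)      # nucleus 2 at least
  # a nucleus 10 µm from everything counts nowhere
  lab2 <- matrix(0L, 40, 40); lab2 <- lab
  far <- RegionMaskSet(list(EC = matrix(FALSE, 40, 40)), px)
  far@masks$EC[1, 1] <- TRUE
  lone <- new("NucleiLabels", labels = {m <- matrix(0L, 40, 40); m[30, 30] <- 1L; m},
              table = data.frame(id = 1L, area_um2 = 1, cx = 30, cy = 30,
                                 apoptotic = NA), pixelSize = px)
  expect_equal(unname(assignNucleiToRegions(lone, far)["EC"]), 0L)
  # brute-force oracle: incidence equals direct pixel intersection with the
  # brute-dilated masks, and a nucleus may count for both markers
  set.seed(42)
  lab3 <- matrix(0L, 24, 24); lab3[10:12, 10:12] <- 1L
  ec3 <- matrix(FALSE, 24, 24); ec3[1:9, ] <- TRUE
  pc3 <- matrix(FALSE, 24, 24); pc3[13:24, ] <- TRUE
  r3 <- RegionMaskSet(list(EC = ec3, pericyte = pc3), px)
  n3 <- new("NucleiLabels", labels = lab3,
            table = data.frame(id = 1L, area_um2 = 9, cx = 11, cy = 11,
                               apoptotic = NA), pixelSize = px)
  cnt3 <- assignNucleiToRegions(n3, r3)
  expect_equal(unname(cnt3["EC"]),
               as.integer(any(lab3 > 0 & brute_dilate(ec3, 3, px))))
  expect_equal(unname(cnt3["pericyte"]),
               as.integer(any(lab3 > 0 & brute_dilate(pc3, 2, px))))
  expect_equal(unname(cnt3), c(1L, 1L))  # counted for both
})

test_that("pericyte coverage uses a 5 µm border on the EC region", {
  px <- c(1, 1)
  ec <- matrix(FALSE, 40, 40); ec[15:25, 15:25] <- TRUE
  # pericyte fully inside EC: coverage equals the pericyte area
  peri_in <- matrix(FALSE, 40, 40); peri_in[17:20, 17:20] <- TRUE
  r <- RegionMaskSet(list(EC = ec, pericyte = peri_in), px)
  expect_equal(pericyteCoverage(r), sum(peri_in) * 1)
  # a band exactly 4 µm outside the boundary is fully counted
  ring <- matrix(FALSE, 40, 40); ring[29, 15:25] <- TRUE  # 4 px beyond x=25
  r2 <- RegionMaskSet(list(EC = ec, pericyte = ring), px)
  expect_equal(pericyteCoverage(r2), sum(ring) * 1)
  # disjoint by more than 6 µm: zero
  far <- matrix(FALSE, 40, 40); far[33:35, 15:25] <- TRUE
  r3 <- RegionMaskSet(list(EC = ec, pericyte = far), px)
  expect_equal(pericyteCoverage(r3), 0)
  expect_error(pericyteCoverage(RegionMaskSet(list(EC = ec), px)), "missing")
})

test_that("ghost fraction is the avascular share of the ECM area", {
  px <- c(1, 1)
  ecm <- matrix(FALSE, 20, 20); ecm[1:10, 1:10] <- TRUE          # 100 px
  ec <- matrix(FALSE, 20, 20); ec[1:6, 1:10] <- TRUE             # 60 in ECM
  r <- RegionMaskSet(list(EC = ec, ECM = ecm), px)
  expect_equal(ghostVesselFraction(r), 0.40)
  expect_equal(ghostVesselFraction(
    RegionMaskSet(list(EC = matrix(TRUE, 20, 20), ECM = ecm), px)), 0)
  expect_equal(ghostVesselFraction(
    RegionMaskSet(list(EC = matrix(FALSE, 20, 20), ECM = ecm), px)), 1)
  expect_error(ghostVesselFraction(
    RegionMaskSet(list(EC = ec, ECM = matrix(FALSE, 20, 20)), px)),
    "undefined-fraction")
})

test_that("apoptosis co-localization reports per-marker counts and viability", {
  px <- c(1, 1)
  lab <- matrix(0L, 30, 30)
  tb <- data.frame(id = integer(), area_um2 = numeric(), cx = numeric(),
                   cy = numeric(), apoptotic = logical())
  k <- 0L
  for (x in seq(2, 29, by = 3)) for (y in seq(2, 29, by = 3)) {
    if (k >= 100L) break
    k <- k + 1L
    lab[x, y] <- k
    tb <- rbind(tb, data.frame(id = k, area_um2 = 1, cx = x, cy = y,
                               apoptotic = k <= 5))
  }
  nuc <- new("NucleiLabels", labels = lab, table = tb, pixelSize = px)
  regions <- RegionMaskSet(list(EC = matrix(TRUE, 30, 30)), px)
  res <- apoptosisColocalization(nuc, regions)
  expect_equal(res$viability, 1 - 5 / k)
  expect_equal(unname(res$apoptotic_counts["EC"]), 5L)
  empty <- new("NucleiLabels", labels = matrix(0L, 5, 5),
               table = tb[0, ], pixelSize = px)
  expect_error(apoptosisColocalization(empty, regions),
               "undefined-viability")
})

test_that("area metrics agree with brute-force pixel counting on toy masks", {
  px <- c(1.3, 0.9)
  for (seed in 1:6) {
    m <- random_masks(seed)
    r <- RegionMaskSet(list(EC = m$a, pericyte = m$b, ECM = m$b), px)
    pxa <- prod(px)
    # ghost fraction: direct counting
    expect_equal(ghostVesselFraction(r), sum(m$b & !m$a) / sum(m$b))
    # coverage: brute-force disk dilation oracle
    expect_equal(pericyteCoverage(r),
                 sum(m$b & brute_dilate(m$a, 5, px)) * pxa)
  }
})

test_that("growing the EC mask moves coverage up and ghost fraction down", {
  px <- c(1, 1)
  m <- random_masks(11)
  ec_small <- m$a & matrix(rep(c(TRUE, FALSE), 12 * 24), 24, 24)
  ec_big <- m$a
  for (masks in list(c("small", "big"))) {
    r_s <- RegionMaskSet(list(EC = ec_small, pericyte = m$b, ECM = m$b), px)
    r_b <- RegionMaskSet(list(EC = ec_big, pericyte = m$b, ECM = m$b), px)
    expect_gte(pericyteCoverage(r_b), pericyteCoverage(r_s))
    expect_lte(ghostVesselFraction(r_b), ghostVesselFraction(r_s))
  }
})

test_that("noise-free scenes are recovered within 5% by the MIP pipeline", {
  sc <- small_scene("control_D7", seed = 8, noise = noise_off)
  m <- quantifyMip(sc)
  tr <- realizedFractions(sc)
  dom_area <- prod(dim(sceneTruth(sc)$vesselMask)[1:2]) *
    prod(voxelSize(sc)[1:2])
  expect_lt(abs(m$vascular_area / dom_area - tr["vascular_area_fraction"]) /
            tr["vascular_area_fraction"], 0.05)
  expect_lt(abs(m$coverage_fraction - tr["coverage_fraction"]) /
            tr["coverage_fraction"], 0.05)
  expect_lt(abs(m$ghost_fraction - tr["ghost_fraction"]) /
            tr["ghost_fraction"], 0.05)
  # nuclei and apoptosis flags recover the generator's truth exactly
  tt <- sceneTruth(sc)$nucleiTable
  expect_equal(m$nuclei_total, nrow(tt))
  expect_equal(m$apoptotic_total, sum(tt$apoptotic))
  expect_equal(m$viability, 1 - mean(tt$apoptotic))
})
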