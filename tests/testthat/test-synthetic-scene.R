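# Synthetic scene generator: determinism, target realization, ghost
# geometry, noise model and preset registry.

test_that("vessel graphs hit their MIP area target and are deterministic", {
  dom <- c(240, 120, 60)
  g1 <- buildVesselGraph(dom, 0.30, seed = 7, radiusMedian = 8,
                         radiusRange = c(4, 16))
  g2 <- buildVesselGraph(dom, 0.30, seed = 7, radiusMedian = 8,
                         radiusRange = c(4, 16))
  expect_identical(g1@nodes, g2@nodes)
  expect_identical(g1@edges, g2@edges)
  # rendered MIP fraction within ±5% of target
  dims <- c(as.integer(dom[1:2] / 0.6), 10L)
  e <- g1@edges
  mask <- array(mvnquant:::cpp_capsule_mask(
    c(dims[1:2], 1L), c(0.6, 0.6, 1),
    g1@nodes[e$from, 1:2, drop = FALSE] |> cbind(0.5),
    g1@nodes[e$to, 1:2, drop = FALSE] |> cbind(0.5), e$radius), dims[1:2])
  expect_gt(mean(mask), 0.30 * 0.95)
  expect_lt(mean(mask), 0.30 * 1.05)
  # all edges lumenized, connected as one network, radii positive
  expect_false(any(g1@edges$ghost))
  expect_true(mvnquant:::.lumen_connected(g1))
  expect_true(all(g1@edges$radius > 0))
})

test_that("unreachable vessel density raises a density-infeasible error", {
  expect_error(buildVesselGraph(c(200, 100, 50), 0.85, seed = 1,
                                radiusMedian = 6, radiusRange = c(4, 8),
                                maxEdges = 4L),
               "density-infeasible")
  expect_error(buildVesselGraph(c(200, 100, 50), 0.95, seed = 1),
               "targetAreaFraction")
})

test_that("scenes are bit-identical for identical preset and seed", {
  s1 <- renderScene("control_D7", seed = 5, dims = c(96, 64, 8),
                    radiusMedian = 7, radiusRange = c(4, 12))
  s2 <- renderScene("control_D7", seed = 5, dims = c(96, 64, 8),
                    radiusMedian = 7, radiusRange = c(4, 12))
  expect_identical(channelVoxels(s1, "endothelium"),
                   channelVoxels(s2, "endothelium"))
  expect_identical(sceneTruth(s1)$nucleiTable, sceneTruth(s2)$nucleiTable)
  expect_identical(realizedFractions(s1), realizedFractions(s2))
})

test_that("realized truth fractions stay within the ±5% realization band", {
  for (preset in c("control_D7", "control_D28", "diabetic_D28")) {
    sc <- small_scene(preset, seed = 2)
    p <- scenePreset(sc)
    target <- c(p@vascularAreaFraction, p@coverageFraction, p@ghostFraction)
    expect_lt(max(abs(realizedFractions(sc) - target) / target), 0.05,
              label = paste("relative realization error for", preset))
  }
})

test_that("ghost masks exclude the vessel and vanish at ghost fraction 0", {
  sc <- small_scene("control_D7", seed = 3)
  tr <- sceneTruth(sc)
  expect_false(any(tr$ghostMask & tr$vesselMask))
  expect_true(all(tr$colIVMask[tr$ghostMask]))
  # a zero-ghost preset renders an empty ghost mask
  p0 <- mvnquant:::.make_preset("no_ghost", 0.25, 0.5, 0, astro = 5L)
  sc0 <- renderScene(p0, seed = 1, dims = c(160, 96, 12),
                     radiusMedian = 8, radiusRange = c(4, 16))
  expect_identical(sum(sceneTruth(sc0)$ghostMask), 0L)
  expect_identical(sceneTruth(sc0)$colIVMask, sceneTruth(sc0)$vesselMask)
})

test_that("with noise off, rendered channels equal the truth intensities", {
  sc <- small_scene("control_D7", seed = 4, noise = noise_off)
  tr <- sceneTruth(sc)
  expect_identical(channelVoxels(sc, "endothelium"),
                   array(15000 * tr$vesselMask, dim(tr$vesselMask)))
  expect_identical(channelVoxels(sc, "colIV"),
                   array(15000 * tr$colIVMask, dim(tr$colIVMask)))
})

test_that("preset registry encodes the printed condition effect sizes", {
  d7 <- getPreset("control_D7")
  expect_equal(getPreset("control_D14")@vascularAreaFraction /
               d7@vascularAreaFraction, 0.70, tolerance = 1e-10)
  expect_equal(getPreset("diabetic_D28")@vascularAreaFraction /
               d7@vascularAreaFraction, 0.30, tolerance = 1e-10)
  expect_equal(d7@coverageFraction /
               getPreset("diabetic_D28")@coverageFraction, 3, tolerance = 1e-10)
  expect_equal(getPreset("diabetic_D28")@ghostFraction / d7@ghostFraction,
               1.6, tolerance = 1e-10)
  expect_equal(getPreset("diabetic_D28")@ghostFraction /
               getPreset("control_D28")@ghostFraction, 1.3, tolerance = 1e-10)
  expect_equal(getPreset("tnf_24h")@leakPermeability /
               getPreset("untreated")@leakPermeability, 4.7, tolerance = 1e-10)
  expect_error(getPreset("no_such_condition"), "unknown preset")
})

test_that("noise-free perfusion series are exactly affine in time", {
  sc <- small_scene("untreated", seed = 6, noise = noise_off)
  ps <- simulatePerfusion(sc, times = c(0, 5, 10, 15), noise = noise_off)
  vm <- vesselMask(ps)
  means <- vapply(ps@frames, function(f) mean(f[!vm]), 0)
  fit <- lm(means ~ ps@times)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_gt(coef(fit)[2], 0)
  # ghost vessels carry no tracer: tracer-positive pixels at t0 are vessel
  f0 <- ps@frames[[1]]
  expect_true(all(xor(f0 > 5000, !vm)))
})
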