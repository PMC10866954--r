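# Study-level reporting: normalization, ANOVA + Sidak, pipeline
# reproducibility and config validation.

test_that("normalization to control self-normalizes the control group", {
  tb <- data.frame(condition = rep(c("ctrl", "trt"), each = 4),
                   day = "D7", v = c(8, 10, 12, 10, 4, 5, 6, 5))
  out <- normalizeToControl(tb, "v", "ctrl", "D7")
  expect_equal(mean(out$v_pct_control[out$condition == "ctrl"]), 100)
  expect_equal(mean(out$v_pct_control[out$condition == "trt"]), 50)
  expect_error(normalizeToControl(tb, "v", "absent"), "empty control")
  tb0 <- tb; tb0$v[tb0$condition == "ctrl"] <- 0
  expect_error(normalizeToControl(tb0, "v", "ctrl"), "zero")
})

test_that("ANOVA with Sidak adjustment behaves at its edge cases", {
  set.seed(1)
  # identical groups: F ~ 0, p ~ 1
  tb <- data.frame(condition = rep(c("a", "b"), each = 6),
                   v = rep(c(1, 2, 3, 1, 2, 3), 2))
  st <- groupStats(tb, "v")
  expect_lt(st$anova$F, 1e-10)
  expect_gt(st$anova$p, 0.99)
  # two groups: Sidak-adjusted p equals the unadjusted p
  tb2 <- data.frame(condition = rep(c("a", "b"), each = 8),
                    v = rnorm(16))
  st2 <- groupStats(tb2, "v")
  expect_equal(st2$pairwise$p_sidak, st2$pairwise$p)
  # three groups: m = 3 comparisons, adjusted >= raw
  tb3 <- data.frame(condition = rep(c("a", "b", "c"), each = 6),
                    v = rnorm(18))
  st3 <- groupStats(tb3, "v")
  expect_equal(nrow(st3$pairwise), 3L)
  expect_true(all(st3$pairwise$p_sidak >= st3$pairwise$p - 1e-12))
  expect_equal(st3$pairwise$p_sidak, 1 - (1 - st3$pairwise$p)^3,
               tolerance = 1e-12)
  expect_error(groupStats(tb3[c(1, 7, 8, 13, 14), ], "v"),
               "degenerate group sizes")
})

test_that("the simulated-null rejection rate is near the nominal level", {
  set.seed(99)
  rej <- 0L; reps <- 400L
  for (i in seq_len(reps)) {
    tb <- data.frame(condition = rep(c("a", "b"), each = 10),
                     v = rnorm(20))
    rej <- rej + (min(groupStats(tb, "v")$pairwise$p_sidak) < 0.05)
  }
  expect_gt(rej / reps, 0.025)
  expect_lt(rej / reps, 0.075)
})

test_that("the pipeline runs self-contained, reproducibly, and validates", {
  cfg <- list(seed = 3, output_dir = file.path(tempdir(), "pipe_a"),
              scene = list(dims = c(128, 96, 10), radius_median = 8,
                           radius_range = c(4, 16)),
              conditions = list(
                list(label = "c7", preset = "control_D7", day = "D7", n = 2),
                list(label = "d28", preset = "diabetic_D28", day = "D28",
                     n = 2)),
              metrics = list("vascular_area", "ghost_fraction"),
              normalize = list(metric = "vascular_area", control = "c7"),
              stats = list(metric = "vascular_area"))
  tab <- runPipeline(cfg)
  expect_equal(nrow(tab), 4L)
  expect_true(file.exists(file.path(cfg$output_dir, "study_table.csv")))
  expect_true(file.exists(file.path(cfg$output_dir, "run_manifest.json")))
  expect_true(file.exists(file.path(cfg$output_dir, "pairwise_stats.csv")))
  # bit-identical rerun from the same config
  csv1 <- readLines(file.path(cfg$output_dir, "study_table.csv"))
  runPipeline(cfg)
  csv2 <- readLines(file.path(cfg$output_dir, "study_table.csv"))
  expect_identical(csv1, csv2)
  # a YAML config on disk behaves like the list
  yml <- tempfile(fileext = ".yaml")
  cfg2 <- cfg; cfg2$output_dir <- file.path(tempdir(), "pipe_b")
  yaml::write_yaml(cfg2, yml)
  tab2 <- runPipeline(yml)
  expect_equal(tab2$vascular_area, tab$vascular_area)
  # requesting ghost metrics without a COL IV channel fails validation
  sc <- small_scene("control_D7", seed = 1, dims = c(96L, 64L, 8L))
  st <- sc@stack
  st2 <- ChannelStack(st@voxels["endothelium"], voxelSize(st),
                      c(endothelium = 1L))
  f <- tempfile(fileext = ".tif")
  writeStack(st2, f)
  bad <- list(seed = 1, output_dir = tempdir(),
              conditions = list(list(label = "x", path = f)),
              metrics = list("ghost_fraction"))
  expect_error(runPipeline(bad), "colIV")
})
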