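# Shared fixtures: small seeded scenes (cached per test run) and common
# oracles. Small grids use proportionally smaller vessel radii so the
# preset area fractions stay reachable.

noise_off <- list(gaussian_sd = 0, poisson_scale = 0, background_slope = 0)

.scene_cache <- new.env(parent = emptyenv())

small_scene <- function(preset = "control_D7", seed = 1, noise = NULL,
                        dims = c(160L, 96L, 12L)) {
  key <- paste(preset, seed, paste(dims, collapse = "x"),
               paste(unlist(noise), collapse = ","))
  if (!exists(key, envir = .scene_cache))
    assign(key, renderScene(preset, seed = seed, dims = dims, noise = noise,
                            radiusMedian = 8, radiusRange = c(4, 16)),
           envir = .scene_cache)
  get(key, envir = .scene_cache)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# independent brute-force disk dilation: pixel is set when any mask pixel
# lies within radius r (µm), by direct distance checking
brute_dilate <- function(mask, r_um, px) {
  d <- dim(mask)
  pts <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, d[1], d[2])
  if (!nrow(pts)) return(out)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    dd <- sqrt(((x - pts[, 1]) * px[1])^2 + ((y - pts[, 2]) * px[2])^2)
    out[x, y] <- any(dd <= r_um)
  }
  out
}

# random small mask pair generator for oracle-equivalence sweeps
random_masks <- function(seed, n = 24L) {
  set.seed(seed)
  list(a = matrix(runif(n * n) < runif(1, 0.2, 0.7), n, n),
       b = matrix(runif(n * n) < runif(1, 0.2, 0.7), n, n))
}
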