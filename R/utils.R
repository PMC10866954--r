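# Internal helpers shared across modules. All physical units are µm unless
# stated otherwise; arrays are (x, y, z) with voxel centers at
# (i - 0.5) * spacing for 1-based index i.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps scene generation deterministic without
# clobbering the user's RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

dims_of <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array")
  if (length(d) == 2L) c(d, 1L) else d
}

# Euclidean distance (physical units) from every voxel to the nearest TRUE
# voxel; Inf when the mask is empty.
edt <- function(mask, spacing = c(1, 1, 1)) {
  d <- dims_of(mask)
  out <- cpp_edt_sq(as.logical(mask), as.integer(d), as.numeric(spacing[seq_along(d)]))
  array(sqrt(out), dim = dim(mask))
}

# Binary dilation/erosion by a Euclidean ball of physical radius r.
dilate_um <- function(mask, r, spacing = c(1, 1)) {
  if (r <= 0) return(mask)
  edt(mask, spacing) <= r
}
erode_um <- function(mask, r, spacing = c(1, 1)) {
  if (r <= 0) return(mask)
  !(edt(!mask, spacing) <= r)
}

# Binary dilation with a cubic structuring element (independent ±r voxels in
# x, y and z), via separable box convolution.
dilate_cube_px <- function(mask, r) {
  if (r <= 0) return(mask)
  d <- dims_of(mask)
  k <- rep(1, 2L * r + 1L)
  kz <- if (d[3] > 1L) k else 1
  s <- cpp_sepconv(as.numeric(mask), as.integer(d), k, k, kz)
  array(s > 0.5, dim = dim(mask))
}

gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing; sigma is in pixels per axis (length 1 or 3).
gaussian_smooth <- function(x, sigma) {
  d <- dims_of(x)
  sigma <- rep(sigma, length.out = 3L)
  out <- cpp_sepconv(as.numeric(x), as.integer(d),
                     gaussian_kernel(sigma[1]), gaussian_kernel(sigma[2]),
                     if (d[3] > 1L) gaussian_kernel(sigma[3]) else 1)
  array(out, dim = dim(x))
}

# Maximum projection over z that avoids apply()'s copy-per-pixel cost.
mip_of <- function(arr) {
  d <- dim(arr)
  if (length(d) == 2L) return(arr)
  out <- arr[, , 1L]
  if (d[3] > 1L) for (z in 2L:d[3]) out <- pmax(out, arr[, , z])
  if (is.logical(arr)) out <- out > 0   # pmax() coerces logical to numeric
  out
}
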