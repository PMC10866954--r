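# Tracer perfusion: forward simulation of extravascular dextran leakage at
# a prescribed apparent permeability, perfusability of a vessel mask, and
# the inverse estimator for the apparent permeability coefficient.
#
# Model (cylindrical lumen convention): the mean extravascular intensity
# rises linearly,
#   I_t(t) = I_t(0) + P * (4 / d) * (I_v - I_bg) * t,
# with P in cm/s, mean lumen diameter d in cm and t in seconds; the
# estimator inverts this between two frames (default t = 5 and 15 min).

#' Simulate a tracer perfusion time-lapse
#'
#' Generates 2D tracer MIP frames over the lumenized vessel mask of a
#' synthetic scene: constant intravascular intensity, extravascular
#' intensity growing linearly with time according to the prescribed
#' apparent permeability and the scene's mean lumen diameter. Ghost
#' vessels carry no tracer. The scene's noise model is applied per frame
#' unless overridden.
#'
#' @param scene a [SyntheticScene-class].
#' @param leakPermeability apparent permeability in cm/s; default the
#'   scene preset's.
#' @param times frame times in minutes, ascending, at least two (default
#'   `c(0, 5, 10, 15)`).
#' @param vesselIntensity,backgroundIntensity intravascular and background
#'   intensity levels (arbitrary units).
#' @param noise noise-model override; `NULL` uses the scene preset's.
#' @return a [PerfusionSeries-class].
#' @examples
#' sc <- renderScene("untreated", seed = 1, dims = c(96, 64, 8))
#' ps <- simulatePerfusion(sc, noise = list(gaussian_sd = 0,
#'   poisson_scale = 0, background_slope = 0))
#' pApp(estimatePermeability(ps))
#' @export
simulatePerfusion <- function(scene, leakPermeability = NULL,
                              times = c(0, 5, 10, 15),
                              vesselIntensity = 12000,
                              backgroundIntensity = 500, noise = NULL) {
  stopifnot(is(scene, "SyntheticScene"))
  if (is.null(leakPermeability))
    leakPermeability <- scene@preset@leakPermeability
  if (leakPermeability < 0) stop("leakPermeability must be >= 0")
  if (length(times) < 2L || is.unsorted(times, strictly = TRUE))
    stop("times must be >= 2 ascending values (minutes)")
  if (is.null(noise)) noise <- scene@preset@noise
  vm2 <- mip_of(scene@truth$vesselMask)
  if (!any(vm2)) stop("no-vessel: empty vessel mask")
  d_cm <- meanDiameter(scene) * 1e-4
  rate <- leakPermeability * (4 / d_cm) *
    (vesselIntensity - backgroundIntensity)      # intensity per second
  frames <- lapply(times, function(t) {
    f <- matrix(backgroundIntensity + rate * t * 60, nrow(vm2), ncol(vm2))
    f[vm2] <- vesselIntensity
    .apply_noise(f, noise)
  })
  px <- voxelSize(scene)[1:2]
  bg_mask <- !dilate_um(vm2, 10 * px[1], px)   # outside mask + 10 px margin
  bg <- if (any(bg_mask)) mean(frames[[1]][bg_mask]) else backgroundIntensity
  new("PerfusionSeries", times = as.numeric(times), frames = frames,
      vesselMask = vm2, backgroundValue = bg, pixelSize = px,
      meanDiameter = meanDiameter(scene))
}

#' Perfusability: percentage of vessel area reached by tracer
#'
#' Thresholds the tracer MIP at a fraction of the clipped display range and
#' reports the tracer-positive fraction of the vessel mask as a percentage.
#'
#' @param tracerMip numeric matrix (tracer MIP, raw intensities).
#' @param vesselMask logical matrix on the same grid.
#' @param tracerThreshold fractional threshold in (0, 1), default 0.25.
#' @param clipMax display-range clip, default 20000.
#' @return percentage in `[0, 100]`.
#' @examples
#' vm <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' perfusability(matrix(c(2e4, 0, 0, 0), 2), vm)  # 50
#' @export
perfusability <- function(tracerMip, vesselMask, tracerThreshold = 0.25,
                          clipMax = 20000) {
  if (!identical(dim(tracerMip), dim(vesselMask)))
    stop("tracer image and vessel mask are on different grids")
  if (tracerThreshold <= 0 || tracerThreshold >= 1)
    stop("tracerThreshold must lie in (0, 1)")
  if (!any(vesselMask)) stop("undefined: empty vessel mask")
  tr <- (pmin(pmax(tracerMip, 0), clipMax) / clipMax) >= tracerThreshold
  100 * sum(tr & vesselMask) / sum(vesselMask)
}

#' Estimate the apparent permeability coefficient
#'
#' Inverts the linear leakage model between two frames:
#' `P = ((I_t(t2) - I_t(t1)) / (I_v(t1) - I_bg)) * (1 / (t2 - t1)) * (d / 4)`
#' with the mean extravascular intensity `I_t` (outside the vessel mask),
#' the mean intravascular intensity `I_v`, background `I_bg` from the first
#' frame outside the 10 px-dilated mask, times in seconds and the mean
#' lumen diameter `d` in cm. A negative extravascular increase clamps to
#' `P = 0` with the `clamped` flag set.
#'
#' With `geometry = "mask"` the lumen-geometry factor `d/4` is replaced by
#' the volume-to-surface ratio `V/S` of a segmented 3D vessel mask.
#'
#' @param series a [PerfusionSeries-class].
#' @param t1,t2 frame times in minutes (defaults 5 and 15).
#' @param meanDiameterUm mean lumen diameter in µm; defaults to the one
#'   carried by the series.
#' @param geometry `"diameter"` (default) or `"mask"`.
#' @param vesselMask3d a [VesselMask3D-class], required for
#'   `geometry = "mask"`.
#' @return a [PermeabilityEstimate-class].
#' @export
estimatePermeability <- function(series, t1 = 5, t2 = 15,
                                 meanDiameterUm = NULL,
                                 geometry = c("diameter", "mask"),
                                 vesselMask3d = NULL) {
  stopifnot(is(series, "PerfusionSeries"))
  geometry <- match.arg(geometry)
  if (t2 <= t1) stop("t2 must exceed t1")
  i1 <- match(t1, series@times); i2 <- match(t2, series@times)
  if (is.na(i1) || is.na(i2))
    stop("missing frame at t = ", if (is.na(i1)) t1 else t2, " min")
  vm <- series@vesselMask
  f1 <- series@frames[[i1]]; f2 <- series@frames[[i2]]
  iv1 <- mean(f1[vm])
  it1 <- mean(f1[!vm]); it2 <- mean(f2[!vm])
  ibg <- series@backgroundValue
  if (iv1 <= ibg)
    stop("invalid-contrast: vessel intensity does not exceed background")
  geom_cm <- if (geometry == "diameter") {
    d <- if (!is.null(meanDiameterUm)) meanDiameterUm else series@meanDiameter
    if (!is.finite(d) || d <= 0)
      stop("mean lumen diameter unavailable; pass meanDiameterUm")
    d * 1e-4 / 4
  } else {
    if (is.null(vesselMask3d)) stop("geometry = 'mask' needs vesselMask3d")
    m <- vesselMask3d@mask
    vsz <- vesselMask3d@voxelSize
    vol <- sum(m) * prod(vsz)
    surf <- .surface_area_um2(m, vsz)
    if (surf <= 0) stop("degenerate vessel surface")
    (vol / surf) * 1e-4
  }
  num <- it2 - it1
  clamped <- num < 0
  if (clamped) {
    warning("extravascular intensity decreased; clamping P to 0")
    num <- 0
  }
  p <- (num / (iv1 - ibg)) / ((t2 - t1) * 60) * geom_cm
  d_used <- if (geometry == "diameter") {
    if (!is.null(meanDiameterUm)) meanDiameterUm else series@meanDiameter
  } else 4 * geom_cm * 1e4
  new("PermeabilityEstimate", pApp = p, t1 = t1, t2 = t2,
      meanDiameter = d_used,
      intensities = c(vessel_t1 = iv1, tissue_t1 = it1, tissue_t2 = it2,
                      background = ibg),
      clamped = clamped)
}

# total exposed voxel-face area of a 3D mask, µm²
.surface_area_um2 <- function(mask, vs) {
  d <- dims_of(mask)
  m <- array(as.logical(mask), d)
  shift <- function(ax, dir) {
    out <- array(FALSE, d)
    if (ax == 1) { if (dir > 0) out[-1, , ] <- m[-d[1], , ] else out[-d[1], , ] <- m[-1, , ] }
    if (ax == 2) { if (dir > 0) out[, -1, ] <- m[, -d[2], ] else out[, -d[2], ] <- m[, -1, ] }
    if (ax == 3) { if (dir > 0) out[, , -1] <- m[, , -d[3]] else out[, , -d[3]] <- m[, , -1] }
    out
  }
  face <- c(vs[2] * vs[3], vs[1] * vs[3], vs[1] * vs[2])
  s <- 0
  for (ax in 1:3) for (dir in c(-1, 1))
    s <- s + sum(m & !shift(ax, dir)) * face[ax]
  s
}
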