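#' @useDynLib mvnquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rpois runif rlnorm aov pt sd median quantile
#' @importFrom utils write.csv head
NULL

#' ChannelStack: a calibrated multi-channel 3D image
#'
#' Container for a multi-channel confocal stack: one 3D voxel array per
#' channel, the physical voxel size in µm, and a map from biological channel
#' roles (e.g. `"endothelium"`, `"pericyte"`, `"colIV"`, `"nuclei"`) to
#' channel indices.
#'
#' @slot voxels list of 3D numeric arrays, all with identical dimensions
#'   `(nx, ny, nz)`; intensities are arbitrary units.
#' @slot voxelSize numeric(3), voxel edge lengths in µm `(x, y, z)`.
#' @slot channelRoles named integer vector mapping role to channel index.
#' @slot provenance free-text metadata (acquisition notes, file origin).
#'
#' @examples
#' st <- ChannelStack(list(a = array(0, c(4, 4, 2))), c(0.6, 0.6, 5),
#'                    c(endothelium = 1L))
#' channelRoles(st)
#' @export
setClass("ChannelStack", representation(
  voxels = "list", voxelSize = "numeric", channelRoles = "integer",
  provenance = "character"))

setValidity("ChannelStack", function(object) {
  if (length(object@voxels) == 0L) return("no channels")
  dims <- lapply(object@voxels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) return("channels must be 3D arrays")
  if (length(unique(dims)) != 1L) return("channels must share dimensions")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive values (µm)")
  if (length(object@channelRoles)) {
    if (is.null(names(object@channelRoles))) return("channelRoles must be named")
    if (any(object@channelRoles < 1L | object@channelRoles > length(object@voxels)))
      return("channelRoles maps to a missing channel")
  }
  TRUE
})

#' @rdname ChannelStack-class
#' @param voxels,voxelSize,channelRoles,provenance see slots.
#' @export
ChannelStack <- function(voxels, voxelSize, channelRoles = NULL,
                         provenance = character()) {
  if (is.null(channelRoles)) {
    channelRoles <- seq_along(voxels)
    names(channelRoles) <- names(voxels)
  }
  new("ChannelStack", voxels = voxels, voxelSize = as.numeric(voxelSize),
      channelRoles = structure(as.integer(channelRoles),
                               names = names(channelRoles)),
      provenance = provenance)
}

#' VesselGraph: a 3D vessel centerline network
#'
#' Nodes are 3D points (µm) inside an axis-aligned box domain; edges carry a
#' radius (µm) and a ghost flag. Ghost edges model basement-membrane sleeves
#' that have lost their endothelium (COL IV+ / UEA I-); an edge is either
#' lumenized or ghost, never both.
#'
#' @slot nodes numeric matrix (n x 3) of node coordinates in µm.
#' @slot edges data.frame with columns `from`, `to` (node indices), `radius`
#'   (µm) and `ghost` (logical).
#' @slot domain numeric(3), box extents in µm (origin at 0).
#' @export
setClass("VesselGraph", representation(
  nodes = "matrix", edges = "data.frame", domain = "numeric"))

setValidity("VesselGraph", function(object) {
  n <- object@nodes
  if (ncol(n) != 3L) return("nodes must be n x 3")
  if (length(object@domain) != 3L || any(object@domain <= 0))
    return("domain must be 3 positive extents (µm)")
  if (nrow(n) && (any(n < -1e-9) || any(sweep(n, 2, object@domain) > 1e-9)))
    return("node coordinates outside domain")
  e <- object@edges
  need <- c("from", "to", "radius", "ghost")
  if (!all(need %in% names(e))) return("edges need from/to/radius/ghost")
  if (nrow(e) && any(e$radius <= 0)) return("edge radii must be > 0")
  if (nrow(e) && (any(e$from < 1 | e$from > nrow(n) | e$to < 1 | e$to > nrow(n))))
    return("edge endpoints out of range")
  TRUE
})

#' ScenePreset: condition-level ground-truth parameters
#'
#' Immutable bundle of target fractions and noise parameters for one
#' experimental condition of the synthetic scene generator. Registered
#' presets encode the relative effect sizes between control and diabetic
#' culture conditions (vascular regression, pericyte coverage loss, ghost
#' vessel accumulation) and the TNF-alpha permeability increase.
#'
#' @slot name condition label.
#' @slot vascularAreaFraction target endothelial (UEA I+) area fraction of
#'   the MIP, dimensionless.
#' @slot coverageFraction target pericyte coverage area / vascular area.
#' @slot ghostFraction target avascular COL IV area / total COL IV area.
#' @slot astrocyteCount integer number of astrocyte bodies.
#' @slot apoptoticFractionEC,apoptoticFractionPC apoptotic nucleus fractions.
#' @slot leakPermeability tracer apparent permeability, cm s^-1.
#' @slot noise list with `gaussian_sd` (intensity units), `poisson_scale`
#'   (photon gain; 0 disables shot noise) and `background_slope` (fraction
#'   of the display range ramped across x).
#' @export
setClass("ScenePreset", representation(
  name = "character", vascularAreaFraction = "numeric",
  coverageFraction = "numeric", ghostFraction = "numeric",
  astrocyteCount = "integer", apoptoticFractionEC = "numeric",
  apoptoticFractionPC = "numeric", leakPermeability = "numeric",
  noise = "list"))

setValidity("ScenePreset", function(object) {
  fr <- c(object@vascularAreaFraction, object@coverageFraction,
          object@ghostFraction, object@apoptoticFractionEC,
          object@apoptoticFractionPC)
  if (any(fr < 0 | fr > 1)) return("fractions must be in [0, 1]")
  if (object@leakPermeability < 0) return("leakPermeability must be >= 0")
  need <- c("gaussian_sd", "poisson_scale", "background_slope")
  if (!all(need %in% names(object@noise))) return("incomplete noise model")
  TRUE
})

#' SyntheticScene: a rendered scene with ground truth
#'
#' A rendered [ChannelStack-class] plus the noise-free truth masks, the
#' nuclei table with cell-type tags, the generating [VesselGraph-class] and
#' the realized (as opposed to target) truth fractions.
#'
#' @slot stack the rendered [ChannelStack-class].
#' @slot truth list: `vesselMask`, `pericyteMask`, `astrocyteMask`,
#'   `colIVMask`, `ghostMask` (3D logical), `nucleiLabels` (3D integer) and
#'   `nucleiTable` (data.frame: id, type, x, y, z µm, apoptotic).
#' @slot graph the generating [VesselGraph-class] (ghost flags final).
#' @slot preset the [ScenePreset-class] used.
#' @slot seed integer seed.
#' @slot realized named numeric: realized `vascular_area_fraction`,
#'   `coverage_fraction`, `ghost_fraction` measured on the truth masks.
#' @export
setClass("SyntheticScene", representation(
  stack = "ChannelStack", truth = "list", graph = "VesselGraph",
  preset = "ScenePreset", seed = "integer", realized = "numeric"))

setValidity("SyntheticScene", function(object) {
  t <- object@truth
  need <- c("vesselMask", "pericyteMask", "astrocyteMask", "colIVMask",
            "ghostMask", "nucleiLabels", "nucleiTable")
  if (!all(need %in% names(t))) return("incomplete truth list")
  d <- dim(t$vesselMask)
  for (m in c("pericyteMask", "astrocyteMask", "colIVMask", "ghostMask"))
    if (!identical(dim(t[[m]]), d)) return("truth masks must share the grid")
  if (any(t$ghostMask & !t$colIVMask)) return("ghostMask must be inside colIVMask")
  if (any(t$ghostMask & t$vesselMask)) return("ghostMask overlaps vesselMask")
  TRUE
})

#' RegionMaskSet: thresholded 2D marker regions
#'
#' Binary MIP masks for the four marker compartments on a common calibrated
#' 2D grid, with the fractional thresholds that produced them.
#'
#' @slot masks named list of logical matrices; names among `EC`, `pericyte`,
#'   `astrocyte`, `ECM`.
#' @slot pixelSize numeric(2), µm per pixel (x, y).
#' @slot thresholds named numeric, fraction of the clipped range per marker.
#' @export
setClass("RegionMaskSet", representation(
  masks = "list", pixelSize = "numeric", thresholds = "numeric"))

setValidity("RegionMaskSet", function(object) {
  if (!length(object@masks)) return("no masks")
  dims <- lapply(object@masks, dim)
  if (length(unique(dims)) != 1L) return("masks must share shape")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    return("pixelSize must be 2 positive values (µm)")
  if (length(object@thresholds) &&
      any(object@thresholds <= 0 | object@thresholds >= 1))
    return("thresholds must lie in (0, 1)")
  TRUE
})

#' @rdname RegionMaskSet-class
#' @param masks,pixelSize,thresholds see slots.
#' @export
RegionMaskSet <- function(masks, pixelSize, thresholds = numeric()) {
  new("RegionMaskSet", masks = masks, pixelSize = as.numeric(pixelSize),
      thresholds = thresholds)
}

#' NucleiLabels: segmented nuclei on a 2D grid
#'
#' @slot labels integer matrix; 0 background, k > 0 the k-th nucleus.
#' @slot table data.frame with `id`, `area_um2`, `cx`, `cy` (pixel centroid)
#'   and `apoptotic` (logical, may be NA until assigned).
#' @slot pixelSize numeric(2), µm per pixel.
#' @export
setClass("NucleiLabels", representation(
  labels = "matrix", table = "data.frame", pixelSize = "numeric"))

setValidity("NucleiLabels", function(object) {
  tb <- object@table
  if (!all(c("id", "area_um2", "cx", "cy", "apoptotic") %in% names(tb)))
    return("table needs id/area_um2/cx/cy/apoptotic")
  if (nrow(tb) && any(tb$area_um2 <= 0)) return("areas must be positive")
  lab <- sort(unique(as.integer(object@labels)))
  lab <- lab[lab > 0]
  if (!identical(lab, sort(as.integer(tb$id)))) return("labels and table disagree")
  TRUE
})

#' VesselMask3D: segmented vasculature with geometry summaries
#'
#' @slot mask 3D logical array.
#' @slot voxelSize numeric(3), µm.
#' @slot meanDiameter area-equivalent mean vessel diameter, µm.
#' @slot skeletonLength total centerline length, µm.
#' @export
setClass("VesselMask3D", representation(
  mask = "array", voxelSize = "numeric", meanDiameter = "numeric",
  skeletonLength = "numeric"))

setValidity("VesselMask3D", function(object) {
  if (any(object@mask) && object@meanDiameter <= 0)
    return("meanDiameter must be > 0 for a non-empty mask")
  TRUE
})

#' ObjectLabels3D: labelled 3D objects of one marker
#'
#' @slot labels 3D integer array (0 = background).
#' @slot marker marker label (`"nuclei"`, `"pericyte"`, `"astrocyte"`, ...).
#' @slot voxelSize numeric(3), µm.
#' @slot volumes numeric vector of per-object volumes (µm^3), named by label.
#' @export
setClass("ObjectLabels3D", representation(
  labels = "array", marker = "character", voxelSize = "numeric",
  volumes = "numeric"))

setValidity("ObjectLabels3D", function(object) {
  if (length(object@volumes) && any(object@volumes <= 0))
    return("object volumes must be > 0")
  TRUE
})

#' PerfusionSeries: tracer time-lapse over a vessel mask
#'
#' @slot times numeric vector of frame times in minutes, strictly increasing.
#' @slot frames list of 2D tracer MIPs matching `times`.
#' @slot vesselMask logical matrix, the perfused vessel compartment.
#' @slot backgroundValue scalar background intensity (estimated from the
#'   first frame outside the dilated vessel mask).
#' @slot pixelSize numeric(2), µm.
#' @slot meanDiameter mean lumen diameter in µm used by the permeability
#'   model (NA when unknown; pass one to [estimatePermeability()]).
#' @export
setClass("PerfusionSeries", representation(
  times = "numeric", frames = "list", vesselMask = "matrix",
  backgroundValue = "numeric", pixelSize = "numeric", meanDiameter = "numeric"))

setValidity("PerfusionSeries", function(object) {
  if (length(object@times) < 2L) return("need at least 2 frames")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (length(object@frames) != length(object@times))
    return("one frame per time point")
  d <- dim(object@vesselMask)
  for (f in object@frames)
    if (!identical(dim(f), d)) return("frames must share the mask's shape")
  TRUE
})

#' PermeabilityEstimate: apparent permeability with its inputs
#'
#' @slot pApp apparent permeability, cm s^-1.
#' @slot t1,t2 the two time points used, minutes.
#' @slot meanDiameter lumen diameter used, µm.
#' @slot intensities named numeric: `vessel_t1`, `tissue_t1`, `tissue_t2`,
#'   `background`.
#' @slot clamped TRUE when a negative extravascular increase was clamped to 0.
#' @export
setClass("PermeabilityEstimate", representation(
  pApp = "numeric", t1 = "numeric", t2 = "numeric", meanDiameter = "numeric",
  intensities = "numeric", clamped = "logical"))

setValidity("PermeabilityEstimate", function(object) {
  if (object@pApp < 0) return("pApp must be >= 0")
  if (object@t2 <= object@t1) return("t2 must exceed t1")
  TRUE
})
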