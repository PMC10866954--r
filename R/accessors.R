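#' Accessors for mvnquant classes
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `channelVoxels()` returns one channel's 3D array by role, `voxelSize()` /
#' `pixelSize()` the physical calibration, `channelRoles()` the role map,
#' `sceneTruth()` the noise-free truth list of a scene, `scenePreset()` and
#' `sceneSeed()` its generation parameters, `realizedFractions()` the truth
#' fractions actually realized, and `meanDiameter()` the mean lumen
#' diameter of a vessel mask, perfusion series or scene (µm).
#'
#' @param x an mvnquant object.
#' @param role a channel role label, e.g. `"endothelium"`.
#' @return the requested component.
#' @examples
#' st <- ChannelStack(list(dapi = array(0, c(4, 4, 2))), c(0.6, 0.6, 5),
#'                    c(nuclei = 1L))
#' voxelSize(st)
#' dim(channelVoxels(st, "nuclei"))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channelVoxels", function(x, role) standardGeneric("channelVoxels"))
#' @rdname accessors
#' @export
setMethod("channelVoxels", "ChannelStack", function(x, role) {
  if (!role %in% names(x@channelRoles))
    stop("role '", role, "' is not mapped in this stack")
  x@voxels[[x@channelRoles[[role]]]]
})
#' @rdname accessors
#' @export
setMethod("channelVoxels", "SyntheticScene", function(x, role)
  channelVoxels(x@stack, role))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "ChannelStack", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "SyntheticScene", function(x) x@stack@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "VesselMask3D", function(x) x@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "ObjectLabels3D", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))
#' @rdname accessors
#' @export
setMethod("channelRoles", "ChannelStack", function(x) x@channelRoles)
#' @rdname accessors
#' @export
setMethod("channelRoles", "SyntheticScene", function(x) x@stack@channelRoles)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "RegionMaskSet", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "NucleiLabels", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "PerfusionSeries", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setGeneric("regionMask", function(x, role) standardGeneric("regionMask"))
#' @rdname accessors
#' @export
setMethod("regionMask", "RegionMaskSet", function(x, role) {
  if (!role %in% names(x@masks)) stop("no '", role, "' mask in this set")
  x@masks[[role]]
})

#' @rdname accessors
#' @export
setGeneric("nucleiTable", function(x) standardGeneric("nucleiTable"))
#' @rdname accessors
#' @export
setMethod("nucleiTable", "NucleiLabels", function(x) x@table)
#' @rdname accessors
#' @export
setGeneric("nucleiLabels", function(x) standardGeneric("nucleiLabels"))
#' @rdname accessors
#' @export
setMethod("nucleiLabels", "NucleiLabels", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))
#' @rdname accessors
#' @export
setMethod("sceneTruth", "SyntheticScene", function(x) x@truth)
#' @rdname accessors
#' @export
setGeneric("scenePreset", function(x) standardGeneric("scenePreset"))
#' @rdname accessors
#' @export
setMethod("scenePreset", "SyntheticScene", function(x) x@preset)
#' @rdname accessors
#' @export
setGeneric("sceneSeed", function(x) standardGeneric("sceneSeed"))
#' @rdname accessors
#' @export
setMethod("sceneSeed", "SyntheticScene", function(x) x@seed)
#' @rdname accessors
#' @export
setGeneric("sceneGraph", function(x) standardGeneric("sceneGraph"))
#' @rdname accessors
#' @export
setMethod("sceneGraph", "SyntheticScene", function(x) x@graph)
#' @rdname accessors
#' @export
setGeneric("realizedFractions", function(x) standardGeneric("realizedFractions"))
#' @rdname accessors
#' @export
setMethod("realizedFractions", "SyntheticScene", function(x) x@realized)

#' @rdname accessors
#' @export
setGeneric("meanDiameter", function(x) standardGeneric("meanDiameter"))
#' @rdname accessors
#' @export
setMethod("meanDiameter", "VesselMask3D", function(x) x@meanDiameter)
#' @rdname accessors
#' @export
setMethod("meanDiameter", "PerfusionSeries", function(x) x@meanDiameter)
#' @rdname accessors
#' @export
setMethod("meanDiameter", "VesselGraph", function(x) {
  e <- x@edges[!x@edges$ghost, , drop = FALSE]
  if (!nrow(e)) return(NA_real_)
  len <- sqrt(rowSums((x@nodes[e$to, , drop = FALSE] -
                       x@nodes[e$from, , drop = FALSE])^2))
  sum(2 * e$radius * len) / sum(len)
})
#' @rdname accessors
#' @export
setMethod("meanDiameter", "SyntheticScene", function(x) meanDiameter(x@graph))

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(x) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setMethod("vesselMask", "VesselMask3D", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("vesselMask", "PerfusionSeries", function(x) x@vesselMask)

#' @rdname accessors
#' @export
setGeneric("objectVolumes", function(x) standardGeneric("objectVolumes"))
#' @rdname accessors
#' @export
setMethod("objectVolumes", "ObjectLabels3D", function(x) x@volumes)
#' @rdname accessors
#' @export
setGeneric("objectLabels", function(x) standardGeneric("objectLabels"))
#' @rdname accessors
#' @export
setMethod("objectLabels", "ObjectLabels3D", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("pApp", function(x) standardGeneric("pApp"))
#' @rdname accessors
#' @export
setMethod("pApp", "PermeabilityEstimate", function(x) x@pApp)

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@voxels[[1]])
  cat("ChannelStack:", length(object@voxels), "channel(s),",
      paste(d, collapse = " x "), "voxels\n")
  cat("  voxel size (µm):", paste(object@voxelSize, collapse = " x "), "\n")
  if (length(object@channelRoles))
    cat("  roles:", paste(names(object@channelRoles), collapse = ", "), "\n")
})

setMethod("show", "VesselGraph", function(object) {
  cat("VesselGraph:", nrow(object@nodes), "nodes,", nrow(object@edges),
      "edges (", sum(object@edges$ghost), "ghost )\n")
  cat("  domain (µm):", paste(round(object@domain, 1), collapse = " x "), "\n")
})

setMethod("show", "ScenePreset", function(object) {
  cat("ScenePreset '", object@name, "'\n", sep = "")
  cat(sprintf("  vascular %.3f | coverage %.3f | ghost %.3f | P %.2e cm/s\n",
              object@vascularAreaFraction, object@coverageFraction,
              object@ghostFraction, object@leakPermeability))
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene, preset '", object@preset@name, "', seed ",
      object@seed, "\n", sep = "")
  show(object@stack)
  cat(sprintf("  realized: vascular %.3f, coverage %.3f, ghost %.3f\n",
              object@realized["vascular_area_fraction"],
              object@realized["coverage_fraction"],
              object@realized["ghost_fraction"]))
})

setMethod("show", "RegionMaskSet", function(object) {
  a <- vapply(object@masks, sum, 0) * prod(object@pixelSize)
  cat("RegionMaskSet:", paste(sprintf("%s %.0f µm²", names(a), a),
                              collapse = ", "), "\n")
})

setMethod("show", "NucleiLabels", function(object) {
  cat("NucleiLabels:", nrow(object@table), "nuclei\n")
})

setMethod("show", "VesselMask3D", function(object) {
  cat(sprintf("VesselMask3D: %d voxels, mean diameter %.1f µm, skeleton %.0f µm\n",
              sum(object@mask), object@meanDiameter, object@skeletonLength))
})

setMethod("show", "ObjectLabels3D", function(object) {
  cat("ObjectLabels3D (", object@marker, "): ", length(object@volumes),
      " objects\n", sep = "")
})

setMethod("show", "PerfusionSeries", function(object) {
  cat("PerfusionSeries:", length(object@times), "frames at t =",
      paste(object@times, collapse = ", "), "min\n")
})

setMethod("show", "PermeabilityEstimate", function(object) {
  cat(sprintf("PermeabilityEstimate: P_app = %.3e cm/s (t %g-%g min, d %.1f µm)%s\n",
              object@pApp, object@t1, object@t2, object@meanDiameter,
              if (object@clamped) " [clamped]" else ""))
})
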