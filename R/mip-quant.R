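# 2D MIP morphometry: common clipping + fractional thresholds per marker,
# nuclei segmentation and border-based assignment, pericyte coverage by
# dilation overlap, ghost-vessel fraction, and apoptosis co-localization.

.marker_thresholds <- c(EC = 0.25, pericyte = 0.40, astrocyte = 0.40,
                        ECM = 0.40)
.marker_borders_um <- c(EC = 3, pericyte = 2, astrocyte = 2, ECM = 3)
.role_for_marker <- c(EC = "endothelium", pericyte = "pericyte",
                      astrocyte = "astrocyte", ECM = "colIV")

#' Clip, rescale and median-smooth a 2D image
#'
#' Intensities are clipped to `[0, clipMax]`, divided by `clipMax` and
#' median-filtered with a square window of side `2 * medianRadius + 1`
#' pixels; radius 0 skips the filter. This is the common preprocessing in
#' front of all fractional marker thresholds.
#'
#' @param image numeric matrix.
#' @param clipMax upper clip intensity (default 20000).
#' @param medianRadius median filter radius in pixels (default 3).
#' @return numeric matrix in `[0, 1]`.
#' @examples
#' normalizeAndSmooth(matrix(40000, 3, 3), medianRadius = 0)
#' @export
normalizeAndSmooth <- function(image, clipMax = 20000, medianRadius = 3) {
  stopifnot(clipMax > 0, medianRadius >= 0)
  if (any(!is.finite(image))) stop("non-finite pixels")
  out <- pmin(pmax(image, 0), clipMax) / clipMax
  if (medianRadius > 0)
    out <- as.matrix(EBImage::medianFilter(out, as.integer(medianRadius)))
  out
}

#' Threshold a normalized image into a marker region
#'
#' Applies the marker's common fractional threshold to an image already
#' normalized to `[0, 1]`: 0.25 for endothelium (EC), 0.40 for pericytes,
#' astrocytes and the basement membrane (ECM). For ECM an extra 10 px
#' median smoothing precedes the threshold.
#'
#' @param image01 numeric matrix in `[0, 1]`.
#' @param marker one of `"EC"`, `"pericyte"`, `"astrocyte"`, `"ECM"`.
#' @param thresholds named threshold overrides (fractions in (0, 1)).
#' @param ecmMedianRadius median radius applied for ECM (default 10 px).
#' @return logical matrix, `image01 >= threshold`.
#' @examples
#' thresholdRegion(matrix(0.3, 2, 2), "EC")        # all TRUE at 0.25
#' thresholdRegion(matrix(0.3, 2, 2), "pericyte")  # all FALSE at 0.40
#' @export
thresholdRegion <- function(image01, marker,
                            thresholds = .marker_thresholds,
                            ecmMedianRadius = 10) {
  if (!marker %in% names(thresholds)) stop("unknown marker '", marker, "'")
  if (marker == "ECM" && ecmMedianRadius > 0)
    image01 <- as.matrix(EBImage::medianFilter(pmin(pmax(image01, 0), 1),
                                               as.integer(ecmMedianRadius)))
  image01 >= thresholds[[marker]]
}

#' Build the marker region set from a stack
#'
#' Projects each marker channel, normalizes (clip + 3 px median) and
#' thresholds it; the ECM channel additionally gets its 10 px median inside
#' the thresholding step.
#'
#' @param stack a [ChannelStack-class] or [SyntheticScene-class].
#' @param clipMax,medianRadius see [normalizeAndSmooth()].
#' @param thresholds threshold overrides, see [thresholdRegion()].
#' @return a [RegionMaskSet-class].
#' @export
segmentRegions <- function(stack, clipMax = 20000, medianRadius = 3,
                           thresholds = .marker_thresholds) {
  if (is(stack, "SyntheticScene")) stack <- stack@stack
  roles <- names(channelRoles(stack))
  masks <- list()
  for (m in names(.role_for_marker)) {
    role <- .role_for_marker[[m]]
    if (!role %in% roles) next
    img <- normalizeAndSmooth(maxProjection(stack, role), clipMax, medianRadius)
    masks[[m]] <- thresholdRegion(img, m, thresholds)
  }
  if (!length(masks)) stop("stack maps none of the marker roles")
  RegionMaskSet(masks, voxelSize(stack)[1:2],
                thresholds[names(thresholds) %in% names(masks)])
}

#' Segment nuclei in a normalized DAPI MIP
#'
#' Gaussian smoothing (sigma 2 px), global Otsu threshold, hole filling,
#' distance-transform watershed to split touching nuclei, and removal of
#' objects below a minimum area. A blank image yields an empty label set.
#'
#' @param dapi01 numeric matrix in `[0, 1]`.
#' @param pixelSize numeric(2), µm per pixel.
#' @param minArea minimum object area in µm² (default 20).
#' @param sigma Gaussian sigma in pixels (default 2).
#' @return a [NucleiLabels-class].
#' @export
segmentNuclei <- function(dapi01, pixelSize, minArea = 20, sigma = 2) {
  stopifnot(length(pixelSize) == 2L, all(pixelSize > 0))
  img <- gaussian_smooth(dapi01, c(sigma, sigma, 0))
  if (max(img) - min(img) < 1e-8)
    return(new("NucleiLabels", labels = matrix(0L, nrow(dapi01), ncol(dapi01)),
               table = data.frame(id = integer(), area_um2 = numeric(),
                                  cx = numeric(), cy = numeric(),
                                  apoptotic = logical()),
               pixelSize = as.numeric(pixelSize)))
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(img, 0), 1)))
  mask <- img > thr
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask)) > 0.5)
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  px_area <- prod(pixelSize)
  sizes <- tabulate(lab)
  keep <- which(sizes * px_area >= minArea)
  relab <- integer(max(lab, 1L))
  relab[keep] <- seq_along(keep)
  lab2 <- matrix(0L, nrow(mask), ncol(mask))
  pos <- lab > 0L
  lab2[pos] <- relab[lab[pos]]
  ids <- seq_along(keep)
  if (length(ids)) {
    idx <- which(lab2 > 0L, arr.ind = TRUE)
    l <- lab2[lab2 > 0L]
    tb <- data.frame(
      id = ids,
      area_um2 = tabulate(l, length(ids)) * px_area,
      cx = as.numeric(tapply(idx[, 1], l, mean)),
      cy = as.numeric(tapply(idx[, 2], l, mean)),
      apoptotic = NA)
  } else {
    tb <- data.frame(id = integer(), area_um2 = numeric(), cx = numeric(),
                     cy = numeric(), apoptotic = logical())
  }
  new("NucleiLabels", labels = lab2, table = tb,
      pixelSize = as.numeric(pixelSize))
}

# dilate each marker mask by its physical border and count nuclei whose
# pixels intersect it; returns a logical nuclei x markers incidence matrix.
.nuclei_incidence <- function(nuclei, regions, borders = .marker_borders_um) {
  lab <- nuclei@labels
  if (!identical(dim(lab), dim(regions@masks[[1]])))
    stop("nuclei and regions are on different grids")
  ids <- nuclei@table$id
  out <- matrix(FALSE, length(ids), length(regions@masks),
                dimnames = list(NULL, names(regions@masks)))
  for (m in names(regions@masks)) {
    b <- if (m %in% names(borders)) borders[[m]] else 0
    dil <- dilate_um(regions@masks[[m]], b, regions@pixelSize)
    hit <- tabulate(lab[dil & lab > 0L], nbins = max(ids, 1L))
    out[, m] <- hit[ids] > 0L
  }
  out
}

#' Assign nuclei to marker regions with physical borders
#'
#' A nucleus is counted for a marker when its mask intersects the marker
#' region dilated by an outer border: 3 µm for EC, 2 µm for pericytes,
#' 2 µm for astrocytes and 3 µm for the ECM. Assignment is non-exclusive:
#' one nucleus may count for several markers.
#'
#' @param nuclei a [NucleiLabels-class].
#' @param regions a [RegionMaskSet-class] on the same grid.
#' @param borders named numeric border widths in µm.
#' @return named integer vector of nuclei counts per marker.
#' @export
assignNucleiToRegions <- function(nuclei, regions,
                                  borders = .marker_borders_um) {
  inc <- .nuclei_incidence(nuclei, regions, borders)
  colSums(inc)
}

#' Pericyte coverage area
#'
#' Area of the pericyte region overlapping the EC region dilated by a 5 µm
#' outer border, in µm².
#'
#' @param regions a [RegionMaskSet-class] with `EC` and `pericyte` masks.
#' @param borderUm outer border on the EC region (default 5 µm).
#' @return coverage area in µm².
#' @export
pericyteCoverage <- function(regions, borderUm = 5) {
  for (m in c("EC", "pericyte"))
    if (!m %in% names(regions@masks)) stop("missing '", m, "' mask")
  dil <- dilate_um(regions@masks$EC, borderUm, regions@pixelSize)
  sum(regions@masks$pericyte & dil) * prod(regions@pixelSize)
}

#' Ghost-vessel fraction
#'
#' The avascular basement-membrane fraction: the EC (vascular) area is
#' subtracted from the ECM (COL IV) area and the remainder divided by the
#' ECM area. Clamped to `[0, 1]`.
#'
#' @param regions a [RegionMaskSet-class] with `EC` and `ECM` masks.
#' @return fraction in `[0, 1]`.
#' @examples
#' ec <- matrix(FALSE, 10, 10); ec[1:6, 1:10] <- TRUE
#' ecm <- matrix(TRUE, 10, 10)
#' r <- RegionMaskSet(list(EC = ec, ECM = ecm), c(1, 1))
#' ghostVesselFraction(r)  # 0.4
#' @export
ghostVesselFraction <- function(regions) {
  for (m in c("EC", "ECM"))
    if (!m %in% names(regions@masks)) stop("missing '", m, "' mask")
  ecm <- regions@masks$ECM
  if (!any(ecm)) stop("undefined-fraction: empty ECM mask")
  f <- sum(ecm & !regions@masks$EC) / sum(ecm)
  min(max(f, 0), 1)
}

#' Apoptosis co-localization and viability
#'
#' Counts apoptotic nuclei per marker using the same border rule as
#' [assignNucleiToRegions()], and reports viability
#' `1 - (apoptotic / total nuclei)`.
#'
#' @param nuclei a [NucleiLabels-class] with apoptotic flags set.
#' @param regions a [RegionMaskSet-class] on the same grid.
#' @param borders named border widths in µm.
#' @return list with `apoptotic_counts` (per marker), `total_apoptotic`,
#'   `total_nuclei` and `viability`.
#' @export
apoptosisColocalization <- function(nuclei, regions,
                                    borders = .marker_borders_um) {
  tb <- nuclei@table
  if (!nrow(tb)) stop("undefined-viability: zero nuclei")
  if (any(is.na(tb$apoptotic))) stop("apoptotic flags are not set")
  inc <- .nuclei_incidence(nuclei, regions, borders)
  apo <- tb$apoptotic
  list(apoptotic_counts = colSums(inc & apo),
       total_apoptotic = sum(apo),
       total_nuclei = nrow(tb),
       viability = 1 - sum(apo) / nrow(tb))
}

# flag nuclei whose area overlaps the thresholded apoptosis-reporter mask
# by at least half
.flag_apoptotic <- function(nuclei, apoMask, minOverlap = 0.5) {
  lab <- nuclei@labels
  tb <- nuclei@table
  if (!nrow(tb)) return(nuclei)
  hit <- tabulate(lab[apoMask & lab > 0L], nbins = max(tb$id))
  tot <- tabulate(lab[lab > 0L], nbins = max(tb$id))
  tb$apoptotic <- (hit[tb$id] / pmax(tot[tb$id], 1L)) >= minOverlap
  new("NucleiLabels", labels = lab, table = tb, pixelSize = nuclei@pixelSize)
}

#' Full 2D MIP quantification of one stack
#'
#' Runs the whole MIP workflow on a calibrated stack or synthetic scene:
#' marker regions, nuclei, border-based nuclei assignment, pericyte
#' coverage, ghost-vessel fraction and (when an apoptosis channel is
#' mapped) apoptosis co-localization.
#'
#' @param x a [ChannelStack-class] or [SyntheticScene-class].
#' @param clipMax,medianRadius preprocessing, see [normalizeAndSmooth()].
#' @param thresholds marker thresholds, see [thresholdRegion()].
#' @param borders nuclei assignment borders (µm).
#' @param coverageBorderUm pericyte coverage border (default 5 µm).
#' @param minNucleusArea µm², see [segmentNuclei()].
#' @param apoThreshold fractional threshold for the apoptosis reporter.
#' @return one-row data.frame (areas in µm², fractions dimensionless):
#'   vascular/pericyte/astrocyte/ecm areas, coverage area and fraction,
#'   ghost fraction, nuclei counts per marker, apoptotic counts, viability.
#' @examples
#' sc <- renderScene("control_D7", seed = 1, dims = c(128, 64, 8))
#' quantifyMip(sc)[, c("vascular_area", "ghost_fraction")]
#' @export
quantifyMip <- function(x, clipMax = 20000, medianRadius = 3,
                        thresholds = .marker_thresholds,
                        borders = .marker_borders_um, coverageBorderUm = 5,
                        minNucleusArea = 20, apoThreshold = 0.40) {
  stack <- if (is(x, "SyntheticScene")) x@stack else x
  regions <- segmentRegions(stack, clipMax, medianRadius, thresholds)
  px <- voxelSize(stack)[1:2]
  pxa <- prod(px)
  areas <- vapply(regions@masks, sum, 0) * pxa
  out <- data.frame(
    vascular_area = if ("EC" %in% names(areas)) areas[["EC"]] else NA_real_,
    pericyte_area = if ("pericyte" %in% names(areas)) areas[["pericyte"]] else NA_real_,
    astrocyte_area = if ("astrocyte" %in% names(areas)) areas[["astrocyte"]] else NA_real_,
    ecm_area = if ("ECM" %in% names(areas)) areas[["ECM"]] else NA_real_)
  if (all(c("EC", "pericyte") %in% names(regions@masks))) {
    out$coverage_area <- pericyteCoverage(regions, coverageBorderUm)
    out$coverage_fraction <- out$coverage_area / out$vascular_area
  }
  if (all(c("EC", "ECM") %in% names(regions@masks)))
    out$ghost_fraction <- ghostVesselFraction(regions)
  roles <- names(channelRoles(stack))
  if ("nuclei" %in% roles) {
    dapi <- normalizeAndSmooth(maxProjection(stack, "nuclei"), clipMax,
                               medianRadius)
    nuc <- segmentNuclei(dapi, px, minNucleusArea)
    cnt <- assignNucleiToRegions(nuc, regions, borders)
    for (m in names(cnt)) out[[paste0("nuclei_", m)]] <- cnt[[m]]
    out$nuclei_total <- nrow(nuc@table)
    if ("apoptosis" %in% roles && nrow(nuc@table)) {
      apo01 <- normalizeAndSmooth(maxProjection(stack, "apoptosis"), clipMax,
                                  medianRadius)
      nuc <- .flag_apoptotic(nuc, apo01 >= apoThreshold)
      col <- apoptosisColocalization(nuc, regions, borders)
      for (m in names(col$apoptotic_counts))
        out[[paste0("apoptotic_", m)]] <- col$apoptotic_counts[[m]]
      out$apoptotic_total <- col$total_apoptotic
      out$viability <- col$viability
    }
  }
  rownames(out) <- NULL
  out
}
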