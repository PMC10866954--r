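# Reading/writing calibrated stacks and basic 2D geometry: plain multi-page
# TIFF in channel-major page order plus a YAML sidecar carrying the voxel
# size (µm) and the channel-role map. Pixel indices are 0-based in the
# sidecar-facing ROI rectangles, half-open [x0, x1) x [y0, y1).

#' Write a ChannelStack to a multi-page TIFF with a YAML sidecar
#'
#' Pages are stored channel-major (all z of channel 1, then channel 2, ...)
#' as 16-bit grayscale; intensities must lie in `[0, 65535]` and are rounded
#' to integers, so integer-valued stacks round-trip exactly. The sidecar
#' (`<path>.yaml`) records `voxel_size_um`, `dims` and `channels`.
#'
#' @param stack a [ChannelStack-class].
#' @param path output TIFF path.
#' @param sidecar sidecar path; default `paste0(path, ".yaml")`.
#' @return `path`, invisibly.
#' @examples
#' st <- ChannelStack(list(a = array(7, c(4, 3, 2))), c(0.6, 0.6, 5))
#' f <- tempfile(fileext = ".tif")
#' writeStack(st, f)
#' st2 <- readStack(f)
#' stopifnot(identical(channelVoxels(st2, "a"), channelVoxels(st, "a")))
#' @export
writeStack <- function(stack, path, sidecar = paste0(path, ".yaml")) {
  stopifnot(is(stack, "ChannelStack"))
  pages <- list()
  for (ch in seq_along(stack@voxels)) {
    v <- stack@voxels[[ch]]
    if (any(!is.finite(v))) stop("non-finite voxels in channel ", ch)
    if (any(v < 0 | v > 65535)) {
      warning("intensities clamped to [0, 65535] for 16-bit storage")
      v <- pmin(pmax(v, 0), 65535)
    }
    for (z in seq_len(dim(v)[3]))
      pages[[length(pages) + 1L]] <- round(v[, , z]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    voxel_size_um = as.list(structure(as.numeric(stack@voxelSize),
                                      names = c("x", "y", "z"))),
    dims = as.integer(dim(stack@voxels[[1]])),
    n_channels = length(stack@voxels),
    channels = as.list(structure(as.integer(stack@channelRoles),
                                 names = names(stack@channelRoles))),
    provenance = as.character(stack@provenance))
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' Read a ChannelStack from a multi-page TIFF plus YAML sidecar
#'
#' The sidecar must provide the voxel size; a stack without calibration is
#' refused rather than silently defaulted, since every downstream metric is
#' in physical units.
#'
#' @param path TIFF path.
#' @param sidecar sidecar path; default `paste0(path, ".yaml")`.
#' @param channelRoles optional named integer map overriding the sidecar's.
#' @return a [ChannelStack-class].
#' @export
readStack <- function(path, sidecar = paste0(path, ".yaml"),
                      channelRoles = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  if (!file.exists(sidecar))
    stop("calibration-missing: no sidecar at '", sidecar,
         "'; voxel size must be supplied")
  meta <- yaml::read_yaml(sidecar)
  vs <- unlist(meta$voxel_size_um)[c("x", "y", "z")]
  if (length(vs) != 3L || any(is.na(vs)) || any(vs <= 0))
    stop("calibration-missing: sidecar lacks a valid voxel_size_um")
  pages <- tiff::readTIFF(path, all = TRUE)
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1L) stop("inconsistent page shapes in '", path, "'")
  nch <- meta$n_channels
  if (is.null(nch)) nch <- max(unlist(meta$channels))
  if (length(pages) %% nch != 0L)
    stop("page count ", length(pages), " not divisible by ", nch, " channels")
  nz <- length(pages) %/% nch
  d2 <- dim(pages[[1]])
  voxels <- vector("list", nch)
  for (ch in seq_len(nch)) {
    arr <- array(0, c(d2, nz))
    for (z in seq_len(nz))
      arr[, , z] <- round(pages[[(ch - 1L) * nz + z]] * 65535)
    voxels[[ch]] <- arr
  }
  roles <- channelRoles
  if (is.null(roles) && length(meta$channels))
    roles <- structure(as.integer(unlist(meta$channels)),
                       names = names(meta$channels))
  if (is.null(roles)) stop("no channel-role map in sidecar or arguments")
  if (any(roles < 1L | roles > nch)) stop("role map points at missing channels")
  names(voxels) <- names(roles)[match(seq_len(nch), roles)]
  ChannelStack(voxels, vs, roles,
               provenance = as.character(meta$provenance %||% character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum intensity projection of one channel
#'
#' Per-pixel maximum over z. The result carries the (x, y) pixel size as an
#' attribute `pixelSize` (µm).
#'
#' @param stack a [ChannelStack-class] (or [SyntheticScene-class]).
#' @param role channel role to project.
#' @return numeric matrix with attribute `pixelSize`.
#' @examples
#' st <- ChannelStack(list(a = array(seq_len(8), c(2, 2, 2))), c(1, 1, 2))
#' maxProjection(st, "a")
#' @export
maxProjection <- function(stack, role) {
  if (is(stack, "SyntheticScene")) stack <- stack@stack
  v <- channelVoxels(stack, role)
  out <- mip_of(v)
  attr(out, "pixelSize") <- stack@voxelSize[1:2]
  out
}

#' ROI layouts and tiling
#'
#' `roiLayout()` partitions a 2D image into up to 15 equal rectangles along
#' its longer axis (matching the whole-channel regions-of-interest
#' convention for 20x images); `tileRois()` crops an image by a layout.
#' Rectangles are 0-based, half-open `[x0, x1) x [y0, y1)` pixel intervals.
#'
#' @param dim integer(2) image dimensions (pixels).
#' @param n number of ROIs, 1-15.
#' @return `roiLayout()`: data.frame with columns x0, x1, y0, y1;
#'   `tileRois()`: list of cropped matrices in layout order.
#' @examples
#' lay <- roiLayout(c(1500, 500), 15)
#' img <- matrix(0, 1500, 500)
#' length(tileRois(img, lay))
#' @export
roiLayout <- function(dim, n) {
  stopifnot(length(dim) == 2L, n >= 1L)
  if (n > 15L) stop("at most 15 ROIs per channel")
  along <- which.max(dim)
  cuts <- round(seq(0L, dim[along], length.out = n + 1L))
  if (any(diff(cuts) <= 0)) stop("image too small for ", n, " ROIs")
  out <- data.frame(x0 = 0L, x1 = dim[1], y0 = 0L, y1 = dim[2])[rep(1, n), ]
  if (along == 1L) { out$x0 <- cuts[-(n + 1L)]; out$x1 <- cuts[-1L] }
  else             { out$y0 <- cuts[-(n + 1L)]; out$y1 <- cuts[-1L] }
  rownames(out) <- NULL
  out
}

#' @rdname roiLayout
#' @param image numeric matrix.
#' @param layout data.frame of rectangles as produced by [roiLayout()].
#' @export
tileRois <- function(image, layout) {
  d <- dim(image)
  need <- c("x0", "x1", "y0", "y1")
  stopifnot(all(need %in% names(layout)))
  if (any(layout$x0 < 0 | layout$y0 < 0 | layout$x1 > d[1] | layout$y1 > d[2] |
          layout$x0 >= layout$x1 | layout$y0 >= layout$y1))
    stop("layout-invalid: rectangle out of image bounds")
  n <- nrow(layout)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (layout$x0[i] < layout$x1[j] && layout$x0[j] < layout$x1[i] &&
        layout$y0[i] < layout$y1[j] && layout$y0[j] < layout$y1[i])
      stop("layout-invalid: rectangles ", i, " and ", j, " overlap")
  }
  lapply(seq_len(n), function(i)
    image[(layout$x0[i] + 1L):layout$x1[i],
          (layout$y0[i] + 1L):layout$y1[i], drop = FALSE])
}
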