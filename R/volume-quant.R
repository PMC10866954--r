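# 3D stack analysis: denoising (Gaussian + background opening), 3-class
# multi-Otsu segmentation with morphological cleanup and watershed
# splitting, random-walker vascular segmentation seeded by the multi-Otsu
# cuts, and proximity metrics (dilation overlap, surface distances).

#' Multi-Otsu thresholding
#'
#' Exhaustive two-threshold Otsu on a 256-bin histogram: the pair of cuts
#' maximizing the between-class variance of the three classes. Used both
#' for 3-class object segmentation (top class = foreground) and to derive
#' the random-walker seed bounds.
#'
#' @param x numeric vector or array.
#' @param nbins histogram resolution (default 256).
#' @return numeric(2), the lower and upper cut (intensity units).
#' @examples
#' multiOtsu(c(rnorm(100, 1), rnorm(100, 5), rnorm(100, 9)))
#' @export
multiOtsu <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) stop("degenerate-histogram: constant image")
  h <- tabulate(pmin(as.integer((v - rng[1]) / diff(rng) * nbins) + 1L,
                     nbins), nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  W <- cumsum(p)
  M <- cumsum(p * mids)
  best <- -Inf; cuts <- c(1L, 2L)
  for (t1 in 1:(nbins - 2L)) {
    w1 <- W[t1]; m1 <- M[t1]
    if (w1 <= 0) next
    t2s <- (t1 + 1L):(nbins - 1L)
    w2 <- W[t2s] - w1
    m2 <- M[t2s] - m1
    w3 <- 1 - W[t2s]
    m3 <- M[nbins] - M[t2s]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    sb <- m1^2 / w1 + ifelse(ok, m2^2 / w2 + m3^2 / w3, -Inf)
    i <- which.max(sb)
    if (sb[i] > best) { best <- sb[i]; cuts <- c(t1, t2s[i]) }
  }
  # cut value = upper edge of the selected bin
  rng[1] + cuts * diff(rng) / nbins
}

#' Denoise a 3D stack
#'
#' Gaussian smoothing in-plane followed by slice-wise background removal:
#' the background is estimated per z-slice by a grayscale opening (running
#' box minimum then maximum, window `2 * ballRadius + 1`) and subtracted;
#' output is clamped at 0.
#'
#' @param arr 3D numeric array (or 2D matrix).
#' @param gaussianSigma Gaussian sigma in pixels (0 disables smoothing).
#' @param ballRadius background window radius in pixels (> 0).
#' @return array of the input shape, non-negative.
#' @export
denoiseStack <- function(arr, gaussianSigma = 1, ballRadius = 50) {
  stopifnot(gaussianSigma >= 0, ballRadius > 0)
  if (any(!is.finite(arr))) stop("non-finite voxels")
  d <- dims_of(arr)
  out <- if (gaussianSigma > 0)
    gaussian_smooth(arr, c(gaussianSigma, gaussianSigma, 0)) else arr
  out <- array(out, d)
  for (z in seq_len(d[3])) {
    sl <- out[, , z]
    bg <- cpp_boxminmax2d(cpp_boxminmax2d(sl, as.integer(ballRadius), 0L),
                          as.integer(ballRadius), 1L)
    out[, , z] <- pmax(sl - bg, 0)
  }
  if (length(dim(arr)) == 2L) out[, , 1] else out
}

# Deterministic distance-transform watershed seeds: local maxima of the
# (lightly smoothed) in-object EDT. Ties are broken by raster order. Two
# suppression rules keep one seed per object core: a physical floor of
# `minSep` in-plane pixels, and a basin rule that merges maxima whose
# inscribed spheres overlap substantially (distance < 1.2 x the smaller
# peak distance) -- voxelization plateaus, not separate bodies. Maxima
# shallower than 1.5 um are discarded as corner artifacts.
.distance_seeds <- function(dt, mask, minSep = 3L, spacing = c(1, 1, 1)) {
  d <- dims_of(dt)
  dts <- gaussian_smooth(dt, c(1, 1, 0))
  nmax <- dts
  for (ax in 1:3) {
    if (ax == 3 && d[3] == 1L) next
    nmax <- array(nmax, d)
    perm <- nmax
    sh <- function(a, axis, by) {
      out <- array(-Inf, d)
      idx <- lapply(d, seq_len)
      src <- idx; dst <- idx
      n <- d[axis]
      if (by > 0) { dst[[axis]] <- (1 + by):n; src[[axis]] <- 1:(n - by) }
      else        { dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n }
      out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
      out
    }
    nmax <- pmax(perm, sh(perm, ax, 1), sh(perm, ax, -1))
    nmax <- array(nmax, d)
  }
  cand <- which(as.logical(mask) & as.numeric(dts) >= as.numeric(nmax) &
                as.numeric(dt) > 0)
  if (!length(cand)) return(integer(0))
  # keep at least the strongest maximum of every connected component, even
  # when it is shallow; drop other sub-1.5 um corner maxima
  cc <- cpp_label(as.logical(mask), as.integer(d), 6L)
  peak <- tapply(as.numeric(dts)[cand], cc[cand], max)
  deep <- as.numeric(dts)[cand] >= pmin(1.5, peak[as.character(cc[cand])])
  cand <- cand[deep]
  ord <- cand[order(-as.numeric(dts)[cand], cand)]
  sep_floor <- minSep * min(spacing[1:2])
  co <- sweep(arrayInd(ord, d), 2, spacing[seq_len(3)], "*")
  dtv <- as.numeric(dts)[ord]
  keep <- logical(length(ord))
  kept <- matrix(0, 0, 3)
  for (i in seq_along(ord)) {
    if (nrow(kept) &&
        min(sqrt(rowSums(sweep(kept, 2, co[i, ])^2))) < sep_floor) next
    keep[i] <- TRUE
    kept <- rbind(kept, co[i, ])
  }
  ord[keep]
}

# Watershed-dynamics merge: regions whose saddle (the highest distance on
# their shared boundary) comes close to the weaker peak are two maxima of
# one object (z-discretization plateaus), not two objects.
.merge_shallow_splits <- function(lab, dt, ratio = 0.7) {
  d <- dims_of(lab)
  nl <- max(lab)
  if (nl < 2L) return(lab)
  peaks <- vapply(seq_len(nl), function(k) max(dt[lab == k]), 0)
  keys <- character(0); saddles <- numeric(0)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    i1 <- lapply(d, seq_len); i2 <- i1
    i1[[ax]] <- 1:(d[ax] - 1L); i2[[ax]] <- 2:d[ax]
    a <- lab[i1[[1]], i1[[2]], i1[[3]]]; b <- lab[i2[[1]], i2[[2]], i2[[3]]]
    da <- dt[i1[[1]], i1[[2]], i1[[3]]]; db <- dt[i2[[1]], i2[[2]], i2[[3]]]
    sel <- a > 0L & b > 0L & a != b
    if (!any(sel)) next
    lo <- pmin(a[sel], b[sel]); hi <- pmax(a[sel], b[sel])
    key <- paste(lo, hi)
    sv <- pmin(da[sel], db[sel])
    agg <- tapply(sv, key, max)
    keys <- c(keys, names(agg)); saddles <- c(saddles, as.numeric(agg))
  }
  if (!length(keys)) return(lab)
  agg <- tapply(saddles, keys, max)
  parent <- seq_len(nl)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_along(agg)) {
    pr <- as.integer(strsplit(names(agg)[i], " ")[[1]])
    if (agg[i] >= ratio * min(peaks[pr])) {
      ra <- find(pr[1]); rb <- find(pr[2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, 0L)
  newid <- match(root, sort(unique(root)))
  out <- lab
  pos <- lab > 0L
  out[pos] <- newid[lab[pos]]
  out
}

#' Segment bright objects with 3-class multi-Otsu and watershed splitting
#'
#' Foreground is the top intensity class of the two multi-Otsu cuts
#' (markers are bright on dark); objects are cleaned with a closing then an
#' opening (radius 1), fused objects are split at the ridges of the
#' distance transform by a seeded watershed, and objects below a minimum
#' volume are dropped.
#'
#' @param arr denoised 3D array.
#' @param marker marker label carried in the result.
#' @param voxelSize numeric(3), µm.
#' @param minVolume minimum object volume in µm³ (default 50).
#' @param minSeedSep watershed seed separation in pixels (default 3).
#' @return an [ObjectLabels3D-class].
#' @export
segmentObjects3Class <- function(arr, marker, voxelSize, minVolume = 50,
                                 minSeedSep = 3L) {
  d <- dims_of(arr)
  cuts <- multiOtsu(arr)
  fg <- array(as.numeric(arr) >= cuts[2], d)
  if (!any(fg))
    return(new("ObjectLabels3D", labels = array(0L, d), marker = marker,
               voxelSize = as.numeric(voxelSize), volumes = numeric()))
  # morphology radius: one in-plane pixel, in physical units, so thin
  # objects in an anisotropic z-grid survive the opening
  vs <- as.numeric(voxelSize)
  r1 <- min(vs[1:2])
  fg <- edt(fg, vs) <= r1            # closing: dilate by 1 px ...
  fg <- !(edt(!fg, vs) <= r1)        # ... then erode
  fg <- !(edt(!fg, vs) <= r1)        # opening: erode ...
  fg <- edt(fg, vs) <= r1            # ... then dilate
  if (!any(fg))
    return(new("ObjectLabels3D", labels = array(0L, d), marker = marker,
               voxelSize = as.numeric(voxelSize), volumes = numeric()))
  dt <- edt(!fg, vs)                 # in-object distance, µm (anisotropy-aware)
  seeds_at <- .distance_seeds(dt, fg, minSeedSep, vs)
  seeds <- array(0L, d)
  seeds[seeds_at] <- seq_along(seeds_at)
  lab <- array(cpp_watershed_seeded(-as.numeric(dt), as.integer(seeds),
                                    as.logical(fg), as.integer(d)), d)
  lab <- .merge_shallow_splits(lab, dt)
  vox <- prod(vs)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * vox >= minVolume)
  relab <- integer(max(lab, 1L)); relab[keep] <- seq_along(keep)
  out <- array(0L, d)
  pos <- lab > 0L
  out[pos] <- relab[lab[pos]]
  vols <- tabulate(out[out > 0L], length(keep)) * vox
  names(vols) <- seq_along(keep)
  new("ObjectLabels3D", labels = out, marker = marker,
      voxelSize = as.numeric(voxelSize), volumes = vols)
}

#' Random-walker vascular segmentation
#'
#' Seeds voxels above the upper multi-Otsu cut as vessel and below the
#' lower cut as background, then assigns the remaining voxels by
#' random-walker label propagation: the probability that a random walker on
#' the intensity-weighted voxel graph (Gaussian weights,
#' `w = exp(-beta (g_i - g_j)^2)`) first reaches a vessel seed, solved as a
#' sparse linear system; voxels with probability >= 0.5 join the vessel.
#' The mean lumen diameter is estimated from the interior distance
#' transform (exact for a cylinder) and the skeleton length derived from
#' the area-equivalent cylinder.
#'
#' @param arr denoised 3D array.
#' @param voxelSize numeric(3), µm.
#' @param beta random-walker edge-weight contrast (default 130).
#' @return a [VesselMask3D-class].
#' @export
segmentVasculatureRandomWalk <- function(arr, voxelSize, beta = 130) {
  d <- dims_of(arr)
  g <- as.numeric(arr)
  rng <- range(g)
  cuts <- multiOtsu(g)
  vseed <- g > cuts[2]
  bseed <- g < cuts[1]
  if (!any(vseed) && !any(bseed))
    stop("seeding-failure: multi-Otsu produced no seed voxels")
  unknown <- !(vseed | bseed)
  if (!any(vseed)) {
    mask <- array(FALSE, d)
  } else if (!any(unknown) || !any(bseed)) {
    mask <- array(vseed | (!any(bseed) & unknown), d)
  } else {
    gn <- (g - rng[1]) / diff(rng)
    idx <- which(unknown)
    n <- length(idx)
    pos <- integer(prod(d)); pos[idx] <- seq_len(n)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    diag_w <- numeric(n); rhs <- numeric(n)
    co <- arrayInd(idx, d)
    for (ax in 1:3) {
      if (d[ax] == 1L) next
      step <- c(1L, d[1], d[1] * d[2])[ax]
      for (s in c(-1L, 1L)) {
        ok <- if (s > 0) co[, ax] < d[ax] else co[, ax] > 1L
        nb <- idx[ok] + s * step
        w <- exp(-beta * (gn[idx[ok]] - gn[nb])^2) + 1e-10
        diag_w[ok] <- diag_w[ok] + w
        nb_un <- unknown[nb]
        ii <- c(ii, which(ok)[nb_un]); jj <- c(jj, pos[nb[nb_un]])
        xx <- c(xx, -w[nb_un])
        vs_nb <- vseed[nb]
        rhs[which(ok)[vs_nb]] <- rhs[which(ok)[vs_nb]] + w[vs_nb]
      }
    }
    L <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                              x = c(xx, diag_w), dims = c(n, n))
    prob <- as.numeric(Matrix::solve(L, rhs))
    mask <- array(FALSE, d)
    mask[vseed] <- TRUE
    mask[idx[prob >= 0.5]] <- TRUE
  }
  if (!any(mask))
    return(new("VesselMask3D", mask = mask, voxelSize = as.numeric(voxelSize),
               meanDiameter = 0, skeletonLength = 0))
  vs <- as.numeric(voxelSize)
  din <- edt(!mask, vs)[mask]
  if (all(!is.finite(din))) din <- rep(min(d * vs) / 2, sum(mask))
  # half-voxel correction: the EDT measures to the nearest background voxel
  # center, ~half an in-plane voxel beyond the true interface
  dbar <- max(6 * (mean(din) - 0.5 * min(vs[1:2])), min(vs[1:2]))
  vol <- sum(mask) * prod(vs)
  skel <- vol / (pi * (dbar / 2)^2)
  new("VesselMask3D", mask = mask, voxelSize = vs, meanDiameter = dbar,
      skeletonLength = skel)
}

#' Dilation-overlap proximity of objects to the vasculature
#'
#' Both each object and the vessel mask are dilated by `dilationPx` voxels
#' independently in x, y and z (cubic structuring element); the overlap
#' volume of the dilated pair indicates proximity.
#'
#' @param objects an [ObjectLabels3D-class].
#' @param vessels a [VesselMask3D-class] on the same grid.
#' @param dilationPx dilation in voxels (default 3).
#' @return data.frame with `id` and `overlap_volume` (µm³).
#' @export
proximityOverlap <- function(objects, vessels, dilationPx = 3L) {
  lab <- objects@labels
  if (!identical(dim(lab), dim(vessels@mask)))
    stop("objects and vessels are on different grids")
  d <- dims_of(lab)
  vdil <- dilate_cube_px(vessels@mask, dilationPx)
  vox <- prod(objects@voxelSize)
  ids <- as.integer(names(objects@volumes))
  if (!length(ids) && max(lab) > 0) ids <- seq_len(max(lab))
  ov <- numeric(length(ids))
  for (k in seq_along(ids)) {
    w <- which(lab == ids[k], arr.ind = TRUE)
    lo <- pmax(apply(w, 2, min) - dilationPx, 1L)
    hi <- pmin(apply(w, 2, max) + dilationPx, d)
    sub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] == ids[k]
    sub <- array(sub, hi - lo + 1L)
    odil <- dilate_cube_px(sub, dilationPx)
    ov[k] <- sum(odil & vdil[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) * vox
  }
  data.frame(id = ids, overlap_volume = ov)
}

# exposed voxel-face centers (6-connectivity) in µm: the surface sits at
# the interface between voxels, so touching masks yield distance 0
.surface_points <- function(mask, vs) {
  d <- dims_of(mask)
  m <- array(as.logical(mask), d)
  shift <- function(ax, dir) {
    out <- array(FALSE, d)
    if (ax == 1) { if (dir > 0) out[-1, , ] <- m[-d[1], , ] else out[-d[1], , ] <- m[-1, , ] }
    if (ax == 2) { if (dir > 0) out[, -1, ] <- m[, -d[2], ] else out[, -d[2], ] <- m[, -1, ] }
    if (ax == 3) { if (dir > 0) out[, , -1] <- m[, , -d[3]] else out[, , -d[3]] <- m[, , -1] }
    out
  }
  pts <- list()
  for (ax in 1:3) for (dir in c(-1, 1)) {
    idx <- which(m & !shift(ax, -dir), arr.ind = TRUE)
    if (!nrow(idx)) next
    p <- sweep(idx - 0.5, 2, vs[seq_len(ncol(idx))], "*")
    p[, ax] <- p[, ax] + 0.5 * dir * vs[ax]
    pts[[length(pts) + 1L]] <- p
  }
  if (!length(pts)) return(matrix(numeric(0), 0, 3))
  unique(do.call(rbind, pts))
}

#' Shortest surface distances between objects and the vasculature
#'
#' Object and vessel surfaces are taken as their boundary-voxel centers in
#' physical coordinates (voxel anisotropy applied); for each object the
#' minimum Euclidean distance to the vessel surface is found with a
#' spatial-hash nearest-neighbour query, and the per-ROI summary is the
#' mean over objects. Objects touching the vessel report 0 within half a
#' voxel diagonal.
#'
#' @param objects an [ObjectLabels3D-class].
#' @param vessels a [VesselMask3D-class] on the same grid.
#' @return list with `records` (data.frame: id, surface_distance µm) and
#'   `mean_distance`.
#' @export
surfaceDistance <- function(objects, vessels) {
  lab <- objects@labels
  if (!identical(dim(lab), dim(vessels@mask)))
    stop("objects and vessels are on different grids")
  if (!any(vessels@mask)) stop("empty vessel mask")
  vs <- objects@voxelSize
  vsurf <- .surface_points(vessels@mask, vs)
  ids <- as.integer(names(objects@volumes))
  if (!length(ids) && max(lab) > 0) ids <- seq_len(max(lab))
  dist <- numeric(length(ids))
  for (k in seq_along(ids)) {
    osurf <- .surface_points(lab == ids[k], vs)
    if (!nrow(osurf)) stop("empty object surface for id ", ids[k])
    dist[k] <- min(cpp_nn_dist(osurf, vsurf))
  }
  list(records = data.frame(id = ids, surface_distance = dist),
       mean_distance = if (length(dist)) mean(dist) else NaN)
}
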