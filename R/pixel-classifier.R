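# Random-forest pixel classification: the refinement stage that learns a
# segmentation from (thresholding-derived, then corrected) masks and
# applies it to unseen stacks. Features are multi-scale Gaussian
# intensities, gradient magnitudes and Laplacians at sigma 1, 2 and 4 px.

.pixel_features <- function(arr) {
  d <- dims_of(arr)
  a <- array(as.numeric(arr), d)
  feats <- list(raw = as.numeric(a))
  grad_mag <- function(s) {
    gx <- (shift_arr(s, 1, -1) - shift_arr(s, 1, 1)) / 2
    gy <- (shift_arr(s, 2, -1) - shift_arr(s, 2, 1)) / 2
    gz <- if (d[3] > 1L) (shift_arr(s, 3, -1) - shift_arr(s, 3, 1)) / 2 else 0
    sqrt(gx^2 + gy^2 + gz^2)
  }
  laplace <- function(s) {
    l <- shift_arr(s, 1, -1) + shift_arr(s, 1, 1) - 2 * s +
         shift_arr(s, 2, -1) + shift_arr(s, 2, 1) - 2 * s
    if (d[3] > 1L) l <- l + shift_arr(s, 3, -1) + shift_arr(s, 3, 1) - 2 * s
    l
  }
  for (sg in c(1, 2, 4)) {
    s <- gaussian_smooth(a, c(sg, sg, if (d[3] > 1L) sg / 2 else 0))
    feats[[paste0("g", sg)]] <- as.numeric(s)
    feats[[paste0("grad", sg)]] <- as.numeric(grad_mag(s))
    feats[[paste0("lap", sg)]] <- as.numeric(laplace(s))
  }
  do.call(cbind, feats)
}

# edge-replicating shift along one axis
shift_arr <- function(a, axis, by) {
  d <- dims_of(a)
  a <- array(a, d)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  if (axis == 1) a[idx, , , drop = FALSE]
  else if (axis == 2) a[, idx, , drop = FALSE]
  else a[, , idx, drop = FALSE]
}

#' Train a random-forest pixel classifier
#'
#' Learns a per-voxel foreground/background classifier from stacks paired
#' with (corrected) binary masks. Training voxels are subsampled, balanced
#' across classes; the forest is seeded, so training and prediction are
#' reproducible.
#'
#' @param stacks list of 3D arrays.
#' @param masks list of logical arrays matching `stacks`.
#' @param seed integer seed.
#' @param numTrees forest size (default 100).
#' @param maxPerClass training voxels sampled per class (default 20000).
#' @return classifier handle for [applyPixelClassifier()].
#' @export
trainPixelClassifier <- function(stacks, masks, seed, numTrees = 100L,
                                 maxPerClass = 20000L) {
  stopifnot(length(stacks) >= 1L, length(stacks) == length(masks))
  feats <- list(); labs <- list()
  for (i in seq_along(stacks)) {
    if (!identical(dim(stacks[[i]]), dim(masks[[i]])))
      stop("stack/mask shape mismatch at pair ", i)
    feats[[i]] <- .pixel_features(stacks[[i]])
    labs[[i]] <- as.logical(masks[[i]])
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  sel <- with_seed(seed, {
    pos <- which(y); neg <- which(!y)
    c(if (length(pos)) sample(pos, min(length(pos), maxPerClass)),
      if (length(neg)) sample(neg, min(length(neg), maxPerClass)))
  })
  df <- data.frame(X[sel, , drop = FALSE], y = factor(y[sel], c(FALSE, TRUE)))
  fit <- ranger::ranger(y ~ ., data = df, num.trees = numTrees,
                        seed = as.integer(seed), num.threads = 1L)
  structure(list(fit = fit, features = colnames(X)),
            class = "mvnPixelClassifier")
}

#' @rdname trainPixelClassifier
#' @param classifier handle from [trainPixelClassifier()].
#' @param stack 3D array to segment.
#' @return `applyPixelClassifier()`: logical array, the predicted mask.
#' @export
applyPixelClassifier <- function(classifier, stack) {
  stopifnot(inherits(classifier, "mvnPixelClassifier"))
  X <- data.frame(.pixel_features(stack))
  pred <- stats::predict(classifier$fit, data = X, num.threads = 1L)
  array(pred$predictions == "TRUE", dim(stack))
}
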