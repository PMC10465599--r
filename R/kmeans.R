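## Region-based segmentation by K-means pixel clustering.
##
## Per-pixel feature vectors (RGB, or luminance for grayscale input,
## optionally augmented with the 3x3 local-mean channel) are clustered by
## Lloyd's algorithm under squared Euclidean distance; the region of interest
## is the union of all clusters except the background cluster, identified as
## the cluster owning the largest fraction of image-border pixels (ties
## broken by lower mean luminance).

#' Lloyd's K-means under squared Euclidean distance
#'
#' Seeded initialization (uniform random choice of k distinct points),
#' assignment to the nearest centroid by squared Euclidean distance, centroid
#' recomputation as cluster means, stopping when the inertia improvement
#' falls below `tol` or `maxIter` is reached. An emptied cluster is re-seeded
#' at the point farthest from its current centroid. With `nstart > 1` the
#' best (lowest-inertia) of `nstart` seeded restarts is returned.
#'
#' @param points n x d numeric matrix (rows are observations).
#' @param k number of clusters; must not exceed the number of distinct rows.
#' @param seed integer seed for initialization.
#' @param maxIter maximum Lloyd iterations (>= 1).
#' @param tol non-negative inertia-improvement stopping threshold.
#' @param nstart number of seeded restarts.
#' @param trace if `TRUE`, attach the per-iteration inertia trace.
#' @return list with `centroids` (k x d), `assignments` (1..k per row),
#'   `inertia`, and optionally `trace`.
#' @examples
#' km <- kmeansLloyd(matrix(c(0, 0.1, 10, 10.1)), k = 2, seed = 1)
#' km$inertia
#' @export
kmeansLloyd <- function(points, k, seed = 1L, maxIter = 100L, tol = 1e-8,
                        nstart = 1L, trace = FALSE) {
  points <- as.matrix(points)
  stopIfNot(nrow(points) > 0, "empty input")
  stopIfNot(maxIter >= 1, "maxIter must be >= 1")
  stopIfNot(tol >= 0, "tol must be non-negative")
  ndistinct <- nrow(unique(points))
  stopIfNot(k <= nrow(points), "k exceeds the number of points")
  if (k > ndistinct) stop("degenerate clustering: k exceeds distinct points",
                          call. = FALSE)
  best <- NULL
  for (s in seq_len(nstart)) {
    res <- withSeed(seed + s - 1L, kmeansOnce(points, k, maxIter, tol, trace))
    if (is.null(best) || res$inertia < best$inertia) best <- res
  }
  best
}

kmeansOnce <- function(points, k, maxIter, tol, trace) {
  n <- nrow(points)
  # seeded init: k distinct rows chosen uniformly
  uniq <- which(!duplicated(points))
  cent <- points[sample(uniq, k), , drop = FALSE]
  sq <- rowSums(points^2)
  inertia <- Inf
  itrace <- numeric(0)
  assign <- rep(1L, n)
  for (it in seq_len(maxIter)) {
    d2 <- outer(sq, rowSums(cent^2), `+`) - 2 * points %*% t(cent)
    assign <- max.col(-d2, ties.method = "first")
    newInertia <- sum(d2[cbind(seq_len(n), assign)])
    newInertia <- max(newInertia, 0)
    for (j in seq_len(k)) {
      idx <- assign == j
      if (!any(idx)) {
        # empty-cluster repair: re-seed at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), assign)])
        cent[j, ] <- points[far, ]
        assign[far] <- j
      } else cent[j, ] <- colMeans(points[idx, , drop = FALSE])
    }
    itrace <- c(itrace, newInertia)
    if (is.finite(inertia) && inertia - newInertia < tol) { inertia <- newInertia; break }
    inertia <- newInertia
  }
  # final consistent assignment against the returned centroids
  d2 <- outer(sq, rowSums(cent^2), `+`) - 2 * points %*% t(cent)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- max(sum(d2[cbind(seq_len(n), assign)]), 0)
  out <- list(centroids = cent, assignments = assign, inertia = inertia)
  if (trace) out$trace <- itrace
  out
}

#' Per-pixel feature matrix
#'
#' One row per pixel (column-major pixel order): the RGB channels for color
#' input or the single luminance channel for grayscale, optionally augmented
#' with the mean over the pixel's 3x3 neighbourhood (edge pixels average the
#' available neighbours), which encourages spatially coherent clusters.
#'
#' @param image H x W matrix or H x W x 3 array.
#' @param useLocalMean append the 3x3 local-mean luminance channel.
#' @return (H*W) x d numeric matrix.
#' @export
pixelFeatures <- function(image, useLocalMean = FALSE) {
  if (is.matrix(image)) feats <- matrix(as.vector(image), ncol = 1)
  else feats <- apply(image, 3, as.vector)
  if (useLocalMean) {
    g <- luminance(image)
    ones <- matrix(1, 3, 3)
    num <- Re(convolve2d(g, ones))
    den <- Re(convolve2d(matrix(1, nrow(g), ncol(g)), ones))
    feats <- cbind(feats, as.vector(num / den))
  }
  feats
}

#' Segment an image by K-means pixel clustering
#'
#' @param image H x W matrix or H x W x 3 array in [0, 1].
#' @param k number of clusters (>= 2); default 3 targets healthy tissue,
#'   symptomatic tissue and background.
#' @param useLocalMean append the 3x3 local-mean feature channel.
#' @param seed integer seed.
#' @param nstart seeded K-means restarts.
#' @return A [SegmentationResult-class]; `labelMap` holds cluster ids 0..k-1
#'   and `roiMask` the foreground (non-background) pixels.
#' @export
segmentImage <- function(image, k = 3L, useLocalMean = FALSE, seed = 1L,
                         nstart = 3L) {
  stopIfNot(k >= 2, "k must be >= 2")
  dims <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  feats <- pixelFeatures(image, useLocalMean)
  km <- kmeansLloyd(feats, k, seed = seed, nstart = nstart)
  labelMap <- matrix(km$assignments - 1L, dims[1], dims[2])
  seg <- new("SegmentationResult", labelMap = labelMap,
             centroids = km$centroids, inertia = km$inertia,
             roiMask = matrix(TRUE, dims[1], dims[2]), k = as.integer(k))
  seg@roiMask <- selectROI(seg, image)
  seg
}

#' Region-of-interest mask from a segmentation
#'
#' Background is the cluster with the highest fraction of its pixels on the
#' image border, ties broken by lower mean luminance; the ROI is the union of
#' every other cluster. If all pixels fall in one cluster the mask is empty
#' and a warning is raised.
#'
#' @param segmentation a [SegmentationResult-class].
#' @param image the segmented image (for the luminance tie-break).
#' @return H x W logical mask.
#' @export
selectROI <- function(segmentation, image) {
  lm <- segmentation@labelMap
  h <- nrow(lm); w <- ncol(lm)
  present <- sort(unique(as.vector(lm)))
  if (length(present) < 2) {
    warning("degenerate segmentation: a single cluster; empty ROI")
    return(matrix(FALSE, h, w))
  }
  border <- matrix(FALSE, h, w)
  border[c(1, h), ] <- TRUE; border[, c(1, w)] <- TRUE
  gray <- luminance(image)
  borderFrac <- vapply(present, function(cl)
    sum(border[lm == cl]) / sum(lm == cl), 0)
  meanLum <- vapply(present, function(cl) mean(gray[lm == cl]), 0)
  bg <- present[order(-borderFrac, meanLum)][1]
  lm != bg
}
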