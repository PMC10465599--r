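#' Six-class nutrient-deficiency label set
#'
#' The fixed class taxonomy used throughout the pipeline: five deficiency
#' phenotypes plus a healthy class. Class ids 1..6 map bijectively onto names,
#' in the conventional dataset order.
#'
#' @return A data.frame with columns `id` (integer 1..6) and `name`.
#' @examples
#' deficiencyClasses()
#' @export
deficiencyClasses <- function() {
  data.frame(
    id = 1:6,
    name = c("nitrogen_deficient", "phosphorus_deficient", "potassium_deficient",
             "calcium_deficient", "iron_deficient", "no_deficiency"),
    stringsAsFactors = FALSE
  )
}

#' @rdname deficiencyClasses
#' @export
classNames <- function() deficiencyClasses()$name

# Coarse grouping: any of the five deficiencies vs the healthy class.
coarseOf <- function(fine) ifelse(fine == "no_deficiency", "healthy", "deficient")

#' Gabor kernel parameters
#'
#' Parameters of the 2-D Gabor elementary function: an isotropic Gaussian
#' envelope with space constant `omega` (pixels, the same along both axes)
#' modulated by a complex plane wave with horizontal / vertical spatial
#' frequencies `u`, `v` (cycles per pixel). The discrete kernel extends over
#' integer offsets in `[-halfSize, halfSize]` in both directions.
#'
#' @slot omega positive real, Gaussian space constant in pixels.
#' @slot u,v real spatial frequencies in cycles/pixel.
#' @slot halfSize positive integer half-width of the kernel support.
#' @export
setClass("GaborParams", representation(
  omega = "numeric", u = "numeric", v = "numeric", halfSize = "integer"
))

setValidity("GaborParams", function(object) {
  if (length(object@omega) != 1 || !is.finite(object@omega) || object@omega <= 0)
    return("omega must be a single positive finite number")
  if (object@halfSize < 1L) return("halfSize must be >= 1")
  if (!is.finite(object@u) || !is.finite(object@v)) return("u and v must be finite")
  TRUE
})

#' @param omega,u,v,halfSize see slot documentation.
#' @rdname GaborParams-class
#' @export
GaborParams <- function(omega = 2, u = 0.125, v = 0, halfSize = 12L) {
  new("GaborParams", omega = omega, u = u, v = v, halfSize = as.integer(halfSize))
}

#' A labelled collection of synthetic leaf images
#'
#' Container for generated leaf images: each image is an H x W x 3 array with
#' values in [0, 1], paired with a manifest row (id, relative path, class
#' label) and the ground-truth elliptical leaf mask used to render it.
#'
#' @slot images list of H x W x 3 numeric arrays in [0, 1].
#' @slot manifest data.frame with columns `id`, `path`, `label`.
#' @slot masks list of H x W logical ground-truth foreground masks.
#' @slot imageSize integer length-2 (height, width).
#' @slot noiseSigma non-negative additive pixel-noise standard deviation.
#' @slot seed integer seed the set was generated from.
#' @export
setClass("LeafImageSet", representation(
  images = "list", manifest = "data.frame", masks = "list",
  imageSize = "integer", noiseSigma = "numeric", seed = "numeric"
))

setValidity("LeafImageSet", function(object) {
  m <- object@manifest
  if (!all(c("id", "path", "label") %in% names(m)))
    return("manifest must have columns id, path, label")
  if (length(object@images) > 0 && length(object@images) != nrow(m))
    return("number of images must match manifest rows")
  if (!all(m$label %in% classNames()))
    return("manifest labels must belong to the six-class taxonomy")
  for (img in object@images) {
    if (!identical(dim(img)[1:2], as.integer(object@imageSize)))
      return("image dimensions must match imageSize")
    if (min(img) < 0 || max(img) > 1) return("pixel values must lie in [0, 1]")
  }
  TRUE
})

#' @describeIn LeafImageSet-class number of images described by the manifest.
#' @param x,object a `LeafImageSet`.
#' @export
nImages <- function(x) nrow(x@manifest)

#' @describeIn LeafImageSet-class manifest accessor.
#' @export
manifest <- function(x) x@manifest

#' @describeIn LeafImageSet-class class label per image (character vector).
#' @export
imageLabels <- function(x) x@manifest$label

setMethod("show", "LeafImageSet", function(object) {
  cat(sprintf("LeafImageSet: %d images (%d rendered), %dx%d px, noise sigma %.3g\n",
              nImages(object), length(object@images),
              object@imageSize[1], object@imageSize[2], object@noiseSigma))
  tab <- table(factor(object@manifest$label, levels = classNames()))
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[[nm]]))
})

#' K-means segmentation of one image
#'
#' @slot labelMap H x W integer matrix of cluster indices in 0..k-1.
#' @slot centroids k x d matrix of cluster centroids in feature space.
#' @slot inertia within-cluster sum of squared (Euclidean) distances.
#' @slot roiMask H x W logical region-of-interest (foreground) mask.
#' @slot k number of clusters requested.
#' @export
setClass("SegmentationResult", representation(
  labelMap = "matrix", centroids = "matrix", inertia = "numeric",
  roiMask = "matrix", k = "integer"
))

setValidity("SegmentationResult", function(object) {
  if (object@inertia < 0) return("inertia must be non-negative")
  if (!identical(dim(object@labelMap), dim(object@roiMask)))
    return("labelMap and roiMask dimensions must agree")
  TRUE
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %dx%d, k = %d, inertia = %.4g, ROI %.1f%% of pixels\n",
              nrow(object@labelMap), ncol(object@labelMap), object@k,
              object@inertia, 100 * mean(object@roiMask)))
})

#' Layer-graph description of the feature-extraction network
#'
#' An ordered directed acyclic graph of layer descriptors (input, conv, relu,
#' avgpool, concat, dropout, global average pool, linear). The default build
#' is the compact SqueezeNet variant: four fire modules, every convolution at
#' stride 1 (downsampling only by pooling), one enlarged 5x5 deep convolution,
#' and a dropout layer before global pooling.
#'
#' @slot layers list of layer descriptors (each a list with `type`, `name`,
#'   `inputs` and type-specific fields such as kernel size and channel counts).
#' @slot layerCount,connectionCount node and edge counts of the layer graph.
#' @slot featureDim length of the output feature vector.
#' @slot inputSize integer (height, width, channels) of the expected input.
#' @export
setClass("NetworkSpec", representation(
  layers = "list", layerCount = "integer", connectionCount = "integer",
  featureDim = "integer", inputSize = "integer"
))

setValidity("NetworkSpec", function(object) {
  convs <- Filter(function(l) l$type == "conv", object@layers)
  if (length(convs) && any(vapply(convs, function(l) l$stride, 1) != 1))
    return("all convolution layers must have stride 1")
  TRUE
})

setMethod("show", "NetworkSpec", function(object) {
  nf <- sum(grepl("^fire\\d+_squeeze_conv$",
                  vapply(object@layers, `[[`, "", "name")))
  cat(sprintf("NetworkSpec: %d layers, %d connections, %d fire modules, feature dim %d, input %s\n",
              object@layerCount, object@connectionCount, nf, object@featureDim,
              paste(object@inputSize, collapse = "x")))
})

#' Hybrid CNN-LSTM classifier with coarse and fine heads
#'
#' The classifier couples a small convolutional trunk (repeated CONV-RELU
#' blocks each closed by 2x2 average pooling) with an LSTM that consumes the
#' rows of the final feature map as a sequence; the final hidden state,
#' optionally concatenated with externally extracted convolutional features,
#' feeds two parallel softmax heads: a coarse head (deficient vs healthy) and
#' a fine six-class head.
#'
#' @slot spec list of architecture hyperparameters (nCr, nCrp, channels,
#'   lstmHidden, featureDim, headArrangement, inputSize).
#' @slot params named list of weight arrays.
#' @slot history data.frame of per-epoch loss and training accuracy.
#' @slot classLevels fine class names in taxonomy order.
#' @slot trained logical.
#' @export
setClass("HDLModel", representation(
  spec = "list", params = "list", history = "data.frame",
  classLevels = "character", trained = "logical"
))

setMethod("show", "HDLModel", function(object) {
  cat(sprintf("HDLModel: %s, trunk %d block(s) x %d conv/relu, LSTM hidden %d, %s heads\n",
              if (object@trained) "trained" else "untrained",
              object@spec$nCrp, object@spec$nCr, object@spec$lstmHidden,
              object@spec$headArrangement))
  if (nrow(object@history))
    cat(sprintf("  final epoch: loss %.4f, train accuracy %.1f%%\n",
                tail(object@history$loss, 1), 100 * tail(object@history$accuracy, 1)))
})

#' Result of a ring-toss optimization run
#'
#' @slot bestPosition best-ever position found.
#' @slot bestObjective its objective value.
#' @slot trace best-so-far objective after each iteration (non-increasing).
#' @slot evaluations total objective evaluations (N * (iterations + 1)).
#' @slot seed seed the run used.
#' @export
setClass("RTGOResult", representation(
  bestPosition = "numeric", bestObjective = "numeric", trace = "numeric",
  evaluations = "integer", seed = "numeric"
))

setValidity("RTGOResult", function(object) {
  if (length(object@trace) > 1 && any(diff(object@trace) > 1e-12))
    return("best-objective trace must be non-increasing")
  TRUE
})

setMethod("show", "RTGOResult", function(object) {
  cat(sprintf("RTGOResult: best objective %.6g after %d evaluations (%d iterations)\n",
              object@bestObjective, object@evaluations, length(object@trace)))
})
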