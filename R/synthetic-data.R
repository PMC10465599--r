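## Synthetic leaf-image generator.
##
## Real deficiency imagery is rarely redistributable, so the pipeline ships a
## seeded generator producing six visually separable stylized phenotypes on an
## elliptical leaf over a dark background (the background gives segmentation a
## genuine foreground/background task). The base pattern of each class is a
## deterministic function of the label and image size; only the additive pixel
## noise is random. Phenotype encodings (stylized, NOT photorealistic):
##   nitrogen_deficient   - uniform chlorotic yellowing of the whole blade
##   phosphorus_deficient - dark purplish patches on green tissue
##   potassium_deficient  - scorched brown margin ring, green interior
##   calcium_deficient    - necrotic dark spots clustered at the apex
##   iron_deficient       - pale interveinal chlorosis with darker green veins
##   no_deficiency        - uniform healthy green

leafPalette <- list(
  background = c(0.05, 0.06, 0.05),
  healthy    = c(0.20, 0.65, 0.15),
  yellowing  = c(0.82, 0.55, 0.18),
  purple     = c(0.35, 0.10, 0.40),
  scorch     = c(0.55, 0.35, 0.10),
  necrosis   = c(0.30, 0.18, 0.08),
  paleChlor  = c(0.75, 0.82, 0.30),
  vein       = c(0.13, 0.48, 0.12)
)

# Elliptical leaf-interior mask plus the normalized elliptical radius field
# (0 at the centre, 1 on the leaf edge) used to place margin/apex symptoms.
leafGeometry <- function(imageSize) {
  h <- imageSize[1]; w <- imageSize[2]
  y <- (seq_len(h) - (h + 1) / 2) / (0.42 * h)
  x <- (seq_len(w) - (w + 1) / 2) / (0.45 * w)
  r <- sqrt(outer(y^2, x^2, `+`))
  list(mask = r <= 1, r = r,
       xn = matrix(rep((seq_len(w) - (w + 1) / 2) / (0.45 * w), each = h), h, w),
       yn = matrix(rep(y, times = w), h, w))
}

#' Ground-truth leaf mask for a given image size
#'
#' The elliptical foreground mask every synthetic leaf is rendered on; used by
#' segmentation tests as ground truth.
#'
#' @param imageSize integer (height, width).
#' @return H x W logical matrix.
#' @export
trueLeafMask <- function(imageSize) leafGeometry(imageSize)$mask

# Deterministic noiseless phenotype pattern for one class: H x W x 3 in [0,1].
leafBasePattern <- function(label, imageSize) {
  stopIfNot(label %in% classNames(),
            sprintf("unknown class label '%s'", label))
  g <- leafGeometry(imageSize)
  h <- imageSize[1]; w <- imageSize[2]
  img <- array(rep(leafPalette$background, each = h * w), c(h, w, 3))
  paint <- function(img, where, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[where] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  img <- paint(img, g$mask, leafPalette$healthy)
  if (label == "nitrogen_deficient") {
    img <- paint(img, g$mask, leafPalette$yellowing)
  } else if (label == "phosphorus_deficient") {
    # fixed patch lattice: purplish blobs at deterministic offsets
    centres <- rbind(c(-0.45, -0.35), c(0.30, -0.45), c(-0.15, 0.25),
                     c(0.45, 0.35), c(-0.5, 0.55))
    patch <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(centres)))
      patch <- patch | ((g$yn - centres[i, 1])^2 +
                        (g$xn - centres[i, 2])^2 < 0.06)
    img <- paint(img, g$mask & patch, leafPalette$purple)
  } else if (label == "potassium_deficient") {
    img <- paint(img, g$mask & g$r >= 0.72, leafPalette$scorch)
  } else if (label == "calcium_deficient") {
    centres <- rbind(c(0.05, 0.70), c(-0.25, 0.60), c(0.30, 0.55),
                     c(0.00, 0.45), c(-0.10, 0.85))
    spots <- matrix(FALSE, h, w)
    for (i in seq_len(nrow(centres)))
      spots <- spots | ((g$yn - centres[i, 1])^2 +
                        (g$xn - centres[i, 2])^2 < 0.025)
    img <- paint(img, g$mask & spots, leafPalette$necrosis)
  } else if (label == "iron_deficient") {
    img <- paint(img, g$mask, leafPalette$paleChlor)
    yn <- g$yn; xn <- g$xn
    veins <- abs(yn) < 0.06                        # midrib
    for (c0 in seq(-0.8, 0.8, by = 0.4))           # lateral veins
      veins <- veins | abs((xn - c0) - 0.9 * yn) < 0.05
    img <- paint(img, g$mask & veins, leafPalette$vein)
  }
  img
}

#' Render one synthetic leaf image
#'
#' Renders the deterministic phenotype pattern for `label` and adds i.i.d.
#' Gaussian pixel noise with standard deviation `noiseSigma` (intensity units
#' on the [0,1] scale), clipping the result back to [0,1].
#'
#' @param label one of [classNames()].
#' @param imageSize integer (height, width), at least 16 x 16.
#' @param noiseSigma non-negative noise standard deviation.
#' @param seed optional integer; when given, the noise draw is reproducible.
#' @return H x W x 3 numeric array in [0, 1].
#' @examples
#' img <- renderLeaf("no_deficiency", c(32, 32), noiseSigma = 0)
#' range(img)
#' @export
renderLeaf <- function(label, imageSize = c(64L, 64L), noiseSigma = 0.05,
                       seed = NULL) {
  stopIfNot(all(imageSize >= 16), "imageSize must be at least 16 x 16")
  stopIfNot(noiseSigma >= 0, "noiseSigma must be non-negative")
  img <- leafBasePattern(label, imageSize)
  if (noiseSigma > 0) {
    noise <- withSeed(seed, array(rnorm(length(img), 0, noiseSigma), dim(img)))
    img <- img + noise
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' Generate a seeded synthetic dataset
#'
#' Emits exactly `classCounts[c]` images per class with a manifest row per
#' image. The whole set is a pure function of its arguments: identical calls
#' give byte-identical images and manifests (each image draws its noise from a
#' seed derived from `seed` and the image's global index).
#'
#' @param classCounts named integer vector over [classNames()] (missing names
#'   count as zero), or an unnamed length-6 vector in taxonomy order.
#' @param imageSize integer (height, width).
#' @param noiseSigma non-negative noise standard deviation.
#' @param seed integer root seed.
#' @param render if `FALSE`, only the manifest and ground-truth bookkeeping are
#'   produced (useful for schema-scale checks without allocating pixels).
#' @return A [LeafImageSet-class].
#' @examples
#' ds <- generateDataset(c(2, 2, 2, 2, 2, 2), imageSize = c(32, 32), seed = 1)
#' nImages(ds)
#' @export
generateDataset <- function(classCounts, imageSize = c(64L, 64L),
                            noiseSigma = 0.05, seed = 1L, render = TRUE) {
  cls <- classNames()
  if (is.null(names(classCounts))) {
    stopIfNot(length(classCounts) == 6, "unnamed classCounts must have length 6")
    names(classCounts) <- cls
  }
  stopIfNot(all(names(classCounts) %in% cls), "unknown class name in classCounts")
  counts <- setNames(rep(0L, 6), cls)
  counts[names(classCounts)] <- as.integer(classCounts)
  stopIfNot(all(counts >= 0), "class counts must be non-negative")
  stopIfNot(sum(counts) > 0, "dataset must contain at least one image")
  imageSize <- as.integer(imageSize)

  labels <- rep(cls, times = counts)
  n <- length(labels)
  ids <- sprintf("img_%05d_%s", seq_len(n), labels)
  man <- data.frame(id = ids,
                    path = file.path(labels, paste0(ids, ".png")),
                    label = labels, stringsAsFactors = FALSE)
  images <- list()
  if (render) {
    images <- lapply(seq_len(n), function(i)
      renderLeaf(labels[i], imageSize, noiseSigma,
                 seed = deriveSeed(seed, "generate", i)))
  }
  masks <- list(trueLeafMask(imageSize))
  new("LeafImageSet", images = images, manifest = man, masks = masks,
      imageSize = imageSize, noiseSigma = noiseSigma, seed = as.numeric(seed))
}

# Subset a LeafImageSet by manifest row indices.
subsetImageSet <- function(x, idx) {
  new("LeafImageSet",
      images = if (length(x@images)) x@images[idx] else list(),
      manifest = x@manifest[idx, , drop = FALSE],
      masks = x@masks, imageSize = x@imageSize,
      noiseSigma = x@noiseSigma, seed = x@seed)
}

#' Stratified train/test split
#'
#' Splits a dataset by class: each class contributes `round(trainFraction * n)`
#' images (half-up rounding) to the training set after a seeded within-class
#' shuffle; any global rounding remainder against
#' `round(trainFraction * total)` is corrected on the largest class. Train and
#' test are disjoint and together cover the dataset.
#'
#' @param dataset a [LeafImageSet-class].
#' @param trainFraction real in (0, 1); the conventional protocols are 0.8 and 0.7.
#' @param seed integer shuffle seed.
#' @return list with elements `train` and `test` (both `LeafImageSet`).
#' @export
splitDataset <- function(dataset, trainFraction = 0.8, seed = 1L) {
  stopIfNot(nImages(dataset) > 0, "dataset is empty")
  stopIfNot(trainFraction > 0 && trainFraction < 1,
            "trainFraction must lie strictly between 0 and 1")
  lab <- imageLabels(dataset)
  counts <- table(factor(lab, levels = classNames()))
  target <- roundHalfUp(trainFraction * as.numeric(counts))
  total <- roundHalfUp(trainFraction * length(lab))
  diffn <- total - sum(target)
  if (diffn != 0) {
    big <- which.max(as.numeric(counts))
    target[big] <- min(max(target[big] + diffn, 0), counts[big])
  }
  trainIdx <- integer(0)
  for (j in seq_along(counts)) {
    idx <- which(lab == classNames()[j])
    if (!length(idx)) next
    idx <- withSeed(deriveSeed(seed, "split", j), sample(idx))
    trainIdx <- c(trainIdx, idx[seq_len(target[j])])
  }
  trainIdx <- sort(trainIdx)
  list(train = subsetImageSet(dataset, trainIdx),
       test = subsetImageSet(dataset, setdiff(seq_along(lab), trainIdx)))
}

#' Write / read an image set as 8-bit PNGs plus a CSV manifest
#'
#' @param x a rendered [LeafImageSet-class].
#' @param dir output directory (created if needed); images land under
#'   per-class subdirectories and the manifest at `manifest.csv` with header
#'   `id,path,label`.
#' @return `dir`, invisibly.
#' @export
writeImageSet <- function(x, dir) {
  stopIfNot(length(x@images) == nImages(x), "image set is not rendered")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in unique(dirname(x@manifest$path)))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nImages(x)))
    png::writePNG(x@images[[i]], file.path(dir, x@manifest$path[i]))
  write.csv(x@manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(dir)
}

#' @param noiseSigma,seed metadata recorded on the reloaded set.
#' @rdname writeImageSet
#' @export
readImageSet <- function(dir, noiseSigma = NA_real_, seed = NA_real_) {
  man <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  images <- lapply(man$path, function(p) {
    img <- png::readPNG(file.path(dir, p))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  sz <- dim(images[[1]])[1:2]
  new("LeafImageSet", images = images, manifest = man,
      masks = list(trueLeafMask(sz)), imageSize = as.integer(sz),
      noiseSigma = if (is.na(noiseSigma)) 0 else noiseSigma,
      seed = if (is.na(seed)) 0 else seed)
}
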