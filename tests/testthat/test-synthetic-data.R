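test_that("rendered leaves are deterministic, bounded, and phenotype-separable", {
  # noiseless healthy leaf: constant within the leaf mask
  img <- renderLeaf("no_deficiency", c(32L, 32L), noiseSigma = 0)
  mask <- trueLeafMask(c(32L, 32L))
  for (ch in 1:3) expect_equal(var(img[, , ch][mask]), 0)

  # seeded determinism
  a <- renderLeaf("iron_deficient", c(32L, 32L), 0.05, seed = 9)
  b <- renderLeaf("iron_deficient", c(32L, 32L), 0.05, seed = 9)
  expect_identical(a, b)

  # pixel range invariant across labels and noise levels
  for (lab in classNames()) for (sg in c(0, 0.05, 0.4)) {
    x <- renderLeaf(lab, c(16L, 16L), sg, seed = 1)
    expect_gte(min(x), 0); expect_lte(max(x), 1)
  }

  # design-time channel ordering: nitrogen yellowing depresses the green
  # channel relative to healthy green (frozen from the base patterns)
  bn <- NutriVision:::leafBasePattern("nitrogen_deficient", c(64L, 64L))
  bh <- NutriVision:::leafBasePattern("no_deficiency", c(64L, 64L))
  expect_lt(mean(bn[, , 2]), mean(bh[, , 2]))

  expect_error(renderLeaf("boron_deficient", c(32L, 32L)), "unknown class")
  expect_error(renderLeaf("no_deficiency", c(8L, 8L)), "at least 16")
})

test_that("generateDataset emits exact class counts and is a pure function of its spec", {
  ds <- generateDataset(rep(1L, 6), imageSize = c(16L, 16L), seed = 4)
  expect_equal(nImages(ds), 6L)
  expect_setequal(imageLabels(ds), classNames())

  ds10 <- generateDataset(c(nitrogen_deficient = 10L), imageSize = c(16L, 16L),
                          seed = 4)
  expect_equal(nImages(ds10), 10L)
  expect_true(all(imageLabels(ds10) == "nitrogen_deficient"))

  # full-catalogue schema check at manifest scale
  full <- generateDataset(c(2259L, 2250L, 1923L, 1910L, 2216L, 2142L),
                          imageSize = c(16L, 16L), seed = 1, render = FALSE)
  expect_equal(nImages(full), 12700L)
  expect_equal(as.integer(table(factor(imageLabels(full), classNames()))),
               c(2259L, 2250L, 1923L, 1910L, 2216L, 2142L))

  # purity: identical spec -> identical manifest and pixels
  r1 <- generateDataset(rep(3L, 6), imageSize = c(16L, 16L), noiseSigma = 0.05,
                        seed = 12)
  r2 <- generateDataset(rep(3L, 6), imageSize = c(16L, 16L), noiseSigma = 0.05,
                        seed = 12)
  expect_identical(manifest(r1), manifest(r2))
  expect_identical(r1@images, r2@images)

  expect_error(generateDataset(rep(0L, 6)), "at least one image")
})

test_that("stratified splits honour per-class half-up rounding and stay disjoint", {
  ds <- generateDataset(c(50L, 50L, 0L, 0L, 0L, 0L), imageSize = c(16L, 16L),
                        seed = 2, render = FALSE)
  sp <- splitDataset(ds, 0.8, seed = 1)
  tab <- table(factor(imageLabels(sp$train), classNames()))
  expect_equal(as.integer(tab[1:2]), c(40L, 40L))
  expect_equal(nImages(sp$test), 20L)

  one <- generateDataset(c(10L, 0L, 0L, 0L, 0L, 0L), imageSize = c(16L, 16L),
                         seed = 2, render = FALSE)
  sp7 <- splitDataset(one, 0.7, seed = 1)
  expect_equal(nImages(sp7$train), 7L)
  expect_equal(nImages(sp7$test), 3L)

  # catalogue-scale per-class train counts, frozen from half-up rounding
  full <- generateDataset(c(2259L, 2250L, 1923L, 1910L, 2216L, 2142L),
                          imageSize = c(16L, 16L), seed = 1, render = FALSE)
  spf <- splitDataset(full, 0.8, seed = 3)
  expect_equal(as.integer(table(factor(imageLabels(spf$train), classNames()))),
               c(1807L, 1800L, 1538L, 1528L, 1773L, 1714L))

  # disjoint cover + stratification bound |train_c/n_c - f| <= 1/n_c
  ds2 <- generateDataset(c(13L, 7L, 29L, 4L, 18L, 11L), imageSize = c(16L, 16L),
                         seed = 5, render = FALSE)
  for (f in c(0.7, 0.8, 0.55)) {
    sp2 <- splitDataset(ds2, f, seed = 7)
    expect_equal(sort(c(manifest(sp2$train)$id, manifest(sp2$test)$id)),
                 sort(manifest(ds2)$id))
    trc <- as.numeric(table(factor(imageLabels(sp2$train), classNames())))
    nc <- as.numeric(table(factor(imageLabels(ds2), classNames())))
    # per-class bound 1/n_c; the largest class additionally absorbs the
    # global rounding remainder (at most 3 with six classes)
    slack <- ifelse(seq_along(nc) == which.max(nc), 4, 1)
    expect_true(all(abs(trc / nc - f) <= slack / nc + 1e-12))
  }

  expect_error(splitDataset(ds2, 1.5), "between 0 and 1")
  expect_error(splitDataset(ds2, 0), "between 0 and 1")
})

test_that("low-noise phenotypes are separable by nearest-centroid on channel means", {
  for (seed in 1:3) {
    ds <- generateDataset(rep(10L, 6), imageSize = c(32L, 32L),
                          noiseSigma = 0.05, seed = seed)
    feats <- t(vapply(ds@images, function(img) apply(img, 3, mean), numeric(3)))
    lab <- factor(imageLabels(ds), classNames())
    centroids <- apply(feats, 2, function(col) tapply(col, lab, mean))
    d2 <- outer(rowSums(feats^2), rowSums(centroids^2), `+`) -
      2 * feats %*% t(centroids)
    pred <- rownames(centroids)[max.col(-d2)]
    expect_gte(mean(pred == as.character(lab)), 0.95)
  }
})

test_that("image sets round-trip through PNG files and the CSV manifest", {
  ds <- generateDataset(rep(2L, 6), imageSize = c(16L, 16L), noiseSigma = 0.03,
                        seed = 8)
  dir <- withr::local_tempdir()
  writeImageSet(ds, dir)
  back <- readImageSet(dir)
  expect_identical(manifest(back)$label, manifest(ds)$label)
  # 8-bit quantization: within half a grey level
  expect_lt(max(abs(back@images[[5]] - ds@images[[5]])), 1 / 255)
})
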