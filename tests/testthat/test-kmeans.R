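test_that("Lloyd iterations reach the known optimum on separated 1-D pairs", {
  km <- kmeansLloyd(matrix(c(0, 0.1, 10, 10.1)), k = 2, seed = 1)
  expect_equal(sort(as.vector(km$centroids)), c(0.05, 10.05))
  expect_equal(km$inertia, 0.01, tolerance = 1e-9)
  expect_equal(km$assignments[1], km$assignments[2])
  expect_equal(km$assignments[3], km$assignments[4])

  # k = n: every point its own centroid, zero inertia
  set.seed(2)
  pts <- matrix(rnorm(10), 5, 2)
  kmn <- kmeansLloyd(pts, k = 5, seed = 1)
  expect_equal(kmn$inertia, 0)

  expect_error(kmeansLloyd(pts, k = 6), "exceeds")
  expect_error(kmeansLloyd(matrix(numeric(0), 0, 2), 1), "empty")
  expect_error(kmeansLloyd(matrix(0.5, 4, 1), 2), "degenerate")
})

test_that("restarted Lloyd matches the exhaustive-partition oracle on small instances", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    pts <- matrix(runif(12), 6, 2)
    km <- kmeansLloyd(pts, 2, seed = s, nstart = 10)
    if (km$inertia <= exhaustiveKmeans2(pts) + 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("inertia traces are non-increasing and assignments nearest-centroid consistent", {
  for (s in 1:10) {
    set.seed(s)
    pts <- matrix(rnorm(80 * 3), 80, 3)
    km <- kmeansLloyd(pts, 4, seed = s, trace = TRUE)
    expect_true(all(diff(km$trace) <= 1e-10))
    d2 <- outer(rowSums(pts^2), rowSums(km$centroids^2), `+`) -
      2 * pts %*% t(km$centroids)
    nearest <- apply(d2, 1, min)
    expect_lt(max(d2[cbind(seq_len(80), km$assignments)] - nearest), 1e-9)
  }
})

test_that("Lloyd agrees with the reference implementation on a separated fixture", {
  set.seed(11)
  pts <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
               matrix(rnorm(60, 5, 0.3), 30, 2),
               matrix(rnorm(60, c(0, 5), 0.3), 30, 2))
  ours <- kmeansLloyd(pts, 3, seed = 1, nstart = 10)
  ref <- stats::kmeans(pts, 3, nstart = 10, iter.max = 50, algorithm = "Lloyd")
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("segmentImage recovers the ROI of a synthetic leaf and flags degeneracy", {
  # two-tone image: clusters reproduce the tones exactly
  img <- matrix(0, 10, 10); img[, 6:10] <- 1
  seg <- segmentImage(img, k = 2, seed = 1)
  expect_equal(length(unique(as.vector(seg@labelMap[, 1:5]))), 1L)
  expect_equal(length(unique(as.vector(seg@labelMap[, 6:10]))), 1L)

  expect_error(segmentImage(matrix(0.5, 8, 8), k = 2), "degenerate")

  truth <- trueLeafMask(c(64L, 64L))
  for (s in 1:5) {
    leaf <- renderLeaf("potassium_deficient", c(64L, 64L), 0.02, seed = s)
    seg <- segmentImage(leaf, k = 2, seed = s)
    expect_gte(sum(seg@roiMask & truth) / sum(truth), 0.95)
    expect_lte(sum(seg@roiMask & !truth) / sum(!truth), 0.05)
    # mask area within 10% of the generator's ground truth
    expect_lt(abs(sum(seg@roiMask) / sum(truth) - 1), 0.10)
  }

  # determinism given (image, k, seed)
  leaf <- renderLeaf("iron_deficient", c(32L, 32L), 0.05, seed = 3)
  s1 <- segmentImage(leaf, k = 3, seed = 5)
  s2 <- segmentImage(leaf, k = 3, seed = 5)
  expect_identical(s1@labelMap, s2@labelMap)
  expect_identical(s1@roiMask, s2@roiMask)
})

test_that("selectROI drops the border-dominant cluster and warns on one cluster", {
  img <- matrix(0.1, 12, 12); img[4:9, 4:9] <- 0.9
  seg <- segmentImage(img, k = 2, seed = 1)
  expect_true(all(seg@roiMask[5:8, 5:8]))
  expect_false(any(seg@roiMask[1, ]))

  degenerate <- new("SegmentationResult", labelMap = matrix(0L, 6, 6),
                    centroids = matrix(0.5, 1, 1), inertia = 0,
                    roiMask = matrix(FALSE, 6, 6), k = 2L)
  expect_warning(mask <- selectROI(degenerate, matrix(0.5, 6, 6)),
                 "degenerate")
  expect_false(any(mask))
})

test_that("the local-mean feature channel is the 3x3 neighbourhood average", {
  set.seed(4)
  img <- matrix(runif(49), 7, 7)
  f <- pixelFeatures(img, useLocalMean = TRUE)
  expect_equal(ncol(f), 2L)
  expect_equal(f[, 1], as.vector(img))
  # interior pixel: plain 3x3 mean; corner: mean over the 4 available cells
  lm <- matrix(f[, 2], 7, 7)
  expect_equal(lm[4, 4], mean(img[3:5, 3:5]), tolerance = 1e-12)
  expect_equal(lm[1, 1], mean(img[1:2, 1:2]), tolerance = 1e-12)
})
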