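test_that("gaborKernel evaluates the elementary function at integer offsets", {
  # centre value: both exponentials are 1, leaving the 1/(2 pi omega^2) norm
  k <- gaborKernel(GaborParams(omega = 1, u = 0, v = 0, halfSize = 6))
  expect_equal(Re(k["0", "0"]), 1 / (2 * pi), tolerance = 1e-12)
  expect_equal(max(abs(Im(k))), 0)
  expect_equal(k, k[rev(seq_len(13)), rev(seq_len(13))],
               ignore_attr = TRUE)

  # frozen from an independent evaluation of the closed form:
  # |g(1,0)| = (1/(8 pi)) exp(-1/8), arg = 2 pi u = pi/2
  k2 <- gaborKernel(GaborParams(omega = 2, u = 0.25, v = 0, halfSize = 6))
  expect_equal(Mod(k2["0", "1"]), 0.0351134361, tolerance = 1e-8)
  expect_equal(Mod(k2["0", "1"]), (1 / (8 * pi)) * exp(-1 / 8), tolerance = 1e-12)
  expect_equal(Arg(k2["0", "1"]), pi / 2, tolerance = 1e-12)

  # u acts along columns (horizontal), v along rows (vertical)
  kv <- gaborKernel(GaborParams(omega = 2, u = 0, v = 0.25, halfSize = 3))
  expect_equal(Arg(kv["1", "0"]), pi / 2, tolerance = 1e-12)

  expect_error(GaborParams(omega = -1), "positive")
})

test_that("generated kernels are conjugate-symmetric with unit Gaussian mass", {
  set.seed(41)
  for (rep in 1:20) {
    p <- GaborParams(omega = runif(1, 0.5, 3), u = runif(1, -0.5, 0.5),
                     v = runif(1, -0.5, 0.5), halfSize = sample(3:10, 1))
    k <- gaborKernel(p)
    n <- nrow(k)
    expect_equal(max(Mod(k - Conj(k[n:1, n:1]))), 0)
    expect_gt(Re(k[(n + 1) / 2, (n + 1) / 2]), 0)
  }
  # envelope normalization: the Gaussian sums to 1 once the support is wide
  for (omega in c(1, 1.5, 2)) {
    k <- gaborKernel(GaborParams(omega = omega, u = 0, v = 0,
                                 halfSize = ceiling(6 * omega)))
    expect_true(sum(Mod(k)) >= 0.999 && sum(Mod(k)) <= 1.001)
  }
})

test_that("convolve2d performs true zero-padded convolution", {
  # constant image: interior pixels equal c * sum(kernel)
  k <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  img <- matrix(0.7, 8, 8)
  out <- convolve2d(img, k)
  expect_equal(out[3:6, 3:6],
               matrix(0.7 * sum(k), 4, 4), tolerance = 1e-12)

  # delta sifting: under true convolution the impulse reproduces the kernel
  # itself (the 180-degree rotation shows up only under correlation)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  kr <- matrix(rnorm(9), 3, 3)
  out2 <- convolve2d(imp, kr)
  expect_equal(out2[4:6, 4:6], kr, tolerance = 1e-12)
  expect_equal(max(abs(out2[-(4:6), ])), 0)

  # brute-force oracle on random (image, kernel) pairs
  set.seed(7)
  for (rep in 1:50) {
    h <- sample(3:9, 1); w <- sample(3:9, 1)
    ks <- sample(c(1, 3, 5), 1)
    img <- matrix(rnorm(h * w), h, w)
    kk <- if (rep %% 2 == 0) matrix(rnorm(ks^2), ks, ks)
          else matrix(complex(real = rnorm(ks^2), imaginary = rnorm(ks^2)), ks, ks)
    expect_lt(max(Mod(convolve2d(img, kk) - bruteConvolve2d(img, kk))), 1e-10)
  }

  # linearity
  set.seed(8)
  i1 <- matrix(rnorm(36), 6, 6); i2 <- matrix(rnorm(36), 6, 6)
  kk <- matrix(rnorm(9), 3, 3)
  expect_equal(convolve2d(2 * i1 + 3 * i2, kk),
               2 * convolve2d(i1, kk) + 3 * convolve2d(i2, kk),
               tolerance = 1e-9)

  expect_error(convolve2d(i1, matrix(1, 2, 2)), "odd")
})

test_that("gaborFilter returns a [0,1] modulus response tuned to matched frequencies", {
  expect_equal(gaborFilter(matrix(0, 10, 10)), matrix(0, 10, 10))

  set.seed(3)
  img <- matrix(runif(14 * 14), 14, 14)
  out <- gaborFilter(img, GaborParams(1.5, 0.2, -0.1, 5))
  expect_gte(min(out), 0); expect_equal(max(out), 1)

  # zero modulation: response is the max-normalized Gaussian blur
  blur <- Re(convolve2d(img, gaborKernel(GaborParams(1, 0, 0, 5))))
  expect_equal(gaborFilter(img, GaborParams(1, 0, 0, 5)), blur / max(blur),
               tolerance = 1e-12)

  # frequency selectivity on the raw modulus response: patterns respond most
  # to the kernel matching their spatial frequency content (period-2 stripes
  # at u=0.5; a checkerboard's energy sits at the diagonal (0.5, 0.5))
  rawMean <- function(img, u, v)
    mean(Mod(convolve2d(img, gaborKernel(GaborParams(2, u, v, 6)))))
  cb <- checkerboard8()
  expect_gt(rawMean(cb, 0.5, 0.5), rawMean(cb, 0.05, 0.05))
  vs <- verticalStripes8()
  expect_gt(rawMean(vs, 0.5, 0), rawMean(vs, 0.05, 0))

  # RGB input goes through luminance
  rgb <- array(runif(14 * 14 * 3), c(14, 14, 3))
  expect_equal(gaborFilter(rgb, GaborParams(1, 0, 0, 5)),
               gaborFilter(luminance(rgb), GaborParams(1, 0, 0, 5)))
  expect_equal(luminance(rgb),
               0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
})

test_that("histogram equalization flattens the intensity distribution", {
  set.seed(5)
  skewed <- matrix(rbeta(64 * 64, 5, 1.3), 64, 64)
  eq <- equalizeHist(skewed)
  expect_gte(min(eq), 0); expect_lte(max(eq), 1)
  # CDF remap: quartiles of the output are near uniform quartiles
  expect_lt(max(abs(quantile(eq, c(0.25, 0.5, 0.75)) - c(0.25, 0.5, 0.75))),
            0.05)
  # monotone: ordering of distinct intensities is preserved
  o <- order(as.vector(skewed))
  expect_true(all(diff(as.vector(eq)[o]) >= 0))
})
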