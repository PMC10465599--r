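# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / exhaustive enumeration, not the package's optimized paths.

# True convolution of a 2-D image with an odd kernel (complex allowed),
# zero-padded, same-size output: out(x,y) = sum_ij image(x-i, y-j) k(i,j).
bruteConvolve2d <- function(image, kernel) {
  h <- nrow(image); w <- ncol(image)
  hr <- (nrow(kernel) - 1) / 2; hc <- (ncol(kernel) - 1) / 2
  out <- matrix(if (is.complex(kernel)) 0+0i else 0, h, w)
  for (y in 1:h) for (x in 1:w) {
    acc <- if (is.complex(kernel)) 0+0i else 0
    for (i in -hr:hr) for (j in -hc:hc) {
      yy <- y - i; xx <- x - j
      if (yy >= 1 && yy <= h && xx >= 1 && xx <= w)
        acc <- acc + image[yy, xx] * kernel[i + hr + 1, j + hc + 1]
    }
    out[y, x] <- acc
  }
  out
}

# Cross-correlation conv layer (quadruple loop) matching conv2dLayer.
bruteConvLayer <- function(x, W, b, pad) {
  d <- dim(x); kd <- dim(W)
  oh <- d[1] + 2 * pad - kd[1] + 1; ow <- d[2] + 2 * pad - kd[2] + 1
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out <- array(0, c(oh, ow, kd[4]))
  for (oc in seq_len(kd[4])) for (y in seq_len(oh)) for (xx in seq_len(ow)) {
    s <- b[oc]
    for (ic in seq_len(d[3])) for (u in seq_len(kd[1])) for (v in seq_len(kd[2]))
      s <- s + xp[y + u - 1, xx + v - 1, ic] * W[u, v, ic, oc]
    out[y, xx, oc] <- s
  }
  out
}

# Exhaustive minimum inertia over all 2-partitions of a small point set.
exhaustiveKmeans2 <- function(pts) {
  n <- nrow(pts); best <- Inf
  for (m in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    i1 <- pts[grp, , drop = FALSE]; i2 <- pts[!grp, , drop = FALSE]
    inertia <- sum(sweep(i1, 2, colMeans(i1))^2) +
      sum(sweep(i2, 2, colMeans(i2))^2)
    best <- min(best, inertia)
  }
  best
}

# Finite-difference gradient of a scalar function of a flat vector.
numericalGradient <- function(f, theta, idx = seq_along(theta), eps = 1e-6) {
  vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps; lp <- f(tp)
    tp[i] <- tp[i] - 2 * eps; lm <- f(tp)
    (lp - lm) / (2 * eps)
  }, 0)
}

# Period-2 test patterns for the Gabor frequency-selectivity checks.
checkerboard8 <- function() (outer(1:8, 1:8, `+`)) %% 2
verticalStripes8 <- function() matrix(rep(c(0, 1), length.out = 8), 8, 8,
                                      byrow = TRUE)

referenceMetricsPath <- function() {
  system.file("extdata", "reference_class_metrics.csv", package = "NutriVision")
}
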