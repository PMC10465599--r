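## Gabor texture pre-processing.
##
## The 2-D Gabor elementary function is an isotropic Gaussian envelope
## modulated by a complex plane wave:
##   g(x, y) = 1/(2 pi omega^2) * exp(-(x^2 + y^2)/(2 omega^2))
##                              * exp(j 2 pi (u x + v y))
## Filtering is plain spatial-domain convolution (true convolution, i.e. the
## kernel is flipped; zero-padded borders; same-size output), and the
## pre-processed image is the pointwise modulus of the complex response,
## rescaled to [0, 1] by its maximum.

#' Discrete complex Gabor kernel
#'
#' Evaluates the Gabor elementary function at integer offsets
#' `x, y in [-halfSize, halfSize]`. The returned matrix is laid out like an
#' image: rows index the vertical offset y, columns the horizontal offset x,
#' so `u` is the horizontal and `v` the vertical spatial frequency. The kernel
#' is conjugate-symmetric (`g(-x,-y) = Conj(g(x,y))`) with a real positive
#' centre value `1/(2 pi omega^2)`.
#'
#' @param params a [GaborParams-class].
#' @return complex (2*halfSize+1)^2 matrix with attribute `params`.
#' @examples
#' k <- gaborKernel(GaborParams(omega = 1, u = 0, v = 0, halfSize = 6))
#' Re(k["0", "0"])  # 1/(2*pi)
#' @export
gaborKernel <- function(params) {
  validObject(params)
  hs <- params@halfSize
  off <- -hs:hs
  x <- matrix(rep(off, each = length(off)), ncol = length(off))   # columns: x
  y <- matrix(rep(off, times = length(off)), ncol = length(off))  # rows: y
  env <- exp(-(x^2 + y^2) / (2 * params@omega^2)) / (2 * pi * params@omega^2)
  phase <- 2 * pi * (params@u * x + params@v * y)
  k <- env * complex(real = cos(phase), imaginary = sin(phase))
  dimnames(k) <- list(as.character(off), as.character(off))
  attr(k, "params") <- params
  k
}

#' Spatial-domain 2-D convolution
#'
#' True convolution (the kernel is rotated 180 degrees, unlike
#' cross-correlation) with zero padding and same-size output:
#' `out(x, y) = sum_{i,j} image(x - i, y - j) * kernel(i, j)`.
#' Accepts real or complex kernels; both kernel sides must be odd.
#'
#' @param image numeric H x W matrix.
#' @param kernel numeric or complex matrix with odd dimensions.
#' @return H x W matrix, complex when the kernel is complex.
#' @export
convolve2d <- function(image, kernel) {
  stopIfNot(is.matrix(image) && length(image) > 0, "image must be a non-empty matrix")
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopIfNot(kr %% 2 == 1 && kc %% 2 == 1, "kernel sides must be odd")
  h <- nrow(image); w <- ncol(image)
  hr <- (kr - 1L) / 2L; hc <- (kc - 1L) / 2L
  cplx <- is.complex(kernel)
  pad <- matrix(if (cplx) 0+0i else 0, h + 2 * hr, w + 2 * hc)
  pad[hr + seq_len(h), hc + seq_len(w)] <- image
  out <- matrix(if (cplx) 0+0i else 0, h, w)
  for (r in seq_len(kr)) {
    i <- r - hr - 1L            # vertical offset of this kernel tap
    for (c in seq_len(kc)) {
      j <- c - hc - 1L
      kv <- kernel[r, c]
      if (kv == 0) next
      out <- out + kv * pad[(seq_len(h)) - i + hr, (seq_len(w)) - j + hc]
    }
  }
  out
}

#' RGB to luminance
#'
#' Rec. 601 weighting `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image H x W x 3 array (an H x W matrix passes through unchanged).
#' @return H x W numeric matrix.
#' @export
luminance <- function(image) {
  if (is.matrix(image)) return(image)
  stopIfNot(length(dim(image)) == 3 && dim(image)[3] >= 3,
            "expected an H x W x 3 array")
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Gabor-filter an image
#'
#' Converts RGB input to luminance, convolves with the Gabor kernel, and
#' returns the chosen real response: the pointwise modulus (default), or the
#' real or imaginary part. The response is rescaled to [0, 1] by dividing by
#' its maximum absolute value (an all-zero response stays all-zero; `real`
#' and `imag` responses are shifted by their minimum before rescaling).
#'
#' @param image H x W matrix or H x W x 3 array with values in [0, 1].
#' @param params a [GaborParams-class].
#' @param response one of `"modulus"`, `"real"`, `"imag"`.
#' @return H x W numeric matrix in [0, 1].
#' @export
gaborFilter <- function(image, params = GaborParams(),
                        response = c("modulus", "real", "imag")) {
  response <- match.arg(response)
  gray <- luminance(image)
  resp <- convolve2d(gray, gaborKernel(params))
  out <- switch(response,
                modulus = Mod(resp),
                real = { x <- Re(resp); x - min(x) },
                imag = { x <- Im(resp); x - min(x) })
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

#' Histogram equalization
#'
#' Plain cumulative-distribution remapping of a grayscale image over 256 bins,
#' offered as the optional contrast-sharpening step before segmentation.
#'
#' @param gray H x W matrix with values in [0, 1].
#' @return H x W matrix in [0, 1].
#' @export
equalizeHist <- function(gray) {
  bins <- pmin(pmax(floor(gray * 255), 0), 255) + 1
  cdf <- cumsum(tabulate(bins, nbins = 256)) / length(gray)
  matrix(cdf[bins], nrow(gray), ncol(gray))
}
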