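## Neural-network primitive layers with hand-written forward and backward
## passes. Feature maps are H x W x C numeric arrays; convolution kernels are
## kh x kw x inC x outC arrays (stride fixed at 1 throughout the networks;
## spatial downsampling happens only in pooling layers). The convolutions use
## the cross-correlation convention standard in deep learning. im2col index
## matrices are cached per shape so the inner loop is a single gather plus a
## BLAS matrix product.

.im2colCache <- new.env(parent = emptyenv())

im2colIndex <- function(h, w, ch, kh, kw, pad) {
  key <- paste(h, w, ch, kh, kw, pad, sep = "_")
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2 * pad; wp <- w + 2 * pad
  outH <- h + 2 * pad - kh + 1; outW <- w + 2 * pad - kw + 1
  base <- as.vector(outer(seq_len(outH), (seq_len(outW) - 1) * hp, `+`))
  off <- as.vector(outer(as.vector(outer(seq_len(kh) - 1,
                                         (seq_len(kw) - 1) * hp, `+`)),
                         (seq_len(ch) - 1) * hp * wp, `+`))
  idx <- outer(base, off, `+`)
  res <- list(idx = idx, outH = outH, outW = outW, hp = hp, wp = wp)
  .im2colCache[[key]] <- res
  res
}

im2col <- function(x, kh, kw, pad) {
  d <- dim(x)
  ix <- im2colIndex(d[1], d[2], d[3], kh, kw, pad)
  if (pad > 0) {
    padded <- array(0, c(ix$hp, ix$wp, d[3]))
    padded[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  } else padded <- x
  col <- padded[as.vector(ix$idx)]
  dim(col) <- dim(ix$idx)
  col
}

#' 2-D convolution layer (stride 1)
#'
#' Computes `out_p = input (x) K_p + b_p` per output channel under the
#' cross-correlation convention, stride 1, configurable zero padding.
#'
#' @param input H x W x inC numeric array.
#' @param kernels kh x kw x inC x outC numeric array.
#' @param biases numeric length outC (recycled scalar allowed).
#' @param pad non-negative integer zero padding.
#' @return (H + 2 pad - kh + 1) x (W + 2 pad - kw + 1) x outC array.
#' @examples
#' x <- array(1:16, c(4, 4, 1))
#' idk <- array(c(0, 0, 0, 0, 1, 0, 0, 0, 0), c(3, 3, 1, 1))
#' all.equal(conv2dLayer(x, idk, 0, pad = 1L)[, , 1], x[, , 1])
#' @export
conv2dLayer <- function(input, kernels, biases = 0, pad = 0L) {
  d <- dim(input); kd <- dim(kernels)
  stopIfNot(length(d) == 3 && length(kd) == 4, "input must be HxWxC, kernels khxkwxinCxoutC")
  stopIfNot(d[3] == kd[3], "input channel count does not match the kernels")
  col <- im2col(input, kd[1], kd[2], pad)
  wmat <- matrix(kernels, kd[1] * kd[2] * kd[3], kd[4])
  out <- col %*% wmat
  out <- sweep(out, 2, rep_len(biases, kd[4]), `+`)
  ix <- im2colIndex(d[1], d[2], d[3], kd[1], kd[2], pad)
  array(out, c(ix$outH, ix$outW, kd[4]))
}

# Backward pass of conv2dLayer. `col` may pass the cached forward im2col.
convBackward <- function(dOut, input, kernels, pad = 0L, col = NULL) {
  d <- dim(input); kd <- dim(kernels)
  if (is.null(col)) col <- im2col(input, kd[1], kd[2], pad)
  dmat <- matrix(dOut, ncol = kd[4])
  dW <- array(crossprod(col, dmat), kd)
  db <- colSums(dmat)
  # dInput: full cross-correlation of dOut with the 180-degree-rotated kernel,
  # input/output channels swapped; pad' = k - 1 - pad restores the input size.
  wflip <- kernels[kd[1]:1, kd[2]:1, , , drop = FALSE]
  wswap <- aperm(wflip, c(1, 2, 4, 3))
  dX <- conv2dLayer(dOut, wswap, 0, pad = kd[1] - 1L - pad)
  list(dW = dW, db = db, dX = dX)
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`.
#'
#' @param x numeric vector, matrix or array.
#' @return object of the same shape.
#' @export
relu <- function(x) { x[x < 0] <- 0; x }

reluBackward <- function(dOut, out) { dOut[out <= 0] <- 0; dOut }

#' 2x2 average pooling, stride 2
#'
#' Each output pixel is the mean of its 2x2 input block (no padding). An odd
#' trailing row or column is dropped with a warning.
#'
#' @param input H x W x C array (a matrix is treated as H x W x 1).
#' @return floor(H/2) x floor(W/2) x C array (matrix in, matrix out).
#' @examples
#' avgPool2x2(matrix(1:4, 2, 2))
#' @export
avgPool2x2 <- function(input) {
  wasMat <- is.matrix(input)
  if (wasMat) input <- array(input, c(dim(input), 1))
  d <- dim(input)
  if (d[1] %% 2 == 1 || d[2] %% 2 == 1) {
    warning("odd input dimension: trailing row/column dropped by 2x2 pooling")
    input <- input[seq_len(d[1] - d[1] %% 2), seq_len(d[2] - d[2] %% 2), ,
                   drop = FALSE]
    d <- dim(input)
  }
  oy <- seq(1, d[1], by = 2); ox <- seq(1, d[2], by = 2)
  out <- (input[oy, ox, , drop = FALSE] + input[oy + 1, ox, , drop = FALSE] +
          input[oy, ox + 1, , drop = FALSE] + input[oy + 1, ox + 1, , drop = FALSE]) / 4
  if (wasMat) matrix(out, dim(out)[1], dim(out)[2]) else out
}

avgPoolBackward <- function(dOut, inputDim) {
  od <- dim(dOut)
  dX <- array(0, inputDim)
  up <- dOut[rep(seq_len(od[1]), each = 2), rep(seq_len(od[2]), each = 2), ,
             drop = FALSE] / 4
  dX[seq_len(2 * od[1]), seq_len(2 * od[2]), ] <- up
  dX
}

globalAvgPool <- function(input) apply(input, 3, mean)

globalAvgPoolBackward <- function(dOut, inputDim) {
  sweep(array(1 / (inputDim[1] * inputDim[2]), inputDim), 3, dOut, `*`)
}

linearForward <- function(x, W, b) as.vector(x %*% W + b)

linearBackward <- function(dOut, x, W) {
  list(dW = outer(as.vector(x), dOut), db = dOut,
       dX = as.vector(W %*% dOut))
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# Cross-entropy of one sample; returns loss and the gradient wrt logits.
softmaxCrossEntropy <- function(logits, targetIndex) {
  p <- softmax(logits)
  dz <- p
  dz[targetIndex] <- dz[targetIndex] - 1
  list(loss = -log(max(p[targetIndex], 1e-12)), dLogits = dz, probs = p)
}

dropoutMask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dims)
}
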