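## Hybrid deep-learning (CNN + LSTM) classifier with coarse and fine heads.
##
## The trunk follows the classic CNN template
##   IMAGE -> [(CONV -> RELU) * N_CR -> POOL] * N_CRP -> FC
## with N_CR <= 5 conv/relu repetitions per block and 2x2 average pooling
## closing each block. The rows of the final feature map are consumed as a
## sequence by an LSTM; the final hidden state (optionally concatenated with
## externally extracted convolutional features) feeds two softmax heads
## arranged in parallel (default) or sequentially: the coarse head separates
## deficient from healthy, the fine head resolves the six classes. The coarse
## label is a deterministic function of the fine label (classes 1-5 are
## deficient, class 6 healthy).
##
## The printed LSTM equation set this follows labels the output gate with the
## cell-state symbol and omits the cell accumulation; the implementation uses
## the standard form (input, candidate without bias, forget, output gates;
## c_t = f (*) c_{t-1} + i (*) g; h_t = o (*) tanh(c_t)), the only reading
## under which h_t = o * tanh(c) is well defined.

#' HDL architecture specification
#'
#' @param nCr conv/relu repetitions per block, integer in 1..5.
#' @param nCrp number of blocks (each closed by 2x2 average pooling).
#' @param channels output channels per block (recycled to length `nCrp`).
#' @param lstmHidden LSTM hidden width.
#' @param auxDim length of the auxiliary feature vector concatenated before
#'   the heads (0 for none).
#' @param headArrangement `"parallel"` (both heads read the pre-head vector)
#'   or `"sequential"` (the fine head additionally reads the coarse
#'   probabilities).
#' @param inputSize integer (height, width, channels) of the trunk input.
#' @return list of class `hdlSpec`.
#' @export
hdlSpec <- function(nCr = 1L, nCrp = 3L, channels = c(8L, 12L, 16L),
                    lstmHidden = 24L, auxDim = 0L,
                    headArrangement = c("parallel", "sequential"),
                    inputSize = c(64L, 64L, 1L)) {
  stopIfNot(nCr >= 1 && nCr <= 5, "nCr must lie in [1, 5]")
  stopIfNot(nCrp >= 1, "nCrp must be >= 1")
  headArrangement <- match.arg(headArrangement)
  channels <- rep_len(as.integer(channels), nCrp)
  finalH <- inputSize[1] %/% (2^nCrp)
  finalW <- inputSize[2] %/% (2^nCrp)
  stopIfNot(finalH >= 1 && finalW >= 1, "too many pooling blocks for this input size")
  structure(list(
    nCr = as.integer(nCr), nCrp = as.integer(nCrp), channels = channels,
    lstmHidden = as.integer(lstmHidden), auxDim = as.integer(auxDim),
    fineClasses = 6L, coarseClasses = 2L,
    headArrangement = headArrangement, inputSize = as.integer(inputSize),
    seqLen = finalH, stepDim = finalW * channels[nCrp]
  ), class = "hdlSpec")
}

# Trunk layer graph for forwardGraph()/backwardGraph().
hdlTrunkLayers <- function(spec) {
  layers <- list(list(type = "input", name = "input", inputs = character(0)))
  prev <- "input"; inC <- spec$inputSize[3]
  for (b in seq_len(spec$nCrp)) {
    for (r in seq_len(spec$nCr)) {
      cn <- sprintf("block%d_conv%d", b, r)
      layers <- c(layers, list(
        list(type = "conv", name = cn, inputs = prev, k = 3L, pad = 1L,
             stride = 1, inC = inC, outC = spec$channels[b]),
        list(type = "relu", name = paste0(cn, "_relu"), inputs = cn)))
      prev <- paste0(cn, "_relu"); inC <- spec$channels[b]
    }
    pn <- sprintf("block%d_pool", b)
    layers <- c(layers, list(list(type = "avgpool", name = pn, inputs = prev)))
    prev <- pn
  }
  layers
}

#' One LSTM step
#'
#' Gates: `i = sigmoid(x W_ix + h W_ih + b_i)`, candidate
#' `g = tanh(x W_gx + h W_gh)` (no bias), `f = sigmoid(x W_fx + h W_fh + b_f)`,
#' `o = sigmoid(x W_ox + h W_oh + b_o)`; cell `c_t = f * c_prev + i * g`;
#' hidden `h_t = o * tanh(c_t)`.
#'
#' @param x input vector (length inputDim).
#' @param hPrev,cPrev previous hidden and cell state (length hidden).
#' @param weights list with `W_ix, W_ih, b_i, W_gx, W_gh, W_fx, W_fh, b_f,
#'   W_ox, W_oh, b_o` (`W_*x` inputDim x hidden, `W_*h` hidden x hidden).
#' @return list with `h`, `c` and the gate activations `gates = list(i, g, f, o)`.
#' @export
lstmStep <- function(x, hPrev, cPrev, weights) {
  w <- weights
  stopIfNot(length(x) == nrow(w$W_ix) && length(hPrev) == nrow(w$W_ih),
            "dimension mismatch in lstmStep")
  sig <- function(z) 1 / (1 + exp(-z))
  i <- sig(as.vector(x %*% w$W_ix + hPrev %*% w$W_ih + w$b_i))
  g <- tanh(as.vector(x %*% w$W_gx + hPrev %*% w$W_gh))
  f <- sig(as.vector(x %*% w$W_fx + hPrev %*% w$W_fh + w$b_f))
  o <- sig(as.vector(x %*% w$W_ox + hPrev %*% w$W_oh + w$b_o))
  c_t <- f * cPrev + i * g
  h_t <- o * tanh(c_t)
  list(h = h_t, c = c_t, gates = list(i = i, g = g, f = f, o = o))
}

lstmInitWeights <- function(inputDim, hidden) {
  mk <- function(nr, nc) matrix(rnorm(nr * nc, 0, 1 / sqrt(nr)), nr, nc)
  list(W_ix = mk(inputDim, hidden), W_ih = mk(hidden, hidden), b_i = rep(0, hidden),
       W_gx = mk(inputDim, hidden), W_gh = mk(hidden, hidden),
       W_fx = mk(inputDim, hidden), W_fh = mk(hidden, hidden), b_f = rep(1, hidden),
       W_ox = mk(inputDim, hidden), W_oh = mk(hidden, hidden), b_o = rep(0, hidden))
}

# Run the LSTM over a sequence (rows of `xs`); cache per-step state for BPTT.
lstmForwardSeq <- function(xs, weights, hidden) {
  T <- nrow(xs)
  h <- rep(0, hidden); c_t <- rep(0, hidden)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    st <- lstmStep(xs[t, ], h, c_t, weights)
    steps[[t]] <- list(x = xs[t, ], hPrev = h, cPrev = c_t,
                       gates = st$gates, c = st$c, h = st$h)
    h <- st$h; c_t <- st$c
  }
  list(h = h, steps = steps)
}

lstmBackwardSeq <- function(fw, weights, dhFinal) {
  w <- weights
  steps <- fw$steps
  T <- length(steps)
  hid <- length(dhFinal)
  dW <- lapply(w, function(x) x * 0)
  dh <- dhFinal; dc <- rep(0, hid)
  dxs <- matrix(0, T, length(steps[[1]]$x))
  for (t in rev(seq_len(T))) {
    s <- steps[[t]]; gt <- s$gates
    tc <- tanh(s$c)
    d_o <- dh * tc
    da_o <- d_o * gt$o * (1 - gt$o)
    dcT <- dc + dh * gt$o * (1 - tc^2)
    da_f <- dcT * s$cPrev * gt$f * (1 - gt$f)
    da_i <- dcT * gt$g * gt$i * (1 - gt$i)
    da_g <- dcT * gt$i * (1 - gt$g^2)
    dc <- dcT * gt$f
    dW$W_ix <- dW$W_ix + outer(s$x, da_i); dW$b_i <- dW$b_i + da_i
    dW$W_ih <- dW$W_ih + outer(s$hPrev, da_i)
    dW$W_gx <- dW$W_gx + outer(s$x, da_g)
    dW$W_gh <- dW$W_gh + outer(s$hPrev, da_g)
    dW$W_fx <- dW$W_fx + outer(s$x, da_f); dW$b_f <- dW$b_f + da_f
    dW$W_fh <- dW$W_fh + outer(s$hPrev, da_f)
    dW$W_ox <- dW$W_ox + outer(s$x, da_o); dW$b_o <- dW$b_o + da_o
    dW$W_oh <- dW$W_oh + outer(s$hPrev, da_o)
    dxs[t, ] <- as.vector(w$W_ix %*% da_i + w$W_gx %*% da_g +
                          w$W_fx %*% da_f + w$W_ox %*% da_o)
    dh <- as.vector(w$W_ih %*% da_i + w$W_gh %*% da_g +
                    w$W_fh %*% da_f + w$W_oh %*% da_o)
  }
  list(dW = dW, dxs = dxs)
}

# Seeded initialization of every HDL parameter group.
initHDLParams <- function(spec, seed = 1L) {
  withSeed(seed, {
    trunk <- initNetworkWeights(hdlTrunkLayers(spec), seed = NULL)
    lstm <- lstmInitWeights(spec$stepDim, spec$lstmHidden)
    pre <- spec$lstmHidden + spec$auxDim
    fineIn <- if (spec$headArrangement == "sequential")
      pre + spec$coarseClasses else pre
    heads <- list(
      coarse = list(W = matrix(rnorm(pre * spec$coarseClasses, 0, sqrt(2 / pre)),
                               pre, spec$coarseClasses),
                    b = rep(0, spec$coarseClasses)),
      fine = list(W = matrix(rnorm(fineIn * spec$fineClasses, 0, sqrt(2 / fineIn)),
                             fineIn, spec$fineClasses),
                  b = rep(0, spec$fineClasses)))
    list(trunk = trunk, lstm = lstm, heads = heads)
  })
}

# Full forward pass; with cache = TRUE keeps everything needed for backprop.
hdlForwardFull <- function(input, spec, params, aux = NULL, cache = FALSE,
                           dropMask = NULL) {
  if (is.matrix(input)) input <- array(input, c(dim(input), 1))
  layers <- hdlTrunkLayers(spec)
  fw <- forwardGraph(layers, params$trunk, input, cache = cache)
  fmap <- if (cache) fw$out else fw
  xs <- matrix(fmap, nrow = dim(fmap)[1])  # rows of the final map as timesteps
  lf <- lstmForwardSeq(xs, params$lstm, spec$lstmHidden)
  pre <- c(lf$h, if (spec$auxDim > 0) aux)
  stopIfNot(length(pre) == spec$lstmHidden + spec$auxDim,
            "auxiliary feature length does not match the model spec")
  if (!is.null(dropMask)) pre <- pre * dropMask
  coarseLogits <- linearForward(pre, params$heads$coarse$W, params$heads$coarse$b)
  coarseP <- softmax(coarseLogits)
  fineIn <- if (spec$headArrangement == "sequential") c(pre, coarseP) else pre
  fineLogits <- linearForward(fineIn, params$heads$fine$W, params$heads$fine$b)
  fineP <- softmax(fineLogits)
  res <- list(coarse = coarseP, fine = fineP)
  if (cache) {
    res$cache <- list(trunkFw = fw, layers = layers, lstmFw = lf, pre = pre,
                      fineIn = fineIn, coarseLogits = coarseLogits,
                      fineLogits = fineLogits, fmapDim = dim(fmap))
  }
  res
}

#' Forward pass of the hybrid classifier
#'
#' @param input trunk input: H x W matrix or H x W x C array matching the
#'   model's input size (typically the ROI-masked Gabor-filtered image).
#' @param model an [HDLModel-class].
#' @param aux optional auxiliary feature vector of length `auxDim`.
#' @return list with `coarse` (length-2) and `fine` (length-6) probability
#'   vectors, each summing to 1; names follow the class taxonomy.
#' @export
hdlForward <- function(input, model, aux = NULL) {
  stopIfNot(length(input) > 0, "empty input")
  out <- hdlForwardFull(input, model@spec, model@params, aux = aux)
  names(out$fine) <- model@classLevels
  names(out$coarse) <- c("deficient", "healthy")
  out[c("coarse", "fine")]
}

#' Train the hybrid classifier
#'
#' Minimizes `crossEntropy(fine) + lambda * crossEntropy(coarse)` with the
#' from-scratch Adam optimizer; coarse targets are derived from the fine
#' labels (classes 1-5 deficient, class 6 healthy). Seeded initialization and
#' shuffling make the loss trace reproducible.
#'
#' @param inputs list of trunk inputs (matrices or H x W x C arrays).
#' @param fineLabels integer vector of class indices 1..6.
#' @param spec an [hdlSpec()].
#' @param aux optional n x auxDim matrix of auxiliary features.
#' @param epochs,batchSize training budget.
#' @param hyper an [adamHyperparams()] (its `alpha` is the learning rate).
#' @param lambda coarse-loss weight (default 0.5).
#' @param dropout dropout rate on the pre-head vector during training.
#' @param seed integer seed.
#' @return A trained [HDLModel-class].
#' @export
trainHDL <- function(inputs, fineLabels, spec, aux = NULL, epochs = 20L,
                     batchSize = 16L, hyper = adamHyperparams(), lambda = 0.5,
                     dropout = 0, seed = 1L) {
  stopIfNot(length(inputs) > 0, "empty training set")
  stopIfNot(length(inputs) == length(fineLabels), "labels do not match inputs")
  if (length(unique(fineLabels)) < 2)
    warning("training set contains a single class")
  params <- initHDLParams(spec, seed = deriveSeed(seed, "network"))
  state <- adamInit(params, hyper)
  n <- length(inputs)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  preDim <- spec$lstmHidden + spec$auxDim
  withSeed(deriveSeed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      epLoss <- 0; epAcc <- 0
      for (start in seq(1, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, n)]
        gradSum <- NULL
        for (i in idx) {
          mask <- if (dropout > 0)
            as.vector(dropoutMask(c(preDim, 1), dropout)) else NULL
          fw <- hdlForwardFull(inputs[[i]], spec, params,
                               aux = if (!is.null(aux)) aux[i, ],
                               cache = TRUE, dropMask = mask)
          g <- hdlBackward(fw, spec, params, fineLabels[i], lambda, mask)
          epLoss <- epLoss + g$loss
          epAcc <- epAcc + (which.max(fw$fine) == fineLabels[i])
          gradSum <- if (is.null(gradSum)) g$grads
                     else sumParamLists(gradSum, g$grads)
        }
        grad <- scaleParamList(gradSum, 1 / length(idx))
        upd <- adamStep(state, params, grad)
        state <- upd$state; params <- upd$params
      }
      epLoss <- epLoss / n
      if (!is.finite(epLoss)) stop("training aborted: non-finite loss", call. = FALSE)
      history <- rbind(history, data.frame(epoch = ep, loss = epLoss,
                                           accuracy = epAcc / n))
    }
  })
  new("HDLModel", spec = unclass(spec), params = params, history = history,
      classLevels = classNames(), trained = TRUE)
}

hdlBackward <- function(fw, spec, params, fineLabel, lambda, dropMask) {
  cache <- fw$cache
  coarseTarget <- if (fineLabel == 6L) 2L else 1L
  ceF <- softmaxCrossEntropy(cache$fineLogits, fineLabel)
  ceC <- softmaxCrossEntropy(cache$coarseLogits, coarseTarget)
  loss <- ceF$loss + lambda * ceC$loss
  bkF <- linearBackward(ceF$dLogits, cache$fineIn, params$heads$fine$W)
  bkC <- linearBackward(lambda * ceC$dLogits, cache$pre, params$heads$coarse$W)
  preDim <- spec$lstmHidden + spec$auxDim
  dPre <- bkF$dX[seq_len(preDim)] + bkC$dX
  if (spec$headArrangement == "sequential") {
    # gradient through the coarse softmax probabilities fed to the fine head
    dCoarseP <- bkF$dX[preDim + seq_len(spec$coarseClasses)]
    p <- fw$coarse
    dCoarseLogits <- p * (dCoarseP - sum(dCoarseP * p))
    bkC2 <- linearBackward(dCoarseLogits, cache$pre, params$heads$coarse$W)
    bkC$dW <- bkC$dW + bkC2$dW; bkC$db <- bkC$db + bkC2$db
    dPre <- dPre + bkC2$dX
  }
  if (!is.null(dropMask)) dPre <- dPre * dropMask
  dh <- dPre[seq_len(spec$lstmHidden)]
  lb <- lstmBackwardSeq(cache$lstmFw, params$lstm, dh)
  dMap <- array(lb$dxs, cache$fmapDim)
  tb <- backwardGraph(cache$layers, params$trunk, cache$trunkFw, dMap)
  list(loss = loss,
       grads = list(trunk = tb$grads, lstm = lb$dW,
                    heads = list(coarse = list(W = bkC$dW, b = bkC$db),
                                 fine = list(W = bkF$dW, b = bkF$db))))
}

# Elementwise sum / scale over the nested HDL parameter structure.
sumParamLists <- function(a, b) {
  rec <- function(x, y) {
    if (is.list(x)) { for (nm in names(x)) x[[nm]] <- rec(x[[nm]], y[[nm]]); x }
    else x + y
  }
  rec(a, b)
}

scaleParamList <- function(a, s) {
  rec <- function(x) {
    if (is.list(x)) { for (nm in names(x)) x[[nm]] <- rec(x[[nm]]); x }
    else x * s
  }
  rec(a)
}

#' Predict labels for a batch of inputs
#'
#' @param object a trained [HDLModel-class].
#' @param inputs list of trunk inputs (or a single matrix/array).
#' @param aux optional n x auxDim matrix of auxiliary features.
#' @param ids optional id column; output rows are sorted by id.
#' @return data.frame with `id`, `fine_label`, `coarse_label` and the six
#'   fine-class probabilities `p1..p6`.
#' @export
setMethod("predict", "HDLModel", function(object, inputs, aux = NULL,
                                          ids = NULL) {
  stopIfNot(object@trained, "model is untrained")
  if (!is.list(inputs)) inputs <- list(inputs)
  n <- length(inputs)
  if (is.null(ids)) ids <- sprintf("sample_%05d", seq_len(n))
  probs <- matrix(0, n, 6)
  coarse <- character(n)
  for (i in seq_len(n)) {
    out <- hdlForward(inputs[[i]], object, aux = if (!is.null(aux)) aux[i, ])
    probs[i, ] <- out$fine
    coarse[i] <- names(out$coarse)[which.max(out$coarse)]
  }
  res <- data.frame(id = ids,
                    fine_label = object@classLevels[max.col(probs, "first")],
                    coarse_label = coarse, stringsAsFactors = FALSE)
  colnames(probs) <- paste0("p", 1:6)
  res <- cbind(res, probs)
  res[order(res$id), , drop = FALSE]
})

#' Coarse label implied by a fine label
#'
#' Classes 1-5 are deficient; class 6 (`no_deficiency`) is healthy.
#'
#' @param fine character vector of fine labels.
#' @return character vector of `"deficient"` / `"healthy"`.
#' @export
coarseLabel <- function(fine) coarseOf(fine)
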