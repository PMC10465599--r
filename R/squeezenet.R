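## Compact SqueezeNet-style feature extractor.
##
## Fire modules follow the squeeze/expand design: a 1x1 "squeeze" convolution
## reduces channels, then two parallel "expand" convolutions (1x1 and 3x3,
## the 3x3 padded to preserve spatial size) are concatenated along channels.
## The network keeps every convolution at stride 1 and downsamples only with
## 2x2 average pooling, postponing downsampling so activation maps stay
## large; one deep convolution uses an enlarged 5x5 filter, and a dropout
## layer sits before global average pooling to curb overfitting.
##
## Layer/connection bookkeeping convention (documented so the counts are
## meaningful): every node of the layer graph counts as one layer - the input
## node, each convolution, each ReLU, each pooling layer, each channel
## concatenation, the dropout layer, the global average pool and the linear
## feature head. A connection is a directed edge between layers; channel
## concatenations have two incoming edges, everything else one. The default
## build (stem conv + 4 fire modules of 7 nodes each + 3 pools + deep conv +
## head) has 39 layers and 42 connections.

#' Fire module specification
#'
#' @param s1x1 squeeze 1x1 filter count.
#' @param e1x1,e3x3 expand 1x1 / 3x3 filter counts; the module outputs
#'   `e1x1 + e3x3` channels. The squeeze width must not exceed that.
#' @return list of class `fireSpec`.
#' @export
fireSpec <- function(s1x1, e1x1, e3x3) {
  stopIfNot(s1x1 >= 1 && e1x1 >= 1 && e3x3 >= 1, "filter counts must be positive")
  stopIfNot(s1x1 <= e1x1 + e3x3, "squeeze width must not exceed expand width")
  structure(list(s1x1 = as.integer(s1x1), e1x1 = as.integer(e1x1),
                 e3x3 = as.integer(e3x3)), class = "fireSpec")
}

# The seven graph nodes of one fire module.
fireLayers <- function(name, input, inC, spec) {
  list(
    list(type = "conv", name = paste0(name, "_squeeze_conv"), inputs = input,
         k = 1L, pad = 0L, stride = 1, inC = inC, outC = spec$s1x1),
    list(type = "relu", name = paste0(name, "_squeeze_relu"),
         inputs = paste0(name, "_squeeze_conv")),
    list(type = "conv", name = paste0(name, "_expand1_conv"),
         inputs = paste0(name, "_squeeze_relu"),
         k = 1L, pad = 0L, stride = 1, inC = spec$s1x1, outC = spec$e1x1),
    list(type = "relu", name = paste0(name, "_expand1_relu"),
         inputs = paste0(name, "_expand1_conv")),
    list(type = "conv", name = paste0(name, "_expand3_conv"),
         inputs = paste0(name, "_squeeze_relu"),
         k = 3L, pad = 1L, stride = 1, inC = spec$s1x1, outC = spec$e3x3),
    list(type = "relu", name = paste0(name, "_expand3_relu"),
         inputs = paste0(name, "_expand3_conv")),
    list(type = "concat", name = paste0(name, "_concat"),
         inputs = c(paste0(name, "_expand1_relu"), paste0(name, "_expand3_relu")))
  )
}

#' Forward pass of one fire module
#'
#' `relu(conv1x1_squeeze)` feeding the channel concatenation of
#' `relu(conv1x1_expand)` and `relu(conv3x3_expand, pad 1)`; spatial size is
#' preserved and the output has `e1x1 + e3x3` channels.
#'
#' @param input H x W x inC array.
#' @param spec a [fireSpec()].
#' @param weights list with elements `squeeze`, `expand1`, `expand3`, each a
#'   list with `W` (kh x kw x inC x outC) and `b`.
#' @return H x W x (e1x1 + e3x3) array.
#' @export
fireModuleForward <- function(input, spec, weights) {
  s <- relu(conv2dLayer(input, weights$squeeze$W, weights$squeeze$b, pad = 0L))
  e1 <- relu(conv2dLayer(s, weights$expand1$W, weights$expand1$b, pad = 0L))
  e3 <- relu(conv2dLayer(s, weights$expand3$W, weights$expand3$b, pad = 1L))
  stopIfNot(dim(e1)[3] == spec$e1x1 && dim(e3)[3] == spec$e3x3,
            "weights do not match the fire specification")
  out <- array(0, c(dim(e1)[1:2], spec$e1x1 + spec$e3x3))
  out[, , seq_len(spec$e1x1)] <- e1
  out[, , spec$e1x1 + seq_len(spec$e3x3)] <- e3
  out
}

#' Build the compact four-fire feature extractor
#'
#' Topology: input, stem 3x3 conv + ReLU + 2x2 average pool, fire modules 1-2,
#' pool, fire modules 3-4, pool, deep 5x5 conv + ReLU, dropout, global average
#' pool, linear feature head. All convolutions stride 1. Under the counting
#' convention documented in this file the graph has 39 layers joined by 42
#' connections.
#'
#' @param featureDim output feature length (>= 1).
#' @param dropoutRate dropout probability in [0, 1).
#' @param inputSize integer (height, width, channels).
#' @param stemChannels stem convolution width.
#' @param fires list of four [fireSpec()]s.
#' @param deepChannels width of the enlarged 5x5 deep convolution.
#' @return A [NetworkSpec-class].
#' @export
buildModifiedSqueezeNet <- function(featureDim = 16L, dropoutRate = 0.5,
                                    inputSize = c(64L, 64L, 3L),
                                    stemChannels = 8L,
                                    fires = list(fireSpec(4, 8, 8), fireSpec(4, 8, 8),
                                                 fireSpec(6, 12, 12), fireSpec(6, 12, 12)),
                                    deepChannels = 32L) {
  stopIfNot(featureDim >= 1, "featureDim must be >= 1")
  stopIfNot(dropoutRate >= 0 && dropoutRate < 1, "dropoutRate must lie in [0, 1)")
  stopIfNot(length(fires) == 4, "the build uses exactly four fire modules")
  layers <- list(
    list(type = "input", name = "input", inputs = character(0)),
    list(type = "conv", name = "stem_conv", inputs = "input", k = 3L, pad = 1L,
         stride = 1, inC = inputSize[3], outC = stemChannels),
    list(type = "relu", name = "stem_relu", inputs = "stem_conv"),
    list(type = "avgpool", name = "pool1", inputs = "stem_relu")
  )
  layers <- c(layers, fireLayers("fire1", "pool1", stemChannels, fires[[1]]))
  layers <- c(layers, fireLayers("fire2", "fire1_concat",
                                 fires[[1]]$e1x1 + fires[[1]]$e3x3, fires[[2]]))
  layers <- c(layers, list(list(type = "avgpool", name = "pool2",
                                inputs = "fire2_concat")))
  layers <- c(layers, fireLayers("fire3", "pool2",
                                 fires[[2]]$e1x1 + fires[[2]]$e3x3, fires[[3]]))
  layers <- c(layers, fireLayers("fire4", "fire3_concat",
                                 fires[[3]]$e1x1 + fires[[3]]$e3x3, fires[[4]]))
  lastC <- fires[[4]]$e1x1 + fires[[4]]$e3x3
  layers <- c(layers, list(
    list(type = "avgpool", name = "pool3", inputs = "fire4_concat"),
    list(type = "conv", name = "deep_conv", inputs = "pool3", k = 5L, pad = 2L,
         stride = 1, inC = lastC, outC = deepChannels),
    list(type = "relu", name = "deep_relu", inputs = "deep_conv"),
    list(type = "dropout", name = "dropout", inputs = "deep_relu",
         rate = dropoutRate),
    list(type = "gap", name = "global_pool", inputs = "dropout"),
    list(type = "linear", name = "feature_head", inputs = "global_pool",
         inDim = deepChannels, outDim = as.integer(featureDim))
  ))
  new("NetworkSpec", layers = layers, layerCount = length(layers),
      connectionCount = sum(lengths(lapply(layers, `[[`, "inputs"))),
      featureDim = as.integer(featureDim), inputSize = as.integer(inputSize))
}

#' Seeded weight initialization for a layer graph
#'
#' He-normal initialization (`sd = sqrt(2 / fan_in)`) for convolution and
#' linear layers, zero biases.
#'
#' @param spec a [NetworkSpec-class] (or bare layer list).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return named list of `list(W, b)` per parameterized layer.
#' @export
initNetworkWeights <- function(spec, seed = 1L) {
  layers <- if (is(spec, "NetworkSpec")) spec@layers else spec
  withSeed(seed, {
    w <- list()
    for (l in layers) {
      if (l$type == "conv") {
        fan <- l$k * l$k * l$inC
        w[[l$name]] <- list(
          W = array(rnorm(l$k * l$k * l$inC * l$outC, 0, sqrt(2 / fan)),
                    c(l$k, l$k, l$inC, l$outC)),
          b = rep(0, l$outC))
      } else if (l$type == "linear") {
        w[[l$name]] <- list(
          W = matrix(rnorm(l$inDim * l$outDim, 0, sqrt(2 / l$inDim)),
                     l$inDim, l$outDim),
          b = rep(0, l$outDim))
      }
    }
    w
  })
}

# Execute a layer graph. Returns the final layer's output; with cache = TRUE
# also every intermediate activation (and dropout masks) for backprop.
# Dropout is active only in trainMode and consumes the current RNG stream.
forwardGraph <- function(layers, weights, x, trainMode = FALSE, cache = FALSE) {
  acts <- list(); masks <- list()
  for (l in layers) {
    out <- switch(l$type,
      input = x,
      conv = conv2dLayer(acts[[l$inputs]], weights[[l$name]]$W,
                         weights[[l$name]]$b, pad = l$pad),
      relu = relu(acts[[l$inputs]]),
      avgpool = avgPool2x2(acts[[l$inputs]]),
      concat = {
        a <- acts[[l$inputs[1]]]; b <- acts[[l$inputs[2]]]
        o <- array(0, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
        o[, , seq_len(dim(a)[3])] <- a
        o[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
        o
      },
      dropout = {
        inp <- acts[[l$inputs]]
        if (trainMode && l$rate > 0) {
          m <- dropoutMask(dim(inp), l$rate)
          masks[[l$name]] <- m
          inp * m
        } else inp
      },
      gap = globalAvgPool(acts[[l$inputs]]),
      linear = linearForward(acts[[l$inputs]], weights[[l$name]]$W,
                             weights[[l$name]]$b),
      stop("unknown layer type: ", l$type))
    acts[[l$name]] <- out
  }
  if (cache) list(out = acts[[layers[[length(layers)]]$name]], acts = acts,
                  masks = masks)
  else acts[[layers[[length(layers)]]$name]]
}

# Backward pass through a layer graph given the cached forward activations.
# Returns per-layer weight gradients and the gradient wrt the graph input.
backwardGraph <- function(layers, weights, fw, dFinal) {
  acts <- fw$acts
  dacts <- list()
  dacts[[layers[[length(layers)]]$name]] <- dFinal
  grads <- list()
  addGrad <- function(store, name, g) {
    if (is.null(store[[name]])) store[[name]] <- g else store[[name]] <- store[[name]] + g
    store
  }
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    dOut <- dacts[[l$name]]
    if (is.null(dOut) || l$type == "input") next
    if (l$type == "conv") {
      inp <- acts[[l$inputs]]
      bk <- convBackward(dOut, inp, weights[[l$name]]$W, pad = l$pad)
      grads[[l$name]] <- list(W = bk$dW, b = bk$db)
      dacts <- addGrad(dacts, l$inputs, bk$dX)
    } else if (l$type == "relu") {
      dacts <- addGrad(dacts, l$inputs, reluBackward(dOut, acts[[l$name]]))
    } else if (l$type == "avgpool") {
      dacts <- addGrad(dacts, l$inputs, avgPoolBackward(dOut, dim(acts[[l$inputs]])))
    } else if (l$type == "concat") {
      c1 <- dim(acts[[l$inputs[1]]])[3]
      dacts <- addGrad(dacts, l$inputs[1], dOut[, , seq_len(c1), drop = FALSE])
      dacts <- addGrad(dacts, l$inputs[2],
                       dOut[, , c1 + seq_len(dim(dOut)[3] - c1), drop = FALSE])
    } else if (l$type == "dropout") {
      m <- fw$masks[[l$name]]
      dacts <- addGrad(dacts, l$inputs, if (is.null(m)) dOut else dOut * m)
    } else if (l$type == "gap") {
      dacts <- addGrad(dacts, l$inputs,
                       globalAvgPoolBackward(dOut, dim(acts[[l$inputs]])))
    } else if (l$type == "linear") {
      bk <- linearBackward(dOut, acts[[l$inputs]], weights[[l$name]]$W)
      grads[[l$name]] <- list(W = bk$dW, b = bk$db)
      dacts <- addGrad(dacts, l$inputs, bk$dX)
    }
  }
  list(grads = grads, dInput = dacts[["input"]])
}

#' Extract feature vectors
#'
#' Runs images through the feature extractor in evaluation mode (dropout
#' disabled, hence deterministic).
#'
#' @param images a [LeafImageSet-class] or list of H x W x C arrays (matrices
#'   are treated as single-channel).
#' @param spec a [NetworkSpec-class].
#' @param weights weights from [initNetworkWeights()] or training.
#' @param trainMode enable dropout (consumes the current RNG stream).
#' @return n x featureDim numeric matrix.
#' @export
extractFeatures <- function(images, spec, weights, trainMode = FALSE) {
  if (is(images, "LeafImageSet")) images <- images@images
  if (!is.list(images)) images <- list(images)
  out <- matrix(0, length(images), spec@featureDim)
  for (i in seq_along(images)) {
    x <- images[[i]]
    if (is.matrix(x)) x <- array(x, c(dim(x), 1))
    stopIfNot(all(dim(x) == spec@inputSize),
              sprintf("image %d does not match the network input size", i))
    out[i, ] <- forwardGraph(spec@layers, weights, x, trainMode = trainMode)
  }
  out
}

#' Train the feature extractor with a temporary classification head
#'
#' Attaches a temporary six-way softmax head to the feature output, minimizes
#' cross-entropy with the from-scratch Adam optimizer, then drops the head.
#'
#' @param images list of input arrays (already preprocessed / masked).
#' @param labels integer class indices 1..6 per image.
#' @param spec a [NetworkSpec-class].
#' @param epochs,batchSize,hyper training budget and [adamHyperparams()].
#' @param seed integer seed for init, shuffling and dropout.
#' @param nClasses temporary-head width.
#' @return list with trained `weights` and per-epoch `history` data.frame.
#' @export
trainFeatureExtractor <- function(images, labels, spec, epochs = 5L,
                                  batchSize = 16L, hyper = adamHyperparams(),
                                  seed = 1L, nClasses = 6L) {
  weights <- initNetworkWeights(spec, seed = deriveSeed(seed, "network"))
  withSeed(deriveSeed(seed, "features"), {
    weights$temp_head <- list(
      W = matrix(rnorm(spec@featureDim * nClasses, 0, sqrt(2 / spec@featureDim)),
                 spec@featureDim, nClasses),
      b = rep(0, nClasses))
    state <- adamInit(weights, hyper)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          accuracy = numeric(0))
    n <- length(images)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      epLoss <- 0; epAcc <- 0
      for (start in seq(1, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1, n)]
        gradSum <- NULL
        for (i in idx) {
          x <- images[[i]]
          if (is.matrix(x)) x <- array(x, c(dim(x), 1))
          fw <- forwardGraph(spec@layers, weights[names(weights) != "temp_head"],
                             x, trainMode = TRUE, cache = TRUE)
          logits <- linearForward(fw$out, weights$temp_head$W, weights$temp_head$b)
          ce <- softmaxCrossEntropy(logits, labels[i])
          epLoss <- epLoss + ce$loss
          epAcc <- epAcc + (which.max(ce$probs) == labels[i])
          hb <- linearBackward(ce$dLogits, fw$out, weights$temp_head$W)
          bk <- backwardGraph(spec@layers, weights, fw, hb$dX)
          g <- bk$grads
          g$temp_head <- list(W = hb$dW, b = hb$db)
          gradSum <- if (is.null(gradSum)) g else addGradLists(gradSum, g)
        }
        grad <- scaleGradList(gradSum, 1 / length(idx))
        upd <- adamStep(state, weights, grad)
        state <- upd$state; weights <- upd$params
      }
      history <- rbind(history, data.frame(epoch = ep, loss = epLoss / n,
                                           accuracy = epAcc / n))
    }
    weights$temp_head <- NULL
    list(weights = weights, history = history)
  })
}

addGradLists <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else { a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W; a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b }
  }
  a
}

scaleGradList <- function(g, s) {
  for (nm in names(g)) { g[[nm]]$W <- g[[nm]]$W * s; g[[nm]]$b <- g[[nm]]$b * s }
  g
}
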