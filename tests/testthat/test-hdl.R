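tinySpec <- function(...) hdlSpec(nCr = 1L, nCrp = 2L, channels = c(3L, 4L),
                                  lstmHidden = 5L, inputSize = c(8L, 8L, 1L),
                                  ...)

zeroLstmWeights <- function(inputDim, hidden) {
  w <- NutriVision:::lstmInitWeights(inputDim, hidden)
  lapply(w, function(x) x * 0)
}

test_that("lstmStep follows the gate equations", {
  w <- zeroLstmWeights(3, 4)
  st <- lstmStep(rnorm(3), rep(0, 4), rep(0, 4), w)
  expect_equal(st$gates$i, rep(0.5, 4))
  expect_equal(st$gates$f, rep(0.5, 4))
  expect_equal(st$gates$o, rep(0.5, 4))
  expect_equal(st$gates$g, rep(0, 4))
  expect_equal(st$c, rep(0, 4))
  expect_equal(st$h, rep(0, 4))

  # zero weights with c_prev = 2: forget gate halves the cell,
  # h = 0.5 * tanh(1)
  st2 <- lstmStep(rnorm(3), rep(0, 4), rep(2, 4), w)
  expect_equal(st2$c, rep(1, 4), tolerance = 1e-12)
  expect_equal(st2$h, rep(0.5 * tanh(1), 4), tolerance = 1e-12)
  expect_equal(st2$h[1], 0.380797078, tolerance = 1e-8)

  # gate ranges under random weights
  set.seed(14)
  for (rep in 1:20) {
    wr <- NutriVision:::lstmInitWeights(6, 5)
    st3 <- lstmStep(rnorm(6), rnorm(5), rnorm(5), wr)
    for (gate in c("i", "f", "o")) {
      expect_true(all(st3$gates[[gate]] > 0 & st3$gates[[gate]] < 1))
    }
    expect_true(all(abs(st3$gates$g) < 1))
    expect_true(all(abs(st3$h) < 1))
  }
  expect_error(lstmStep(rnorm(2), rep(0, 4), rep(0, 4), w), "mismatch")
})

test_that("forward pass emits normalized probabilities from both heads", {
  spec <- tinySpec()
  params <- NutriVision:::initHDLParams(spec, seed = 1)
  # zero-initialized heads: uniform probabilities
  params$heads$coarse$W[] <- 0; params$heads$coarse$b[] <- 0
  params$heads$fine$W[] <- 0; params$heads$fine$b[] <- 0
  model <- new("HDLModel", spec = unclass(spec), params = params,
               history = data.frame(), classLevels = classNames(),
               trained = TRUE)
  out <- hdlForward(matrix(runif(64), 8, 8), model)
  expect_equal(as.vector(out$coarse), rep(1 / 2, 2), tolerance = 1e-12)
  expect_equal(as.vector(out$fine), rep(1 / 6, 6), tolerance = 1e-12)

  set.seed(15)
  for (rep in 1:20) {
    p <- NutriVision:::initHDLParams(spec, seed = rep)
    m <- new("HDLModel", spec = unclass(spec), params = p,
             history = data.frame(), classLevels = classNames(), trained = TRUE)
    o <- hdlForward(matrix(runif(64), 8, 8), m)
    expect_equal(sum(o$coarse), 1, tolerance = 1e-6)
    expect_equal(sum(o$fine), 1, tolerance = 1e-6)
    expect_true(all(o$fine >= 0))
  }
})

test_that("analytic gradients match numerical gradients for both head arrangements", {
  set.seed(16)
  inp <- matrix(runif(64), 8, 8)
  for (arrangement in c("parallel", "sequential")) {
    spec <- tinySpec(auxDim = 2L, headArrangement = arrangement)
    params <- NutriVision:::initHDLParams(spec, seed = 3)
    aux <- rnorm(2)
    lossFn <- function(p) {
      fw <- NutriVision:::hdlForwardFull(inp, spec, p, aux = aux, cache = TRUE)
      NutriVision:::softmaxCrossEntropy(fw$cache$fineLogits, 3L)$loss +
        0.5 * NutriVision:::softmaxCrossEntropy(fw$cache$coarseLogits, 1L)$loss
    }
    fw <- NutriVision:::hdlForwardFull(inp, spec, params, aux = aux, cache = TRUE)
    g <- NutriVision:::hdlBackward(fw, spec, params, 3L, 0.5, NULL)
    fl <- NutriVision:::flattenParams(params)
    gfl <- NutriVision:::flattenByRegistry(g$grads, fl$registry)
    idx <- sample(length(fl$theta), 40)
    num <- numericalGradient(function(th)
      lossFn(NutriVision:::unflattenParams(th, fl$registry)), fl$theta, idx)
    expect_lt(max(abs(num - gfl[idx])), 1e-6)
  }
})

test_that("a tiny model overfits a 12-image batch and training is seed-reproducible", {
  ds <- generateDataset(rep(2L, 6), imageSize = c(32L, 32L), noiseSigma = 0.02,
                        seed = 7)
  spec <- hdlSpec(nCr = 1L, nCrp = 2L, channels = c(6L, 8L), lstmHidden = 12L,
                  inputSize = c(32L, 32L, 1L))
  inputs <- lapply(ds@images, luminance)
  labels <- match(imageLabels(ds), classNames())
  m <- trainHDL(inputs, labels, spec, epochs = 200L, batchSize = 12L,
                hyper = adamHyperparams(alpha = 0.003), seed = 2)
  expect_equal(tail(m@history$accuracy, 1), 1)

  # memorized training images predict their own labels
  pred <- predict(m, inputs, ids = manifest(ds)$id)
  expect_equal(nrow(pred), 12L)
  expect_equal(pred$fine_label,
               imageLabels(ds)[match(pred$id, manifest(ds)$id)])
  expect_equal(pred$coarse_label, coarseLabel(pred$fine_label))
  expect_false(is.unsorted(pred$id))

  # loss trace: finite, with a strong overall decline (Adam's per-epoch
  # trajectory oscillates; the steady-progress claim is about the trend)
  h <- m@history$loss
  expect_true(all(is.finite(h)))
  expect_lt(mean(tail(h, 10)), 0.25 * mean(head(h, 10)))
  expect_lte(tail(h, 1), 1.25 * min(h))

  m2 <- trainHDL(inputs, labels, spec, epochs = 200L, batchSize = 12L,
                 hyper = adamHyperparams(alpha = 0.003), seed = 2)
  expect_identical(m@history$loss, m2@history$loss)

  expect_warning(trainHDL(inputs[1:2], c(1L, 1L), spec, epochs = 1L, seed = 1),
                 "single class")
  untrained <- new("HDLModel", spec = unclass(spec),
                   params = NutriVision:::initHDLParams(spec, 1),
                   history = data.frame(), classLevels = classNames(),
                   trained = FALSE)
  expect_error(predict(untrained, inputs[1]), "untrained")
})

test_that("model checkpoints restore predictions exactly", {
  ds <- generateDataset(rep(1L, 6), imageSize = c(16L, 16L), noiseSigma = 0.02,
                        seed = 3)
  spec <- hdlSpec(nCr = 1L, nCrp = 1L, channels = 4L, lstmHidden = 6L,
                  inputSize = c(16L, 16L, 1L))
  inputs <- lapply(ds@images, luminance)
  m <- trainHDL(inputs, match(imageLabels(ds), classNames()), spec,
                epochs = 5L, seed = 1)
  path <- withr::local_tempfile()
  saveHDLModel(m, path)
  back <- loadHDLModel(path)
  expect_identical(predict(back, inputs), predict(m, inputs))
})
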