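## End-to-end pipeline: generate -> preprocess -> segment -> extract ->
## train -> (tune) -> evaluate.
##
## All randomness flows from one root seed expanded by a documented
## per-stage derivation (deriveSeed), so a repeated run with the same config
## and seed reproduces every artifact bit for bit. Per image the chain is:
## optional histogram equalization, Gabor filtering of the luminance, K-means
## ROI segmentation of the colour image, then the ROI mask zeroes background
## pixels of both the Gabor image (the classifier-trunk input) and the RGB
## image (the feature-extractor input).

#' Default pipeline configuration
#'
#' @return nested named list of all pipeline settings with their defaults.
#' @export
defaultConfig <- function() {
  list(
    dataset = list(class_counts = setNames(rep(50L, 6), classNames()),
                   image_size = c(64L, 64L), noise_sigma = 0.02),
    preprocess = list(omega = 2, u = 0.125, v = 0, half_size = 12L,
                      response = "modulus", equalize = FALSE),
    segmentation = list(k = 3L, local_mean = FALSE, nstart = 3L),
    network = list(feature_dim = 16L, dropout = 0.5, use_features = TRUE,
                   feature_epochs = 0L,
                   n_cr = 1L, n_crp = 3L, channels = c(8L, 12L, 16L),
                   lstm_hidden = 24L, head_arrangement = "parallel"),
    optimizer = list(alpha = 0.001, beta1 = 0.9, beta2 = 0.999, eta = 1e-8,
                     epochs = 25L, batch_size = 16L, lambda = 0.5,
                     dropout = 0),
    split = list(train_fraction = 0.8),
    tuning = list(pop = 5L, iterations = 3L, epochs = 4L,
                  train_subset = 96L, val_subset = 48L)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; unknown keys are rejected and
#' every range violation is reported in one aggregated error.
#'
#' @param config path to a YAML config or a nested list (possibly partial);
#'   `NULL` or an empty file yields the full default config.
#' @return normalized config list.
#' @export
validateConfig <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopIfNot(is.list(config), "config must be a list or a YAML file path")
  def <- defaultConfig()
  errors <- character(0)
  bad <- setdiff(names(config), names(def))
  if (length(bad)) errors <- c(errors, paste("unknown config block(s):",
                                             paste(bad, collapse = ", ")))
  for (blk in intersect(names(config), names(def))) {
    extra <- setdiff(names(config[[blk]]), names(def[[blk]]))
    if (length(extra))
      errors <- c(errors, sprintf("unknown key(s) in %s: %s", blk,
                                  paste(extra, collapse = ", ")))
    for (key in intersect(names(config[[blk]]), names(def[[blk]])))
      def[[blk]][[key]] <- config[[blk]][[key]]
  }
  cfg <- def
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(cfg$split$train_fraction > 0 && cfg$split$train_fraction < 1,
      "split.train_fraction must lie strictly in (0, 1)")
  chk(cfg$network$n_cr >= 1 && cfg$network$n_cr <= 5,
      "network.n_cr must lie in [1, 5]")
  chk(cfg$dataset$noise_sigma >= 0, "dataset.noise_sigma must be >= 0")
  chk(all(cfg$dataset$image_size >= 16), "dataset.image_size must be >= 16")
  chk(cfg$segmentation$k >= 2, "segmentation.k must be >= 2")
  chk(cfg$preprocess$omega > 0, "preprocess.omega must be > 0")
  chk(cfg$network$dropout >= 0 && cfg$network$dropout < 1,
      "network.dropout must lie in [0, 1)")
  chk(cfg$optimizer$alpha > 0, "optimizer.alpha must be > 0")
  chk(all(unlist(cfg$dataset$class_counts) >= 0) &&
        sum(unlist(cfg$dataset$class_counts)) > 0,
      "dataset.class_counts must be non-negative with a positive total")
  if (length(errors)) stop("invalid configuration:\n  - ",
                           paste(errors, collapse = "\n  - "), call. = FALSE)
  cfg
}

# Preprocess + segment a rendered image set; returns the classifier inputs.
preprocessSet <- function(imgset, cfg, seed, verbose = FALSE) {
  params <- GaborParams(cfg$preprocess$omega, cfg$preprocess$u,
                        cfg$preprocess$v, cfg$preprocess$half_size)
  n <- nImages(imgset)
  trunk <- vector("list", n); masked <- vector("list", n)
  roiFrac <- numeric(n); inertia <- numeric(n)
  for (i in seq_len(n)) {
    img <- imgset@images[[i]]
    gray <- luminance(img)
    if (isTRUE(cfg$preprocess$equalize)) gray <- equalizeHist(gray)
    gab <- gaborFilter(gray, params, response = cfg$preprocess$response)
    seg <- segmentImage(img, k = cfg$segmentation$k,
                        useLocalMean = isTRUE(cfg$segmentation$local_mean),
                        seed = deriveSeed(seed, "segment", i),
                        nstart = cfg$segmentation$nstart)
    roi <- seg@roiMask
    trunk[[i]] <- gab * roi
    m <- img
    for (ch in 1:3) m[, , ch] <- m[, , ch] * roi
    masked[[i]] <- m
    roiFrac[i] <- mean(roi); inertia[i] <- seg@inertia
  }
  list(trunk = trunk, masked = masked, roiFraction = roiFrac,
       inertia = inertia)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Generates the dataset, makes the stratified split, preprocesses and
#' segments every image, extracts convolutional features, trains the hybrid
#' classifier on the training split and evaluates it on the held-out split.
#'
#' @param config a config list or YAML path (see [validateConfig()]).
#' @param seed root seed; every stage derives its own stream from it.
#' @param outDir optional output directory; when given, the manifest, ROI
#'   masks (8-bit PNG), feature CSVs, metrics JSON, confusion CSV and a run
#'   record are written there.
#' @param verbose print per-stage progress lines.
#' @return list with `model`, `report` (test-split metrics), `predictions`,
#'   `split`, `featureWeights`, `featureSpec`, `runRecord`.
#' @export
runPipeline <- function(config = NULL, seed = 1L, outDir = NULL,
                        verbose = FALSE) {
  cfg <- validateConfig(config)
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  note <- function(stage, start, extra = "") {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
    if (verbose) message(sprintf("[%s] %.1fs %s", stage, timings[[stage]], extra))
  }

  s <- tic()
  ds <- generateDataset(unlist(cfg$dataset$class_counts),
                        imageSize = cfg$dataset$image_size,
                        noiseSigma = cfg$dataset$noise_sigma,
                        seed = deriveSeed(seed, "generate"))
  note("generate", s, sprintf("n=%d", nImages(ds)))

  s <- tic()
  sp <- splitDataset(ds, cfg$split$train_fraction,
                     seed = deriveSeed(seed, "split"))
  note("split", s, sprintf("train=%d test=%d", nImages(sp$train), nImages(sp$test)))

  s <- tic()
  ppTrain <- preprocessSet(sp$train, cfg, seed)
  ppTest <- preprocessSet(sp$test, cfg, seed + 1L)
  note("preprocess", s)

  s <- tic()
  auxTrain <- NULL; auxTest <- NULL; fSpec <- NULL; fWeights <- NULL
  if (isTRUE(cfg$network$use_features)) {
    fSpec <- buildModifiedSqueezeNet(
      featureDim = cfg$network$feature_dim, dropoutRate = cfg$network$dropout,
      inputSize = c(cfg$dataset$image_size, 3L))
    if (cfg$network$feature_epochs > 0) {
      tr <- trainFeatureExtractor(
        ppTrain$masked, match(imageLabels(sp$train), classNames()), fSpec,
        epochs = cfg$network$feature_epochs,
        batchSize = cfg$optimizer$batch_size,
        seed = deriveSeed(seed, "features"))
      fWeights <- tr$weights
    } else {
      fWeights <- initNetworkWeights(fSpec, seed = deriveSeed(seed, "features"))
    }
    auxTrain <- extractFeatures(ppTrain$masked, fSpec, fWeights)
    auxTest <- extractFeatures(ppTest$masked, fSpec, fWeights)
  }
  note("extract", s)

  s <- tic()
  spec <- hdlSpec(nCr = cfg$network$n_cr, nCrp = cfg$network$n_crp,
                  channels = cfg$network$channels,
                  lstmHidden = cfg$network$lstm_hidden,
                  auxDim = if (is.null(auxTrain)) 0L else ncol(auxTrain),
                  headArrangement = cfg$network$head_arrangement,
                  inputSize = c(cfg$dataset$image_size, 1L))
  hyper <- adamHyperparams(cfg$optimizer$alpha, cfg$optimizer$beta1,
                           cfg$optimizer$beta2, cfg$optimizer$eta)
  model <- trainHDL(ppTrain$trunk, match(imageLabels(sp$train), classNames()),
                    spec, aux = auxTrain, epochs = cfg$optimizer$epochs,
                    batchSize = cfg$optimizer$batch_size, hyper = hyper,
                    lambda = cfg$optimizer$lambda,
                    dropout = cfg$optimizer$dropout,
                    seed = deriveSeed(seed, "train"))
  note("train", s)

  s <- tic()
  pred <- predict(model, ppTest$trunk, aux = auxTest,
                  ids = manifest(sp$test)$id)
  truth <- imageLabels(sp$test)[match(pred$id, manifest(sp$test)$id)]
  cm <- confusionMatrix(truth, pred$fine_label)
  report <- metricsReport(cm)
  note("evaluate", s)

  runRecord <- list(
    schema = "nutrivision-run-1",
    config = cfg, rootSeed = seed,
    stageSeeds = sapply(c("generate", "split", "segment", "features", "train"),
                        function(st) deriveSeed(seed, st)),
    timings = timings,
    counts = list(train = nImages(sp$train), test = nImages(sp$test)),
    totalSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(manifest(ds), file.path(outDir, "manifest.csv"),
              row.names = FALSE, quote = FALSE)
    maskDir <- file.path(outDir, "masks")
    dir.create(maskDir, showWarnings = FALSE)
    for (i in seq_len(nImages(sp$test)))
      png::writePNG((ppTest$trunk[[i]] > 0) * 1,
                    file.path(maskDir, paste0(manifest(sp$test)$id[i], ".png")))
    if (!is.null(auxTest)) {
      featCsv <- cbind(data.frame(id = manifest(sp$test)$id), auxTest)
      colnames(featCsv) <- c("id", paste0("f", seq_len(ncol(auxTest))))
      write.csv(featCsv, file.path(outDir, "features.csv"), row.names = FALSE,
                quote = FALSE)
    }
    writeMetricsReport(report, file.path(outDir, "metrics.json"),
                       file.path(outDir, "confusion.csv"))
    jsonlite::write_json(runRecord, file.path(outDir, "run_record.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(model = model, report = report, predictions = pred, split = sp,
       featureWeights = fWeights, featureSpec = fSpec, runRecord = runRecord,
       preprocessed = list(train = ppTrain, test = ppTest))
}

#' Evaluate a trained model on an image set
#'
#' Re-runs preprocess, segment and feature extraction on `imgset` and scores
#' the model's predictions.
#'
#' @param model a trained [HDLModel-class].
#' @param imgset a rendered [LeafImageSet-class].
#' @param cfg validated config the model was trained under.
#' @param featureSpec,featureWeights the feature extractor used at training
#'   time (`NULL` when the model uses no auxiliary features).
#' @param seed preprocessing seed.
#' @return list with `report`, `predictions`, `confusion`.
#' @export
evaluateModel <- function(model, imgset, cfg, featureSpec = NULL,
                          featureWeights = NULL, seed = 1L) {
  cfg <- validateConfig(cfg)
  pp <- preprocessSet(imgset, cfg, seed)
  aux <- NULL
  if (!is.null(featureSpec))
    aux <- extractFeatures(pp$masked, featureSpec, featureWeights)
  stopIfNot(all(imageLabels(imgset) %in% model@classLevels),
            "label set mismatch between image set and model")
  pred <- predict(model, pp$trunk, aux = aux, ids = manifest(imgset)$id)
  truth <- imageLabels(imgset)[match(pred$id, manifest(imgset)$id)]
  cm <- confusionMatrix(truth, pred$fine_label)
  list(report = metricsReport(cm), predictions = pred, confusion = cm)
}

#' Tune hyperparameters with RTGO at reduced budget
#'
#' Builds a reduced-budget tuning context from a training split (a seeded
#' subset for training, another for validation), then minimizes the
#' classifier error rate over the 4-D hyperparameter space.
#'
#' @param trunkInputs,labels preprocessed trunk inputs and integer labels.
#' @param aux optional auxiliary feature matrix.
#' @param cfg validated config (tuning block sets the budget).
#' @param seed root seed.
#' @return list with the RTGO `result`, decoded `best` hyperparameters and
#'   the tuning `context`.
#' @export
tuneHyperparameters <- function(trunkInputs, labels, aux = NULL, cfg = NULL,
                                seed = 1L) {
  cfg <- validateConfig(cfg)
  n <- length(trunkInputs)
  nTr <- min(cfg$tuning$train_subset, floor(0.67 * n))
  nVa <- min(cfg$tuning$val_subset, n - nTr)
  idx <- withSeed(deriveSeed(seed, "tune"), sample(n))
  trIdx <- idx[seq_len(nTr)]; vaIdx <- idx[nTr + seq_len(nVa)]
  baseSpec <- hdlSpec(nCr = cfg$network$n_cr, nCrp = cfg$network$n_crp,
                      channels = cfg$network$channels,
                      lstmHidden = cfg$network$lstm_hidden,
                      auxDim = if (is.null(aux)) 0L else ncol(aux),
                      headArrangement = cfg$network$head_arrangement,
                      inputSize = dim(if (is.matrix(trunkInputs[[1]]))
                        array(trunkInputs[[1]], c(dim(trunkInputs[[1]]), 1))
                        else trunkInputs[[1]]))
  context <- makeTuningContext(
    trunkInputs[trIdx], labels[trIdx], trunkInputs[vaIdx], labels[vaIdx],
    baseSpec,
    trainAux = if (!is.null(aux)) aux[trIdx, , drop = FALSE],
    valAux = if (!is.null(aux)) aux[vaIdx, , drop = FALSE],
    epochs = cfg$tuning$epochs, seed = deriveSeed(seed, "tune", 1L))
  objective <- function(x) classifierErrorFitness(x, context)
  result <- rtgoOptimize(objective, hyperparameterSpace(),
                         N = cfg$tuning$pop, iterations = cfg$tuning$iterations,
                         seed = deriveSeed(seed, "tune", 2L))
  best <- result@bestPosition
  list(result = result,
       best = list(learningRate = best[1], dropout = best[2],
                   lstmHidden = as.integer(roundHalfUp(best[3])),
                   batchSize = as.integer(roundHalfUp(best[4]))),
       context = context)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint bundles the architecture spec, all weight arrays with a
#' name/shape index, and a schema version field.
#'
#' @param model an [HDLModel-class].
#' @param path checkpoint file path.
#' @export
saveHDLModel <- function(model, path) {
  idx <- lapply(flattenParams(model@params)$registry$entries, function(e)
    list(name = paste(e$path, collapse = "."), dims = e$dims, length = e$len))
  saveRDS(list(schema = "nutrivision-checkpoint-1", spec = model@spec,
               params = model@params, history = model@history,
               classLevels = model@classLevels, index = idx), path)
}

#' @rdname saveHDLModel
#' @export
loadHDLModel <- function(path) {
  x <- readRDS(path)
  stopIfNot(identical(x$schema, "nutrivision-checkpoint-1"),
            "unrecognized checkpoint schema")
  new("HDLModel", spec = x$spec, params = x$params, history = x$history,
      classLevels = x$classLevels, trained = TRUE)
}
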