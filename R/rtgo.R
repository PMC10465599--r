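## Ring Toss Game Optimization (RTGO).
##
## A population metaheuristic for bounded minimization. Each iteration the
## best 10% of the population (at least one member) become "score bars";
## every member throws a ring at one uniformly assigned score bar: with a
## fresh r ~ U[0,1] per dimension and F = round-half-up(1 + r) in {1, 2},
## the displacement is
##   dx_d = r * (sb_d - F * x_d)   if the score bar beats the member,
##   dx_d = r * (x_d - F * sb_d)   otherwise,
## the candidate x + dx is clipped to the bounds (integral dimensions
## rounded), and replaces the member only on strict improvement (greedy
## acceptance), so the best-so-far trace is non-increasing.

#' Bounded search space
#'
#' @param lower,upper numeric bound vectors (equal length, all finite,
#'   `lower < upper`).
#' @param integer logical per-dimension integrality flags.
#' @param names optional dimension names.
#' @return list of class `searchSpace` with `m` dimensions.
#' @export
searchSpace <- function(lower, upper, integer = rep(FALSE, length(lower)),
                        names = NULL) {
  stopIfNot(length(lower) == length(upper), "bound lengths differ")
  stopIfNot(all(is.finite(lower)) && all(is.finite(upper)), "bounds must be finite")
  stopIfNot(all(lower < upper), "lower bounds must be below upper bounds")
  structure(list(lower = lower, upper = upper, integer = integer,
                 names = names, m = length(lower)), class = "searchSpace")
}

clipToSpace <- function(x, space) {
  x <- pmin(pmax(x, space$lower), space$upper)
  if (any(space$integer)) x[space$integer] <- roundHalfUp(x[space$integer])
  pmin(pmax(x, space$lower), space$upper)
}

#' Initialize and evaluate a population
#'
#' Uniform sampling within the bounds (integral dimensions rounded), followed
#' by objective evaluation of every member.
#'
#' @param objective function mapping a position vector to a finite scalar.
#' @param space a [searchSpace()].
#' @param N population size (>= 2).
#' @param seed integer seed.
#' @return list with `X` (N x m positions) and `OF` (length-N objectives).
#' @export
initPopulation <- function(objective, space, N, seed = 1L) {
  stopIfNot(N >= 2, "population size must be >= 2")
  X <- withSeed(seed, {
    mat <- matrix(runif(N * space$m), N, space$m)
    mat <- sweep(sweep(mat, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
    t(apply(mat, 1, clipToSpace, space = space))
  })
  if (space$m == 1) X <- matrix(as.vector(X), ncol = 1)
  OF <- apply(X, 1, function(x) evalObjective(objective, x))
  list(X = X, OF = OF)
}

evalObjective <- function(objective, x) {
  v <- objective(x)
  if (!is.finite(v))
    stop(sprintf("objective returned a non-finite value at (%s)",
                 paste(signif(x, 6), collapse = ", ")), call. = FALSE)
  v
}

#' Select the score bars (population elite)
#'
#' The `max(1, round(0.10 * N))` members with the smallest objective values
#' (half-up rounding; ties broken by lower member index).
#'
#' @param population list with `X` and `OF` as from [initPopulation()].
#' @return list with `SB` (positions), `OF_SB` (objectives), `idx`, `N_SB`.
#' @export
selectScoreBars <- function(population) {
  N <- length(population$OF)
  nsb <- max(1L, roundHalfUp(0.10 * N))
  ord <- order(population$OF, seq_len(N))[seq_len(nsb)]
  list(SB = population$X[ord, , drop = FALSE], OF_SB = population$OF[ord],
       idx = ord, N_SB = nsb)
}

#' One ring throw
#'
#' Draws one r ~ U[0,1] per dimension (from the current RNG stream), sets
#' F = round-half-up(1 + r) from the same r, applies the toward/away
#' displacement rule depending on whether the score bar beats the member,
#' and clips the candidate to the bounds.
#'
#' @param x member position, `ofX` its objective.
#' @param sb score-bar position, `ofSB` its objective.
#' @param space a [searchSpace()].
#' @param r optional fixed random vector (for worked examples/tests).
#' @return candidate position vector, with the per-dimension `F` draws
#'   attached as attribute `"F"`.
#' @export
ringThrow <- function(x, ofX, sb, ofSB, space, r = NULL) {
  if (is.null(r)) r <- runif(space$m)
  F <- ifelse(r >= 0.5, 2, 1)   # round-half-up(1 + r)
  dx <- ifelse(rep(ofSB < ofX, space$m), r * (sb - F * x), r * (x - F * sb))
  structure(clipToSpace(x + dx, space), F = F)
}

#' Greedy acceptance
#'
#' The candidate replaces the member only on strict improvement; ties keep
#' the incumbent.
#'
#' @param x,ofX incumbent position and objective.
#' @param cand,ofCand candidate position and objective.
#' @return list with `x`, `of`, and `accepted`.
#' @export
greedyAccept <- function(x, ofX, cand, ofCand) {
  if (ofCand < ofX) list(x = cand, of = ofCand, accepted = TRUE)
  else list(x = x, of = ofX, accepted = FALSE)
}

#' Minimize a bounded objective with RTGO
#'
#' @param objective function from position vector to finite scalar (error
#'   rate, loss, ...), minimized.
#' @param space a [searchSpace()].
#' @param N population size (>= 2).
#' @param iterations iteration budget (>= 1).
#' @param seed integer seed.
#' @return An [RTGOResult-class]; `trace` holds the best objective after each
#'   iteration and `evaluations = N * (iterations + 1)`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- rtgoOptimize(sphere, searchSpace(rep(-5, 3), rep(5, 3)),
#'                     N = 10, iterations = 25, seed = 1)
#' res@bestObjective
#' @export
rtgoOptimize <- function(objective, space, N = 30L, iterations = 100L,
                         seed = 1L) {
  stopIfNot(iterations >= 1, "iterations must be >= 1")
  pop <- initPopulation(objective, space, N, seed = seed)
  trace <- numeric(iterations)
  withSeed(seed + 1L, {
    for (it in seq_len(iterations)) {
      bars <- selectScoreBars(pop)
      assign <- sample.int(bars$N_SB, N, replace = TRUE)
      for (i in seq_len(N)) {
        j <- assign[i]
        cand <- ringThrow(pop$X[i, ], pop$OF[i], bars$SB[j, ], bars$OF_SB[j],
                          space)
        ofC <- evalObjective(objective, cand)
        acc <- greedyAccept(pop$X[i, ], pop$OF[i], cand, ofC)
        pop$X[i, ] <- acc$x; pop$OF[i] <- acc$of
      }
      trace[it] <- min(pop$OF)
    }
  })
  best <- which.min(pop$OF)
  new("RTGOResult", bestPosition = pop$X[best, ], bestObjective = pop$OF[best],
      trace = trace, evaluations = as.integer(N * (iterations + 1)),
      seed = as.numeric(seed))
}

#' Equal-budget uniform random search baseline
#'
#' Samples `N * (iterations + 1)` positions uniformly in the bounds and
#' returns the best, for budget-matched comparison against [rtgoOptimize()].
#'
#' @inheritParams rtgoOptimize
#' @return An [RTGOResult-class].
#' @export
randomSearch <- function(objective, space, N = 30L, iterations = 100L,
                         seed = 1L) {
  budget <- N * (iterations + 1)
  X <- withSeed(seed, {
    mat <- matrix(runif(budget * space$m), budget, space$m)
    mat <- sweep(sweep(mat, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
    t(apply(mat, 1, clipToSpace, space = space))
  })
  if (space$m == 1) X <- matrix(as.vector(X), ncol = 1)
  OF <- apply(X, 1, function(x) evalObjective(objective, x))
  cm <- cummin(OF)
  trace <- cm[pmin(length(cm), N * (seq_len(iterations) + 1))]
  best <- which.min(OF)
  new("RTGOResult", bestPosition = X[best, ], bestObjective = OF[best],
      trace = trace, evaluations = as.integer(budget), seed = as.numeric(seed))
}

#' Classifier-error fitness for hyperparameter tuning
#'
#' Decodes a position in the 4-D hyperparameter space (learning rate, dropout
#' rate, LSTM hidden width, batch size), trains the hybrid classifier at the
#' reduced budget held in `context`, and returns the validation error rate
#' `100 * misclassified / total` (percent) - the quantity RTGO minimizes.
#'
#' @param position numeric length-4 vector `(learningRate, dropout,
#'   lstmHidden, batchSize)`; the last two are integral.
#' @param context a tuning context from [makeTuningContext()].
#' @return validation error rate in percent.
#' @export
classifierErrorFitness <- function(position, context) {
  stopIfNot(length(position) == 4, "expected a 4-dimensional hyperparameter vector")
  lr <- position[1]; drop <- position[2]
  hidden <- as.integer(roundHalfUp(position[3]))
  batch <- as.integer(roundHalfUp(position[4]))
  stopIfNot(lr > 0 && drop >= 0 && drop < 1 && hidden >= 1 && batch >= 1,
            "hyperparameter vector failed to decode")
  spec <- hdlSpec(nCr = context$spec$nCr, nCrp = context$spec$nCrp,
                  channels = context$spec$channels, lstmHidden = hidden,
                  auxDim = context$spec$auxDim,
                  headArrangement = context$spec$headArrangement,
                  inputSize = context$spec$inputSize)
  model <- trainHDL(context$trainInputs, context$trainLabels, spec,
                    aux = context$trainAux, epochs = context$epochs,
                    batchSize = batch, hyper = adamHyperparams(alpha = lr),
                    dropout = drop, seed = context$seed)
  pred <- predict(model, context$valInputs, aux = context$valAux,
                  ids = sprintf("v%05d", seq_along(context$valInputs)))
  truth <- classNames()[context$valLabels]
  100 * mean(pred$fine_label != truth)
}

#' Bundle the data and budget a tuning fitness evaluation needs
#'
#' @param trainInputs,trainLabels,valInputs,valLabels reduced-budget training
#'   and validation data (trunk inputs and integer class labels 1..6).
#' @param spec the base [hdlSpec()] whose LSTM width the tuner overrides.
#' @param trainAux,valAux optional auxiliary feature matrices.
#' @param epochs reduced training budget per evaluation.
#' @param seed seed used for every candidate training run.
#' @return list of class `tuningContext`.
#' @export
makeTuningContext <- function(trainInputs, trainLabels, valInputs, valLabels,
                              spec, trainAux = NULL, valAux = NULL,
                              epochs = 5L, seed = 1L) {
  structure(list(trainInputs = trainInputs, trainLabels = trainLabels,
                 valInputs = valInputs, valLabels = valLabels, spec = spec,
                 trainAux = trainAux, valAux = valAux, epochs = epochs,
                 seed = seed), class = "tuningContext")
}

#' Default 4-D hyperparameter search space
#'
#' Learning rate in `[1e-4, 1e-2]`, dropout in `[0, 0.5]`, LSTM hidden width
#' in `{8..40}`, batch size in `{8..32}`.
#'
#' @return a [searchSpace()].
#' @export
hyperparameterSpace <- function() {
  searchSpace(lower = c(1e-4, 0, 8, 8), upper = c(1e-2, 0.5, 40, 32),
              integer = c(FALSE, FALSE, TRUE, TRUE),
              names = c("learningRate", "dropout", "lstmHidden", "batchSize"))
}
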