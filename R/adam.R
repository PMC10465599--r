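## From-scratch Adam optimizer.
##
## Bias-corrected first/second-moment stochastic gradient method:
##   i <- i + 1
##   m <- beta1 m + (1 - beta1) g
##   v <- beta2 v + (1 - beta2) g^2
##   mhat <- m / (1 - beta1^i);  vhat <- v / (1 - beta2^i)
##   theta <- theta - alpha * mhat / (sqrt(vhat) + eta)
## The denominator offset eta is added AFTER the square root. The optimizer
## operates on a flat parameter vector with a shape registry, so the same
## implementation serves the feature extractor and the classifier (whose
## parameters are nested lists of arrays).

#' Adam hyperparameters
#'
#' @param alpha positive step size (default 0.001).
#' @param beta1,beta2 moment decay rates in `[0, 1)` (defaults 0.9, 0.999).
#' @param eta positive denominator offset (default 1e-8).
#' @return list of class `adamHyperparams`.
#' @export
adamHyperparams <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                            eta = 1e-8) {
  stopIfNot(alpha > 0, "alpha must be positive")
  stopIfNot(eta > 0, "eta must be positive")
  stopIfNot(beta1 >= 0 && beta1 < 1, "beta1 must lie in [0, 1)")
  stopIfNot(beta2 >= 0 && beta2 < 1, "beta2 must lie in [0, 1)")
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2, eta = eta),
            class = "adamHyperparams")
}

# Flatten an arbitrarily nested parameter list (leaves are numeric arrays)
# to one vector plus a registry of paths and shapes; inverse operation below.
flattenParams <- function(params) {
  if (is.numeric(params)) {
    return(list(theta = as.vector(params),
                registry = list(flat = TRUE, dims = dim(params))))
  }
  entries <- list()
  walk <- function(x, path) {
    if (is.numeric(x)) {
      entries[[length(entries) + 1L]] <<-
        list(path = path, dims = dim(x), len = length(x))
    } else if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    } else stop("unsupported parameter leaf of class ", class(x)[1])
  }
  walk(params, character(0))
  pieces <- vector("list", length(entries))
  getLeaf <- function(x, path) { for (p in path) x <- x[[p]]; x }
  for (i in seq_along(entries))
    pieces[[i]] <- as.vector(getLeaf(params, entries[[i]]$path))
  list(theta = unlist(pieces, use.names = FALSE),
       registry = list(flat = FALSE, entries = entries))
}

# Flatten `x` in the leaf order of an existing registry, so a gradient list
# always aligns with the parameter vector regardless of its own name order.
flattenByRegistry <- function(x, registry) {
  if (isTRUE(registry$flat)) return(as.vector(x))
  pieces <- lapply(registry$entries, function(e) {
    leaf <- x
    for (p in e$path) leaf <- leaf[[p]]
    if (is.null(leaf) || length(leaf) != e$len)
      stop("gradient structure does not match parameters at ",
           paste(e$path, collapse = "."), call. = FALSE)
    as.vector(leaf)
  })
  unlist(pieces, use.names = FALSE)
}

unflattenParams <- function(theta, registry) {
  if (isTRUE(registry$flat)) {
    if (!is.null(registry$dims)) dim(theta) <- registry$dims
    return(theta)
  }
  out <- list(); pos <- 0L
  setLeaf <- function(x, path, value) {
    if (length(path) == 1) { x[[path]] <- value; return(x) }
    x[[path[1]]] <- setLeaf(if (is.null(x[[path[1]]])) list() else x[[path[1]]],
                            path[-1], value)
    x
  }
  for (e in registry$entries) {
    x <- theta[pos + seq_len(e$len)]
    if (!is.null(e$dims)) dim(x) <- e$dims
    out <- setLeaf(out, e$path, x)
    pos <- pos + e$len
  }
  out
}

#' Initialize Adam state
#'
#' Zero first and second moment vectors and step counter 0, shaped to match
#' `params` (a numeric vector/array or a nested list of arrays).
#'
#' @param params parameters to be optimized (template only; not stored).
#' @param hyper an [adamHyperparams()].
#' @return list of class `adamState` with elements `m`, `v`, `step`, `hyper`,
#'   `registry`.
#' @export
adamInit <- function(params, hyper = adamHyperparams()) {
  stopIfNot(inherits(hyper, "adamHyperparams"), "hyper must come from adamHyperparams()")
  fl <- flattenParams(params)
  structure(list(m = numeric(length(fl$theta)), v = numeric(length(fl$theta)),
                 step = 0L, hyper = hyper, registry = fl$registry),
            class = "adamState")
}

#' One Adam update
#'
#' Applies the bias-corrected moment update to `params` given `gradient`
#' (same shape as `params`).
#'
#' @param state an `adamState` from [adamInit()].
#' @param params current parameters.
#' @param gradient gradient of the objective at `params`.
#' @return list with updated `state` and `params`.
#' @examples
#' st <- adamInit(0)
#' adamStep(st, 0, 1)$params  # approx -0.001
#' @export
adamStep <- function(state, params, gradient) {
  fp <- flattenParams(params)
  g <- flattenByRegistry(gradient, fp$registry)
  stopIfNot(length(g) == length(fp$theta), "gradient shape does not match parameters")
  if (any(!is.finite(g))) stop("non-finite gradient", call. = FALSE)
  h <- state$hyper
  i <- state$step + 1L
  m <- h$beta1 * state$m + (1 - h$beta1) * g
  v <- h$beta2 * state$v + (1 - h$beta2) * g^2
  mhat <- m / (1 - h$beta1^i)
  vhat <- v / (1 - h$beta2^i)
  theta <- fp$theta - h$alpha * mhat / (sqrt(vhat) + h$eta)
  state$m <- m; state$v <- v; state$step <- i
  list(state = state, params = unflattenParams(theta, fp$registry))
}

#' Run Adam for a fixed step budget
#'
#' Convenience driver: repeatedly evaluates `gradFn(params)` and applies
#' [adamStep()], optionally stopping early when the gradient norm drops below
#' `gradTol`.
#'
#' @param params initial parameters (vector or nested list).
#' @param gradFn function returning the gradient at the current parameters.
#' @param steps fixed step budget.
#' @param hyper an [adamHyperparams()].
#' @param gradTol optional early-stop tolerance on the gradient L2 norm.
#' @return list with final `params`, `state`, and `steps` actually taken.
#' @export
adamOptimize <- function(params, gradFn, steps = 1000L,
                         hyper = adamHyperparams(), gradTol = 0) {
  state <- adamInit(params, hyper)
  for (s in seq_len(steps)) {
    g <- gradFn(params)
    if (gradTol > 0 && sqrt(sum(flattenParams(g)$theta^2)) < gradTol)
      return(list(params = params, state = state, steps = s - 1L))
    upd <- adamStep(state, params, g)
    state <- upd$state; params <- upd$params
  }
  list(params = params, state = state, steps = steps)
}

#' Serialize / restore Adam state
#'
#' Round-trips bit-exactly through R's native serialization.
#'
#' @param state an `adamState`.
#' @param path file path.
#' @export
saveAdamState <- function(state, path) saveRDS(state, path)

#' @rdname saveAdamState
#' @export
loadAdamState <- function(path) readRDS(path)
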