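sphere <- function(x) sum(x^2)

test_that("population initialization is bounded, seeded, and integrality-aware", {
  sp <- searchSpace(c(0, 1), c(1, 8), integer = c(FALSE, TRUE))
  pop <- initPopulation(sphere, sp, N = 10, seed = 3)
  expect_equal(dim(pop$X), c(10L, 2L))
  expect_true(all(pop$X[, 1] >= 0 & pop$X[, 1] <= 1))
  expect_true(all(pop$X[, 2] == round(pop$X[, 2])))
  expect_true(all(pop$X[, 2] >= 1 & pop$X[, 2] <= 8))
  expect_equal(pop$OF, apply(pop$X, 1, sphere))

  pop2 <- initPopulation(sphere, sp, N = 10, seed = 3)
  expect_identical(pop$X, pop2$X)
  expect_error(initPopulation(sphere, sp, N = 1), ">= 2")
  expect_error(searchSpace(c(0, 2), c(1, 1)), "below")
})

test_that("score bars are the best 10% (at least one), ties by index", {
  mkpop <- function(of) list(X = matrix(seq_along(of), ncol = 1), OF = of)
  expect_equal(selectScoreBars(mkpop(runif(100)))$N_SB, 10L)
  expect_equal(selectScoreBars(mkpop(runif(5)))$N_SB, 1L)

  # N = 10 admits a single score bar: the best member
  bars <- selectScoreBars(mkpop(c(3, 1, 2, 5, 4, 9, 8, 7, 6, 0)))
  expect_equal(bars$idx, 10L)
  expect_equal(bars$OF_SB, 0)
  # N = 20 admits two, returned best-first with index tie-breaks
  bars2 <- selectScoreBars(mkpop(c(3, 1, 2, 5, 4, 9, 8, 7, 6, 0,
                                   3, 1, 2, 5, 4, 9, 8, 7, 6, 30)))
  expect_equal(bars2$idx, c(10L, 2L))
  expect_equal(bars2$OF_SB, c(0, 1))

  # the 10% rule with half-up rounding across population sizes
  for (N in c(2:30, 55, 94, 95, 250, 1000)) {
    got <- selectScoreBars(list(X = matrix(0, N, 1), OF = runif(N)))$N_SB
    expect_equal(got, max(1L, floor(0.10 * N + 0.5)))
  }
})

test_that("ring throws reproduce the displacement worked examples", {
  sp <- searchSpace(-10, 10)
  # r = 0: no displacement
  expect_equal(as.vector(ringThrow(2, 5, 1, 1, sp, r = 0)), 2)
  # score bar better, r = 0.4 -> F = 1, dx = 0.4 * (1 - 2) = -0.4
  expect_equal(as.vector(ringThrow(2, 5, 1, 1, sp, r = 0.4)), 1.6,
               tolerance = 1e-12)
  # member better, r = 0.6 -> F = 2, dx = 0.6 * (2 - 2*1) = 0
  expect_equal(as.vector(ringThrow(2, 1, 1, 5, sp, r = 0.6)), 2,
               tolerance = 1e-12)
  # r = 0.5 rounds half-up to F = 2
  expect_equal(attr(ringThrow(2, 5, 1, 1, sp, r = 0.5), "F"), 2)

  # empirical F frequency over 1e5 per-dimension draws
  spBig <- searchSpace(rep(-1, 1e5), rep(1, 1e5))
  cand <- withr::with_seed(99, ringThrow(rep(0, 1e5), 1, rep(0.5, 1e5), 0, spBig))
  freq <- mean(attr(cand, "F") == 2)
  expect_gte(freq, 0.49); expect_lte(freq, 0.51)

  # candidates are clipped to bounds
  spTight <- searchSpace(0, 1)
  expect_true(all(replicate(50, as.vector(ringThrow(1, 5, 0.9, 1, spTight))) <= 1))
})

test_that("greedy acceptance is strict", {
  expect_true(greedyAccept(1, 5, 2, 4)$accepted)
  acc <- greedyAccept(1, 5, 2, 5)
  expect_false(acc$accepted)
  expect_equal(acc$x, 1)
})

test_that("optimization traces are non-increasing and respect bounds", {
  sp <- searchSpace(c(-5, -5, 0), c(5, 5, 7), integer = c(FALSE, FALSE, TRUE))
  seen <- new.env(); seen$bad <- 0L
  watched <- function(x) {
    if (any(x < sp$lower - 1e-12) || any(x > sp$upper + 1e-12) ||
        x[3] != round(x[3])) seen$bad <- seen$bad + 1L
    sum((x - c(1, -2, 3))^2)
  }
  for (s in 1:5) {
    res <- rtgoOptimize(watched, sp, N = 12, iterations = 30, seed = s)
    expect_true(all(diff(res@trace) <= 1e-12))
    expect_equal(res@evaluations, 12L * 31L)
    expect_lte(res@bestObjective, res@trace[1])
  }
  expect_equal(seen$bad, 0L)

  # constant objective: flat trace
  resC <- rtgoOptimize(function(x) 7, searchSpace(-1, 1), N = 5,
                       iterations = 10, seed = 1)
  expect_equal(resC@trace, rep(7, 10))

  expect_error(rtgoOptimize(function(x) NaN, searchSpace(-1, 1), N = 3,
                            iterations = 2, seed = 1), "non-finite")
})

test_that("the classifier-error fitness decodes hyperparameters and returns a percent", {
  ds <- generateDataset(rep(3L, 6), imageSize = c(16L, 16L), noiseSigma = 0.02,
                        seed = 5)
  inputs <- lapply(ds@images, luminance)
  labels <- match(imageLabels(ds), classNames())
  spec <- hdlSpec(nCr = 1L, nCrp = 1L, channels = 4L, lstmHidden = 6L,
                  inputSize = c(16L, 16L, 1L))
  ctx <- makeTuningContext(inputs[1:12], labels[1:12], inputs[13:18],
                           labels[13:18], spec, epochs = 2L, seed = 1)
  err <- classifierErrorFitness(c(0.003, 0.1, 6, 6), ctx)
  expect_gte(err, 0); expect_lte(err, 100)
  # error rate is 100 * wrong / total, so with 6 validation images err*6/100
  # is a whole number of misclassifications
  expect_equal(err * 6 / 100, round(err * 6 / 100), tolerance = 1e-9)
  expect_error(classifierErrorFitness(c(0.01, 0.1, 6), ctx), "4-dimensional")
  expect_error(classifierErrorFitness(c(-1, 0.1, 6, 6), ctx), "decode")
})
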