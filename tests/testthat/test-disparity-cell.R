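# Disparity-cell responses, training, tuning and diffusive coupling.

test_that("responses are template-bounded and symmetric for flat fields", {
  p <- defaultParams
  pat <- basePatterns9[[2]]
  # fully developed field: template evokes the maximum, complement the minimum
  cell <- disparityCell(saturatedField(pat), p)
  expect_gt(cellResponse(cell, pat), 0.999 * p@iB)
  expect_lt(cellResponse(cell, complementPattern(pat)), 0.001 * p@iB)
  # undeveloped symmetric field: every pattern evokes the same response
  flat <- disparityCell(flatField(9, 9), p)
  rs <- vapply(patternSet9, function(q) cellResponse(flat, q), numeric(1))
  expect_equal(rs, rep(p@iB / 2, 8))
  expect_error(cellResponse(flat, makeDisparityPattern(5, 2, 3, 1, "bar")),
               "dimensions")
})

test_that("training learns a single-pattern set and respects innate bias", {
  # single disparity plus complement: that disparity is always learned
  ps1 <- makePatternSet(9, 9, 1, seed = 3)
  cell <- trainCell(disparityCell(initReceptiveField(9, 9, seed = 4)), ps1,
                    epochs = 30, seed = 5)
  expect_identical(cell@learnedDisparity, 0L)
  # a field pre-biased toward the disparity-3 template learns disparity 3
  rf <- biasReceptiveField(initReceptiveField(9, 9, seed = 6),
                           basePatterns9[[4]], 0.2)
  cell3 <- trainCell(disparityCell(rf), patternSet9, epochs = 60, seed = 7)
  expect_identical(cell3@learnedDisparity, 3L)
  expect_identical(dim(cell3@trace), c(60L, 4L))
  # incomplete sets (no complements) are rejected
  expect_error(trainCell(disparityCell(rf), basePatterns9, epochs = 5),
               "complement")
})

test_that("training amplifies the initial preference and sharpens tuning", {
  agree <- logical(0); ratios <- numeric(0); meanInc <- numeric(0)
  for (s in 1:25) {
    cell0 <- disparityCell(initReceptiveField(9, 9, seed = childSeed(s, 1)))
    tc0 <- tuningCurve(cell0, patternSet9)
    tie <- sum(tc0@responses > max(tc0@responses) - 1e-9) > 1
    cell <- trainCell(cell0, patternSet9, epochs = 80, seed = childSeed(s, 2))
    tc <- tuningCurve(cell, patternSet9)
    r <- tc@responses
    if (!tie)
      agree <- c(agree, cell@learnedDisparity ==
                   tc0@disparities[which.max(tc0@responses)])
    ratios <- c(ratios, max(r) / mean(r[-which.max(r)]))
    meanInc <- c(meanInc,
                 mean(diff(cell@trace[, cell@learnedDisparity + 1L])))
  }
  expect_gte(mean(agree), 0.9)        # learning selects the argmax
  expect_true(all(ratios > 1.5))      # sharp tuning
  expect_true(all(meanInc > 0))       # response grows epoch over epoch
})

test_that("tuning curves report per-disparity polarity maxima", {
  cell <- disparityCell(saturatedField(basePatterns9[[2]]))
  tc <- tuningCurve(cell, patternSet9)
  expect_identical(tc@disparities, 0:3)
  expect_identical(tc@disparities[which.max(tc@responses)], 1L)
  # a cell saturated on a *complement* still peaks at that disparity
  cellC <- disparityCell(saturatedField(complementPattern(basePatterns9[[2]])))
  tcC <- tuningCurve(cellC, patternSet9)
  expect_identical(tcC@disparities[which.max(tcC@responses)], 1L)
  # bank of one
  tc1 <- tuningCurve(cell, basePatterns9[2])
  expect_length(tc1@responses, 1L)
  expect_error(tuningCurve(cell, list()), "empty")
})

test_that("hwhh interpolates the half-height crossing", {
  tri <- new("TuningCurve", disparities = 0:2, responses = c(0, 1, 0))
  expect_equal(hwhh(tri), 0.5)
  # flat curve: undefined
  flat <- new("TuningCurve", disparities = 0:3, responses = rep(1, 4))
  expect_error(hwhh(flat), "flat")
  # one side never drops to half-height: the defined side alone is used
  oneSided <- new("TuningCurve", disparities = 0:2,
                  responses = c(0.8, 1, 0.95))
  expect_equal(hwhh(oneSided), 0.5)   # left crossing at response 0.9
  # Gaussian-sampled curve matches a dense-grid brute-force oracle
  d <- -5:5
  resp <- exp(-d^2 / (2 * 1.8^2))
  curve <- new("TuningCurve", disparities = d, responses = resp)
  grid <- seq(-5, 5, by = 1e-4)
  gresp <- approx(d, resp, xout = grid)$y       # same piecewise-linear model
  half <- (max(resp) + min(resp)) / 2
  oracle <- mean(c(min(grid[gresp >= half]) * -1, max(grid[gresp >= half])))
  expect_equal(hwhh(curve), oracle, tolerance = 1e-3)
})

test_that("coupling topology is validated and infinite resistance decouples", {
  cells <- list(disparityCell(initReceptiveField(9, 9, seed = 1)),
                disparityCell(initReceptiveField(9, 9, seed = 2)))
  expect_error(coupleCells(cells, matrix(c(1, 1, 1, 0), 2, 2)), "self-loops")
  expect_error(coupleCells(cells, matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(coupleCells(cells, twoCellTopology, rCouple = -5), "rCouple")
  # rCouple = Inf: the mixing matrix is the identity and training matches
  # the standalone cell exactly
  ens <- coupleCells(cells, twoCellTopology, rCouple = Inf)
  expect_equal(ens$mixing, diag(2))
  ensT <- trainEnsemble(ens, patternSet9, epochs = 20, seed = 9)
  solo <- trainCell(cells[[1]], patternSet9, epochs = 20, seed = 9)
  expect_equal(ensT$cells[[1]]@rf@vfg1, solo@rf@vfg1)
  expect_identical(ensT$cells[[1]]@learnedDisparity, solo@learnedDisparity)
})

test_that("the output buffer is one-way: neighbours cannot back-drive a cell", {
  cell <- disparityCell(initReceptiveField(9, 9, seed = 3))
  r0 <- cellResponse(cell, basePatterns9[[1]])
  # perturbing another cell's state (its output would change) leaves this
  # cell's response bit-identical
  other <- disparityCell(initReceptiveField(9, 9, seed = 4))
  other@rf@vfg1[] <- other@params@vfgMin
  expect_identical(cellResponse(cell, basePatterns9[[1]]), r0)
})

test_that("diffusive coupling makes two cells adopt the stronger bias", {
  res <- vapply(1:10, function(s) {
    set.seed(s)
    tgt <- sample(0:3, 1)
    rf1 <- biasReceptiveField(initReceptiveField(9, 9, seed = childSeed(s, 1)),
                              patternSet9[[tgt + 1]], 0.3)
    rf2 <- initReceptiveField(9, 9, seed = childSeed(s, 2))
    ens <- coupleCells(list(disparityCell(rf1), disparityCell(rf2)),
                       twoCellTopology, rCouple = 100)
    ens <- trainEnsemble(ens, patternSet9, epochs = 60, seed = childSeed(s, 3))
    ens$cells[[1]]@learnedDisparity == ens$cells[[2]]@learnedDisparity
  }, logical(1))
  expect_true(all(res))
})
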