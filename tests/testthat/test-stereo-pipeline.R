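# Patch splicing, prefilters, winner-cell detection and the disparity map.

# one generator-matched filter bank shared by the pipeline tests
rampPatterns <- makePatternSet(9, 9, 4, style = "ramp", seed = 1)
rampBank <- makeCellBank(rampPatterns, epochs = 60, bias = 0.15, seed = 42)
getRampBank <- function() rampBank

test_that("splicing produces the documented window geometries", {
  pair <- makeStereoPair(80, 80)
  w <- extractAndSplice(pair, c(40, 40), h = 9, wL = 4, wR = 5)
  expect_identical(dim(w@intensities), c(9L, 9L))
  expect_true(w@valid)
  # window content: left patch columns around the pixel, right patch from
  # the same epipolar rows
  expect_equal(w@intensities[, 1:4], pair@left[36:44, 38:41])
  expect_equal(w@intensities[, 5:9], pair@right[36:44, 38:42])
  big <- makeStereoPair(40, 90, data.frame(row0 = 1, row1 = 40, col0 = 1,
                                           col1 = 90, d = 0))
  w2 <- extractAndSplice(big, c(20, 45), h = 10, wL = 20, wR = 20)
  expect_identical(dim(w2@intensities), c(10L, 40L))
  # corner pixel: replicate-padded and flagged
  wc <- extractAndSplice(pair, c(1, 1), 9, 4, 5)
  expect_false(wc@valid)
  expect_identical(dim(wc@intensities), c(9L, 9L))
  expect_error(extractAndSplice(pair, c(1, 1), 100, 4, 5), "geometry")
})

test_that("gaussian prefilter is an identity at sigma 0 and DC-invariant", {
  m <- matrix(runif(100), 10, 10)
  expect_identical(gaussianPrefilter(m, 0), m)
  expect_equal(gaussianPrefilter(matrix(0.7, 8, 8), 2), matrix(0.7, 8, 8))
  expect_error(gaussianPrefilter(m, -1), "sigma")
  # impulse response equals the separable discrete Gaussian kernel
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gaussianPrefilter(imp, 1)
  k <- exp(-(-3:3)^2 / 2); k <- k / sum(k)
  expect_equal(out[5:11, 5:11], outer(k, k), tolerance = 1e-12)
})

test_that("edge prefilter recovers vertical structure and kills constants", {
  expect_equal(edgePrefilter(matrix(1, 9, 9)), matrix(0, 9, 9))
  # vertical step edge: response is maximal along the step columns
  step <- cbind(matrix(0, 9, 5), matrix(1, 9, 5))
  mag <- edgePrefilter(step)
  expect_true(all(which(mag[5, ] == max(mag[5, ])) %in% c(5, 6)))
  # horizontal gradient component agrees with a brute-force loop oracle
  set.seed(8)
  img <- matrix(runif(64), 8, 8)
  d1 <- c(1, 2, 1) / 4; d2 <- c(-1, 0, 1) / 2
  refl <- function(i, n) if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  oracle <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) {
    gx <- 0; gy <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- img[refl(r + dr, 8), refl(c + dc, 8)]
      gx <- gx + v * d1[dr + 2] * d2[dc + 2]
      gy <- gy + v * d2[dr + 2] * d1[dc + 2]
    }
    oracle[r, c] <- sqrt(gx^2 + gy^2)
  }
  expect_equal(edgePrefilter(img), oracle, tolerance = 1e-12)
  # thresholded variant binarizes
  expect_true(all(edgePrefilter(step, threshold = 0.1) %in% c(0, 1)))
})

test_that("binarized ramp windows reproduce the generator's patterns", {
  pair <- makeStereoPair(80, 80)
  bank <- getRampBank()
  centers <- list(c(20, 20), c(20, 60), c(60, 20), c(60, 60))
  for (i in seq_along(centers)) {
    w <- extractAndSplice(pair, centers[[i]], 9, 4, 5)
    expect_equal(binarizeWindow(w), rampPatterns[[i]]@bits)
  }
})

test_that("winner-cell detection returns the true disparity and flags ties", {
  pair <- makeStereoPair(80, 80)
  bank <- getRampBank()
  for (px in list(c(20, 20), c(20, 60), c(60, 20), c(60, 60))) {
    det <- detectDisparity(extractAndSplice(pair, px, 9, 4, 5), bank)
    expect_identical(det$disparity, pair@groundTruth[px[1], px[2]])
    expect_true(det$valid)
    expect_length(det$responses, 4L)
  }
  # zero-contrast window: degenerate, flagged invalid, lowest disparity
  det0 <- detectDisparity(matrix(0, 9, 9), bank)
  expect_identical(det0$disparity, 0L)
  expect_false(det0$valid)
  # bank of one always answers its own disparity
  det1 <- detectDisparity(extractAndSplice(pair, c(60, 60), 9, 4, 5), bank[2])
  expect_identical(det1$disparity, 1L)
  # untrained cells are rejected
  untrained <- disparityCell(initReceptiveField(9, 9, seed = 1))
  expect_error(detectDisparity(matrix(0, 9, 9), list(untrained)), "untrained")
})

test_that("disparity maps agree with a per-pixel brute-force oracle", {
  pair <- makeStereoPair(40, 40, quadrantLayout(40, 40))
  bank <- getRampBank()
  dm <- disparityMap(pair, bank)
  set.seed(3)
  px <- cbind(sample(5:36, 12, replace = TRUE), sample(5:36, 12, replace = TRUE))
  for (i in seq_len(nrow(px))) {
    det <- detectDisparity(extractAndSplice(pair, px[i, ], 9, 4, 5), bank)
    expect_identical(dm@values[px[i, 1], px[i, 2]], det$disparity)
  }
})

test_that("maps are deterministic, accurate in region interiors, and border-flagged", {
  pair <- makeStereoPair(40, 40, quadrantLayout(40, 40))
  bank <- getRampBank()
  dm1 <- disparityMap(pair, bank)
  dm2 <- disparityMap(pair, bank)
  expect_identical(dm1@values, dm2@values)
  expect_identical(dm1@validMask, dm2@validMask)
  expect_false(any(dm1@validMask[1, ]))          # border rows padded
  im <- interiorMask(pair, 9, 4, 5)
  expect_gt(sum(im), 0)
  expect_gte(100 - averageError(dm1, pair, im), 95)
  # single-region zero-disparity pair: the valid map is identically zero
  z <- makeStereoPair(40, 40, data.frame(row0 = 1, row1 = 40, col0 = 1,
                                         col1 = 40, d = 0))
  dz <- disparityMap(z, bank)
  expect_true(all(dz@values[dz@validMask] == 0L))
})

test_that("translating the scene translates the valid region of the map", {
  bank <- getRampBank()
  lay1 <- data.frame(row0 = c(1, 16), row1 = c(15, 40),
                     col0 = c(1, 1), col1 = c(40, 40), d = c(1, 3))
  lay2 <- data.frame(row0 = c(1, 17), row1 = c(16, 40),
                     col0 = c(1, 1), col1 = c(40, 40), d = c(1, 3))
  m1 <- disparityMap(makeStereoPair(40, 40, lay1), bank)
  m2 <- disparityMap(makeStereoPair(40, 40, lay2), bank)
  rows <- 8:30  # away from image borders in both maps
  ok <- m1@validMask[rows, ] & m2@validMask[rows + 1, ]
  expect_true(all((m1@values[rows, ] == m2@values[rows + 1, ])[ok]))
})

test_that("average error is the percent mismatch over valid pixels", {
  truth <- matrix(0L, 10, 10)
  good <- new("DisparityMap", values = truth,
              validMask = matrix(TRUE, 10, 10))
  expect_equal(averageError(good, truth), 0)
  quarter <- truth; quarter[1:5, 1:5] <- 1L
  expect_equal(averageError(new("DisparityMap", values = quarter,
                                validMask = matrix(TRUE, 10, 10)), truth), 25)
  flipped <- new("DisparityMap", values = 1L - truth,
                 validMask = matrix(TRUE, 10, 10))
  expect_equal(averageError(flipped, truth), 100)
  none <- new("DisparityMap", values = truth,
              validMask = matrix(FALSE, 10, 10))
  expect_error(averageError(none, truth), "no valid pixels")
  expect_error(averageError(good, matrix(0L, 5, 5)), "shape")
})
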