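# Per-pixel disparity estimation: epipolar patches from the two images are
# spliced into a binocular window and a bank of trained disparity cells
# competes as filters; the winner's disparity labels the pixel.

#' A spliced binocular window
#'
#' @slot intensities h x (wL+wR) matrix: left patch next to right patch.
#' @slot origin (row, col) pixel coordinate in the reference (left) image.
#' @slot wL,wR patch widths.
#' @slot valid FALSE when the window needed border padding.
#' @export
setClass("SplicedWindow",
  representation(intensities = "matrix", origin = "integer",
                 wL = "integer", wR = "integer", valid = "logical"))

setMethod("show", "SplicedWindow", function(object) {
  cat("SplicedWindow", nrow(object@intensities), "x",
      ncol(object@intensities), "at (", object@origin[1], ",",
      object@origin[2], ")", if (!object@valid) "[padded]" else "", "\n")
})

#' Extract and splice epipolar patches around a pixel
#'
#' Takes an h x wL patch from the left image and an h x wR patch from the
#' same epipolar rows of the right image, both anchored so that the patch
#' top-left sits at \code{(row - floor(h/2), col - floor(w/2))} (1-based),
#' and concatenates them left | right into an h x (wL + wR) window -- the
#' ocular-dominance columnar pair the disparity cells were trained on.
#' Windows that do not fit inside the images are completed by replicate
#' padding and flagged invalid.
#'
#' @param pair a [StereoPair-class] (or list with left/right matrices).
#' @param pixel length-2 integer (row, col), 1-based, in the left image.
#' @param h,wL,wR window geometry (e.g. 9, 4, 5).
#' @return A [SplicedWindow-class].
#' @export
extractAndSplice <- function(pair, pixel, h, wL, wR) {
  left <- if (is(pair, "StereoPair")) pair@left else pair$left
  right <- if (is(pair, "StereoPair")) pair@right else pair$right
  h <- as.integer(h); wL <- as.integer(wL); wR <- as.integer(wR)
  if (h > nrow(left) || max(wL, wR) > ncol(left))
    stop("patch geometry exceeds the image size")
  r <- as.integer(pixel[1]); c <- as.integer(pixel[2])
  rows <- r - h %/% 2L + seq_len(h) - 1L
  colsL <- c - wL %/% 2L + seq_len(wL) - 1L
  colsR <- c - wR %/% 2L + seq_len(wR) - 1L
  valid <- all(rows >= 1L, rows <= nrow(left),
               colsL >= 1L, colsL <= ncol(left),
               colsR >= 1L, colsR <= ncol(right))
  ri <- boundaryIndex(rows, nrow(left), "replicate")
  cl <- boundaryIndex(colsL, ncol(left), "replicate")
  cr <- boundaryIndex(colsR, ncol(right), "replicate")
  win <- cbind(left[ri, cl, drop = FALSE], right[ri, cr, drop = FALSE])
  new("SplicedWindow", intensities = win, origin = c(r, c),
      wL = wL, wR = wR, valid = valid)
}

#' Gaussian prefilter
#'
#' Separable Gaussian smoothing with reflective boundaries; \code{sigma = 0}
#' is the identity. Works on any numeric matrix (a spliced window or a full
#' image).
#'
#' @param x numeric matrix or [SplicedWindow-class].
#' @param sigma standard deviation in pixels (>= 0).
#' @return Smoothed object of the same type.
#' @export
gaussianPrefilter <- function(x, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (is(x, "SplicedWindow")) {
    x@intensities <- gaussianPrefilter(x@intensities, sigma)
    return(x)
  }
  if (sigma == 0) return(x)
  k <- gaussianKernel(sigma)
  convolve1d(convolve1d(x, k, "rows", "reflect"), k, "cols", "reflect")
}

#' Edge prefilter (gradient magnitude)
#'
#' Sobel gradient magnitude of a grayscale image (reflective boundaries).
#' Smooth illumination differences between the two cameras are removed by
#' the differentiation, which is why edge prefiltering improves disparity
#' maps on imperfect imagery. Optionally binarized at a fixed threshold;
#' by default the magnitude image is returned and the pipeline binarizes
#' per-window at the median.
#'
#' @param image numeric matrix.
#' @param threshold optional scalar; if given, returns 0/1 at
#'   \code{magnitude > threshold}.
#' @return Numeric matrix (magnitude, or 0/1 if thresholded).
#' @export
edgePrefilter <- function(image, threshold = NULL) {
  d1 <- c(1, 2, 1) / 4   # smoothing tap
  d2 <- c(-1, 0, 1) / 2  # derivative tap
  gx <- convolve1d(convolve1d(image, d2, "cols", "reflect"), d1, "rows", "reflect")
  gy <- convolve1d(convolve1d(image, d2, "rows", "reflect"), d1, "cols", "reflect")
  mag <- sqrt(gx^2 + gy^2)
  if (!is.null(threshold)) (mag > threshold) * 1 else mag
}

#' Binarize a window at its median
#'
#' Cells consume ON/OFF pulses, so window intensities are mapped to bits by
#' thresholding at the window median (parameter-free and invariant to
#' brightness offset and contrast within the window).
#'
#' @param window numeric matrix or [SplicedWindow-class].
#' @return 0/1 matrix of the same shape.
#' @export
binarizeWindow <- function(window) {
  x <- if (is(window, "SplicedWindow")) window@intensities else window
  (x > stats::median(x)) * 1
}

#' Train a bank of disparity cells, one per disparity
#'
#' Cell \code{d} starts from a seeded random field given a small innate
#' bias toward the disparity-\code{d} template, then trains on the full
#' pattern set (all disparities plus complements). The learned preference
#' is verified; a cell that failed to acquire its target disparity raises
#' an error.
#'
#' @param patterns pattern set from [makePatternSet()] (D patterns + D
#'   complements).
#' @param params a [TsWtaParams-class].
#' @param epochs training epochs (default 80).
#' @param bias innate bias strength in volts (default 0.15).
#' @param seed global seed; cells use derived child seeds.
#' @param initRange initial floating-gate range (default 4.8-5.5 V).
#' @return List of D trained [DisparityCell-class] objects, element
#'   \code{d+1} tuned to disparity \code{d}.
#' @export
makeCellBank <- function(patterns, params = tsWtaParams(), epochs = 80,
                         bias = 0.15, seed = 1, initRange = c(4.8, 5.5)) {
  base <- checkPatternSet(patterns)
  h <- nrow(base[[1]]@bits); w <- ncol(base[[1]]@bits)
  lapply(seq_along(base), function(i) {
    rf <- initReceptiveField(h, w, seed = childSeed(seed, 100 + i), initRange)
    rf <- biasReceptiveField(rf, base[[i]], bias, params)
    cell <- disparityCell(rf, params)
    cell <- trainCell(cell, patterns, epochs = epochs,
                      seed = childSeed(seed, 200 + i))
    if (is.na(cell@learnedDisparity) ||
        cell@learnedDisparity != base[[i]]@disparity)
      stop("bank cell failed to acquire disparity ", base[[i]]@disparity)
    # the window binarization produces base-polarity bits, so the filter
    # template must have locked onto the base pattern, not its complement
    if (cellResponse(cell, base[[i]]) <
        cellResponse(cell, complementPattern(base[[i]])))
      stop("bank cell for disparity ", base[[i]]@disparity,
           " learned the complementary polarity; increase the bias")
    cell
  })
}

## Precompute the linear form of each cell's response to a bit matrix:
## response = b0 + sum(bits * p). Used to score many windows cheaply.
bankWeights <- function(bank) {
  lapply(bank, function(cell) {
    s1 <- fieldShares(cell@rf, cell@params)
    n <- length(s1)
    list(b0 = cell@params@iB * sum(1 - s1) / n,
         p = cell@params@iB * (2 * s1 - 1) / n)
  })
}

#' Detect the disparity of one spliced window
#'
#' The window is binarized at its median and every cell of the bank
#' responds; the cell with the highest response wins and its disparity is
#' returned. Ties (including zero-contrast windows, which are degenerate
#' under median binarization) resolve to the lowest disparity and are
#' flagged invalid.
#'
#' @param window a [SplicedWindow-class] or numeric matrix.
#' @param bank list of trained [DisparityCell-class]s from [makeCellBank()].
#' @return List with elements \code{disparity}, \code{responses} (named by
#'   disparity), and \code{valid}.
#' @export
detectDisparity <- function(window, bank) {
  for (cell in bank)
    if (is.na(cell@learnedDisparity))
      stop("bank contains an untrained (or ambiguous) cell")
  d <- vapply(bank, function(cl) cl@learnedDisparity, integer(1))
  o <- order(d)
  bank <- bank[o]; d <- d[o]
  bits <- binarizeWindow(window)
  resp <- vapply(bank, function(cl) responseToBits(cl@rf, bits, cl@params),
                 numeric(1))
  names(resp) <- d
  top <- which(resp > max(resp) - 1e-12)
  degenerate <- length(top) > 1L || stats::var(as.vector(
    if (is(window, "SplicedWindow")) window@intensities else window)) == 0
  winValid <- if (is(window, "SplicedWindow")) window@valid else TRUE
  list(disparity = d[top[1L]], responses = resp,
       valid = winValid && !degenerate)
}

#' Compute a per-pixel disparity map
#'
#' Optionally prefilters both images (edge magnitude, then Gaussian
#' smoothing -- applied at image level, which for interior pixels is
#' equivalent to filtering each spliced window and avoids smearing across
#' the splice seam), then runs [detectDisparity()] on the spliced window of
#' every pixel. Deterministic given its inputs.
#'
#' @param pair a [StereoPair-class].
#' @param bank trained cell bank from [makeCellBank()].
#' @param h,wL,wR window geometry; defaults from the bank's field shape.
#' @param sigma Gaussian prefilter width (0 = off).
#' @param edges logical; apply the edge (gradient-magnitude) prefilter.
#' @return A [DisparityMap-class]; border and tie pixels have
#'   \code{validMask = FALSE}.
#' @export
disparityMap <- function(pair, bank, h = NULL, wL = NULL, wR = NULL,
                         sigma = 0, edges = FALSE) {
  rf0 <- bank[[1]]@rf
  h <- as.integer(h %||% nrow(rf0@vfg1))
  wL <- as.integer(wL %||% rf0@wL)
  wR <- as.integer(wR %||% rf0@wR)
  if (h != nrow(rf0@vfg1) || wL + wR != ncol(rf0@vfg1))
    stop("window geometry does not match the bank's receptive fields")
  H <- nrow(pair@left); W <- ncol(pair@left)
  if (h > H || max(wL, wR) > W) stop("patch geometry exceeds the image size")
  left <- pair@left; right <- pair@right
  if (edges) { left <- edgePrefilter(left); right <- edgePrefilter(right) }
  if (sigma > 0) {
    left <- gaussianPrefilter(left, sigma)
    right <- gaussianPrefilter(right, sigma)
  }
  wts <- bankWeights(bank)
  dOf <- vapply(bank, function(cl) cl@learnedDisparity, integer(1))
  o <- order(dOf); wts <- wts[o]; dOf <- dOf[o]
  n <- h * (wL + wR)
  values <- matrix(NA_integer_, H, W)
  valid <- matrix(FALSE, H, W)
  rOffs <- -(h %/% 2L) + seq_len(h) - 1L
  clOffs <- -(wL %/% 2L) + seq_len(wL) - 1L
  crOffs <- -(wR %/% 2L) + seq_len(wR) - 1L
  padBy <- max(h, wL, wR)
  ridx <- boundaryIndex(seq_len(H + 2L * padBy) - padBy, H, "replicate")
  cidx <- boundaryIndex(seq_len(W + 2L * padBy) - padBy, W, "replicate")
  leftP <- left[ridx, cidx]; rightP <- right[ridx, cidx]
  for (r in seq_len(H)) {
    rws <- r + padBy + rOffs
    fitsR <- all(r + rOffs >= 1L) && all(r + rOffs <= H)
    for (c in seq_len(W)) {
      win <- cbind(leftP[rws, c + padBy + clOffs, drop = FALSE],
                   rightP[rws, c + padBy + crOffs, drop = FALSE])
      bits <- (win > stats::median(win)) * 1
      resp <- vapply(wts, function(wt) wt$b0 + sum(bits * wt$p), numeric(1))
      top <- which(resp > max(resp) - 1e-12)
      values[r, c] <- dOf[top[1L]]
      fits <- fitsR && all(c + clOffs >= 1L) && all(c + clOffs <= W) &&
        all(c + crOffs >= 1L) && all(c + crOffs <= W)
      valid[r, c] <- fits && length(top) == 1L
    }
  }
  new("DisparityMap", values = values, validMask = valid)
}

#' Mask of pixels whose window is wholly inside one disparity region
#'
#' Interior pixels are those whose spliced window (and the columns its
#' right patch draws on, up to the maximum disparity) lies inside a single
#' ground-truth region, away from image borders and occlusion fills. Map
#' accuracy is assessed on these pixels; region boundaries are genuinely
#' ambiguous for a windowed matcher.
#'
#' @param pair a [StereoPair-class].
#' @param h,wL,wR window geometry.
#' @return H x W logical matrix.
#' @export
interiorMask <- function(pair, h, wL, wR) {
  truth <- pair@groundTruth
  H <- nrow(truth); W <- ncol(truth)
  maxd <- max(truth)
  rr <- h %/% 2L
  cr <- max(wL %/% 2L, wR %/% 2L, wL - 1L - wL %/% 2L, wR - 1L - wR %/% 2L) +
    maxd
  mask <- matrix(FALSE, H, W)
  for (r in seq_len(H)) {
    if (r - rr < 1L || r + rr > H) next
    for (c in seq_len(W)) {
      if (c - cr < 1L || c + cr > W) next
      blockT <- truth[(r - rr):(r + rr), (c - cr):(c + cr)]
      blockO <- pair@occlusion[(r - rr):(r + rr), (c - cr):(c + cr)]
      mask[r, c] <- all(blockT == truth[r, c]) && !any(blockO)
    }
  }
  mask
}

#' Average disparity-map error
#'
#' Percentage of valid pixels whose estimated disparity differs from the
#' ground truth.
#'
#' @param map a [DisparityMap-class].
#' @param truth integer matrix of true disparities (or a
#'   [StereoPair-class], whose ground truth is used).
#' @param mask optional logical matrix restricting the evaluation (e.g.
#'   [interiorMask()]); combined with the map's own validity mask.
#' @return Error percentage in [0, 100].
#' @export
averageError <- function(map, truth, mask = NULL) {
  if (is(truth, "StereoPair")) truth <- truth@groundTruth
  if (!all(dim(truth) == dim(map@values))) stop("shape mismatch")
  use <- map@validMask
  if (!is.null(mask)) use <- use & mask
  n <- sum(use)
  if (n == 0L) stop("no valid pixels: average error undefined")
  100 * sum(map@values[use] != truth[use]) / n
}
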