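# Generators for disparity training patterns, probe banks and
# ground-truthed synthetic stereo pairs.

## Bit content of the spliced window a monotone (ramp) texture produces at
## disparity d: the binarized-at-median ranks of the column indices seen by
## the left patch (0..wL-1) and the right patch (d + 0..wR-1, re-centered
## for unequal subfield widths). Depends only on d for any strictly
## increasing texture, which is what makes template detection
## translation-invariant on ramp textures.
rampRowBits <- function(wL, wR, d) {
  leftVals <- seq_len(wL) - 1L
  rightVals <- d + (seq_len(wR) - 1L) + (wL %/% 2L) - (wR %/% 2L)
  vals <- c(leftVals, rightVals)
  as.numeric(vals > stats::median(vals))
}

#' Generate one binary interlaced disparity pattern
#'
#' The left subfield (width \code{wL}) and right subfield (width \code{wR})
#' are juxtaposed as in an ocular-dominance columnar pair; the right
#' subfield repeats the left content shifted horizontally by \code{d}
#' columns (zero-fill at vacated columns). Styles:
#' \describe{
#'   \item{bar}{vertical ON bar at \code{refCol} in the left subfield and at
#'     \code{refCol + d} in the right subfield.}
#'   \item{random_dot}{seeded Bernoulli(1/2) left subfield; right subfield
#'     is the left content shifted by \code{d}.}
#'   \item{ramp}{the binarized spliced window a strictly monotone luminance
#'     ramp produces at disparity \code{d} (generator-matched to
#'     [makeStereoPair()]'s default texture; seed unused).}
#' }
#'
#' @param h rows.
#' @param wL,wR subfield widths.
#' @param d disparity, \code{0 <= d < min(wL, wR)}.
#' @param style one of \code{"bar"}, \code{"random_dot"}, \code{"ramp"}.
#' @param seed seed for the random_dot style.
#' @param refCol 0-based reference column of the bar (default 0; must
#'   satisfy \code{refCol + d < wR}).
#' @return A [DisparityPattern-class].
#' @examples
#' p <- makeDisparityPattern(9, 4, 5, d = 3, style = "bar")
#' which(p@bits[1, ] == 1) # columns 1 (left bar) and 4+1+3 (right bar)
#' @export
makeDisparityPattern <- function(h, wL, wR, d,
                                 style = c("bar", "random_dot", "ramp"),
                                 seed = 1, refCol = 0L) {
  style <- match.arg(style)
  h <- as.integer(h); wL <- as.integer(wL); wR <- as.integer(wR)
  d <- as.integer(d)
  if (d < 0L || d >= min(wL, wR))
    stop("disparity out of range: need 0 <= d < min(wL, wR)")
  if (style == "bar") {
    refCol <- as.integer(refCol)
    if (refCol < 0L || refCol >= wL || refCol + d >= wR)
      stop("bar reference column out of range for this geometry")
    left <- matrix(0, h, wL); left[, refCol + 1L] <- 1
    right <- matrix(0, h, wR); right[, refCol + d + 1L] <- 1
    bits <- cbind(left, right)
  } else if (style == "random_dot") {
    set.seed(as.integer(seed))
    left <- matrix(stats::rbinom(h * wL, 1, 0.5), h, wL)
    right <- matrix(0, h, wR)
    src <- seq_len(wR) - d            # right col c takes left col c - d
    ok <- src >= 1L & src <= wL
    right[, ok] <- left[, src[ok]]
    bits <- cbind(left, right)
  } else {
    bits <- matrix(rampRowBits(wL, wR, d), h, wL + wR, byrow = TRUE)
  }
  new("DisparityPattern", bits = bits, wL = wL, wR = wR,
      disparity = d, isComplement = FALSE)
}

#' Bitwise complement of a disparity pattern
#'
#' Complementary patterns alternate the ON/OFF drive of each synapse pair;
#' the complement of a complement is the original pattern.
#'
#' @param pattern a [DisparityPattern-class].
#' @return The complemented [DisparityPattern-class].
#' @export
complementPattern <- function(pattern) {
  pattern@bits <- 1 - pattern@bits
  pattern@isComplement <- !pattern@isComplement
  pattern
}

#' Generate a full training set of disparity patterns
#'
#' Returns the \code{D} disparity patterns (0..D-1) followed by their
#' \code{D} complements, all pairwise distinct; 2D patterns in total (e.g.
#' eight for a 9 x 9 field with D = 4, forty for a 10 x 40 field with
#' D = 20). For the random_dot style each disparity uses its own derived
#' child seed so the patterns are mutually uninformative.
#'
#' @param h rows.
#' @param w total spliced width (split near-evenly).
#' @param D number of disparities; must not exceed
#'   [representableDisparities()]\code{(w)}.
#' @param style,seed passed to [makeDisparityPattern()].
#' @return List of 2D [DisparityPattern-class] objects.
#' @export
makePatternSet <- function(h, w, D, style = c("random_dot", "bar", "ramp"),
                           seed = 1) {
  style <- match.arg(style)
  D <- as.integer(D)
  if (D < 1L) stop("D must be >= 1")
  if (D > representableDisparities(w))
    stop("D = ", D, " exceeds the ", representableDisparities(w),
         " disparities representable by a ", w, "-column field ",
         "(representableDisparities)")
  sw <- splitWidth(w)
  base <- lapply(seq_len(D) - 1L, function(d)
    makeDisparityPattern(h, sw["wL"], sw["wR"], d, style = style,
                         seed = childSeed(seed, d)))
  out <- c(base, lapply(base, complementPattern))
  keys <- vapply(out, function(p) paste(p@bits, collapse = ""), character(1))
  if (anyDuplicated(keys))
    stop("generated patterns are not pairwise distinct; choose another seed")
  out
}

# ---------------------------------------------------------------------------
# Stereo pairs
# ---------------------------------------------------------------------------

#' Quadrant region layout
#'
#' Convenience layout: four equal quadrants with the given disparities
#' (top-left, top-right, bottom-left, bottom-right).
#'
#' @param H,W image size.
#' @param disparities length-4 integer vector.
#' @return A data.frame with columns row0, row1, col0, col1, d (1-based,
#'   inclusive) suitable for [makeStereoPair()].
#' @export
quadrantLayout <- function(H, W, disparities = c(0L, 1L, 2L, 3L)) {
  stopifnot(length(disparities) == 4L)
  hm <- H %/% 2L; wm <- W %/% 2L
  data.frame(
    row0 = c(1L, 1L, hm + 1L, hm + 1L),
    row1 = c(hm, hm, H, H),
    col0 = c(1L, wm + 1L, 1L, wm + 1L),
    col1 = c(wm, W, wm, W),
    d = as.integer(disparities)
  )
}

## Default texture: strictly monotone horizontal luminance ramp with
## increasing slope (quadratic). Monotonicity makes the rank structure of
## every epipolar window translation invariant, which template cells
## require; the increasing slope keeps the horizontal gradient strictly
## monotone too, so the edge-prefiltered image remains detectable.
textureImage <- function(H, W, texture = c("ramp", "bars"), seed = 1,
                         barPeriod = 4L) {
  texture <- match.arg(texture)
  if (texture == "ramp") {
    v <- ((seq_len(W) - 1L) / (W - 1L))^2
    matrix(v, H, W, byrow = TRUE)
  } else {
    v <- as.numeric((seq_len(W) - 1L) %% barPeriod == 0L)
    matrix(v, H, W, byrow = TRUE)
  }
}

#' Generate a ground-truthed synthetic stereo pair
#'
#' The left image is textured; the right image is built by shifting each
#' region of the left image horizontally by its disparity (left-referenced:
#' pixel \code{(r, c)} of the left image lands at \code{(r, c - d)} in the
#' right image). Right-image columns with no unique source are filled from
#' the nearest written column of the row and flagged occluded.
#'
#' @param H,W image size.
#' @param regionLayout data.frame of rectangles (columns row0, row1, col0,
#'   col1, d; 1-based inclusive) tiling the image, e.g. [quadrantLayout()].
#' @param texture \code{"ramp"} (default; strictly monotone luminance ramp,
#'   the texture the template cells are generator-matched to) or
#'   \code{"bars"}.
#' @param seed texture seed (reserved for stochastic textures).
#' @return A [StereoPair-class].
#' @export
makeStereoPair <- function(H, W, regionLayout = quadrantLayout(H, W),
                           texture = "ramp", seed = 1) {
  H <- as.integer(H); W <- as.integer(W)
  rl <- regionLayout
  need <- c("row0", "row1", "col0", "col1", "d")
  if (!all(need %in% names(rl))) stop("regionLayout must have columns ",
                                      paste(need, collapse = ", "))
  cover <- matrix(0L, H, W)
  truth <- matrix(NA_integer_, H, W)
  for (i in seq_len(nrow(rl))) {
    rs <- rl$row0[i]:rl$row1[i]; cs <- rl$col0[i]:rl$col1[i]
    cover[rs, cs] <- cover[rs, cs] + 1L
    truth[rs, cs] <- as.integer(rl$d[i])
  }
  if (any(cover > 1L)) stop("regionLayout rectangles overlap")
  if (any(cover < 1L)) stop("regionLayout does not tile the image")
  left <- textureImage(H, W, texture, seed)
  right <- matrix(NA_real_, H, W)
  written <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    src <- seq_len(W)               # left column
    dst <- src - truth[r, ]          # right column it lands on
    ok <- dst >= 1L & dst <= W
    for (c in src[ok]) {
      dc <- dst[c]
      right[r, dc] <- left[r, c]
      written[r, dc] <- written[r, dc] + 1L
    }
  }
  occl <- written != 1L
  # fill occluded/vacant columns from the nearest written column in the row
  for (r in seq_len(H)) {
    bad <- which(is.na(right[r, ]))
    if (length(bad)) {
      good <- which(!is.na(right[r, ]))
      nearest <- vapply(bad, function(b) good[which.min(abs(good - b))],
                        integer(1))
      right[r, bad] <- right[r, nearest]
    }
  }
  new("StereoPair", left = left, right = right, groundTruth = truth,
      occlusion = occl)
}

#' Add imaging noise to a stereo pair
#'
#' Models the two dominant nuisances of a real camera pair: an interocular
#' brightness offset/gain mismatch between the left and right sensors, plus
#' independent pixel noise. The offset is what breaks raw intensity
#' matching and what gradient (edge) prefiltering cancels.
#'
#' @param pair a [StereoPair-class].
#' @param offset brightness offset added to the right image (default 0.05
#'   of the unit intensity range).
#' @param gain multiplicative gain applied to the right image (default 1).
#' @param sigma standard deviation of iid Gaussian pixel noise added to
#'   both images (default 0.003).
#' @param seed seed for the pixel noise.
#' @return The noisy [StereoPair-class] (ground truth unchanged).
#' @export
addImagingNoise <- function(pair, offset = 0.05, gain = 1, sigma = 0.003,
                            seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(as.integer(seed))
  d <- dim(pair@left)
  pair@left <- pair@left + matrix(stats::rnorm(prod(d), 0, sigma), d[1], d[2])
  pair@right <- gain * pair@right + offset +
    matrix(stats::rnorm(prod(d), 0, sigma), d[1], d[2])
  pair
}
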