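# The receptive field of a disparity cell: an h x w grid of ts-WTA units
# covering a spliced binocular window (left subfield | right subfield).

#' Near-even left/right split of a spliced field width
#'
#' @param w total spliced width (columns).
#' @return Integer vector \code{c(wL, wR)} with \code{wL = floor(w/2)},
#'   \code{wR = ceiling(w/2)} (matching the 9 = 4 + 5 split).
#' @export
splitWidth <- function(w) {
  w <- as.integer(w)
  if (w < 2L) stop("total width must be >= 2")
  c(wL = w %/% 2L, wR = w - w %/% 2L)
}

#' Number of disparities a spliced field can represent
#'
#' A spliced binocular field of total width \code{totalWidth} under the
#' near-even split can encode \code{floor(totalWidth/2) = min(wL, wR)}
#' distinct integer disparities, starting at 0. A 9-column field
#' accommodates 4 disparities (0..3); a 40-column field accommodates 20.
#'
#' @param totalWidth total spliced width in columns (>= 2).
#' @return Integer count of representable disparities.
#' @examples
#' representableDisparities(9)  # 4
#' representableDisparities(40) # 20
#' @export
representableDisparities <- function(totalWidth) {
  unname(splitWidth(totalWidth)["wL"])
}

#' Initialize a receptive field with random synaptic biases
#'
#' Every floating-gate voltage is drawn uniformly from \code{initRange}
#' (default 4.8-5.5 V), reproducibly for a given seed.
#'
#' @param h,w grid height and total spliced width (w is split near-evenly
#'   into left and right subfields).
#' @param seed integer seed.
#' @param initRange length-2 numeric (low, high), low < high.
#' @return A [ReceptiveField-class].
#' @export
initReceptiveField <- function(h, w, seed, initRange = c(4.8, 5.5)) {
  h <- as.integer(h); w <- as.integer(w)
  if (h < 1L || w < 2L) stop("field must have h >= 1 and w >= 2")
  if (length(initRange) != 2L || initRange[1] >= initRange[2])
    stop("initRange must be (low, high) with low < high")
  sw <- splitWidth(w)
  set.seed(as.integer(seed))
  v1 <- matrix(stats::runif(h * w, initRange[1], initRange[2]), h, w)
  v2 <- matrix(stats::runif(h * w, initRange[1], initRange[2]), h, w)
  new("ReceptiveField", vfg1 = v1, vfg2 = v2,
      wL = unname(sw["wL"]), wR = unname(sw["wR"]),
      initRange = as.numeric(initRange))
}

#' Bias a receptive field toward a stimulus template
#'
#' Lowers the floating-gate voltage of the template-aligned synapse at every
#' grid position by \code{delta} (clipped to the admissible range),
#' emulating a cell with a stronger innate ("genetic") bias for that
#' stimulus.
#'
#' @param rf a [ReceptiveField-class].
#' @param pattern a [DisparityPattern-class] with matching dimensions.
#' @param delta bias strength in volts (> 0).
#' @param params a [TsWtaParams-class] providing the clipping range.
#' @return The biased [ReceptiveField-class].
#' @export
biasReceptiveField <- function(rf, pattern, delta, params = tsWtaParams()) {
  if (!all(dim(pattern@bits) == dim(rf@vfg1)))
    stop("pattern dimensions must match the receptive field")
  if (delta <= 0) stop("delta must be > 0")
  b <- pattern@bits
  rf@vfg1 <- clip(rf@vfg1 - delta * b, params@vfgMin, params@vfgMax)
  rf@vfg2 <- clip(rf@vfg2 - delta * (1 - b), params@vfgMin, params@vfgMax)
  rf
}

## Fraction of the unit resource drawn by synapse 1 at every grid position.
fieldShares <- function(rf, params) {
  e1 <- exp(-params@kappa * (rf@vfg1 - params@vfgMin))
  e2 <- exp(-params@kappa * (rf@vfg2 - params@vfgMin))
  e1 / (e1 + e2)
}

#' Write / read a receptive field as CSV
#'
#' The CSV holds h*w rows with columns \code{row}, \code{col}, \code{vfg1},
#' \code{vfg2} plus a header comment-free layout; subfield widths and init
#' range are stored in the first row's extra columns \code{wL}, \code{wR},
#' \code{initLo}, \code{initHi}.
#'
#' @param rf a [ReceptiveField-class].
#' @param path file path.
#' @return `writeFieldCSV` returns `path` invisibly; `readFieldCSV` returns
#'   the reconstructed [ReceptiveField-class].
#' @export
writeFieldCSV <- function(rf, path) {
  h <- nrow(rf@vfg1); w <- ncol(rf@vfg1)
  df <- data.frame(
    row = rep(seq_len(h), w),
    col = rep(seq_len(w), each = h),
    vfg1 = as.vector(rf@vfg1),
    vfg2 = as.vector(rf@vfg2),
    wL = c(rf@wL, rep(NA, h * w - 1L)),
    wR = c(rf@wR, rep(NA, h * w - 1L)),
    initLo = c(rf@initRange[1], rep(NA, h * w - 1L)),
    initHi = c(rf@initRange[2], rep(NA, h * w - 1L))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFieldCSV
#' @export
readFieldCSV <- function(path) {
  df <- utils::read.csv(path)
  h <- max(df$row); w <- max(df$col)
  v1 <- matrix(NA_real_, h, w); v2 <- matrix(NA_real_, h, w)
  v1[cbind(df$row, df$col)] <- df$vfg1
  v2[cbind(df$row, df$col)] <- df$vfg2
  new("ReceptiveField", vfg1 = v1, vfg2 = v2,
      wL = as.integer(df$wL[1]), wR = as.integer(df$wR[1]),
      initRange = c(df$initLo[1], df$initHi[1]))
}

#' Render a receptive field to a grayscale matrix or PGM file
#'
#' Gray level encodes the share of the resource drawn by the ON synapse
#' (1 = fully ON-dominated, 0 = fully OFF-dominated), for visual comparison
#' of undeveloped versus developed fields.
#'
#' @param rf a [ReceptiveField-class].
#' @param params a [TsWtaParams-class].
#' @param path optional PGM output path; if given, the image is written.
#' @return The h x w share matrix in [0, 1], invisibly if written to file.
#' @export
renderField <- function(rf, params = tsWtaParams(), path = NULL) {
  s <- fieldShares(rf, params)
  if (!is.null(path)) {
    writePGM(s, path)
    return(invisible(s))
  }
  s
}
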