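# Plain-text image IO: PGM (P2) for fields, maps and stereo frames, plus
# PNG via the png package. Images are numeric matrices in [0, 1] in memory.

#' Write / read a grayscale matrix as plain PGM (P2)
#'
#' @param img numeric matrix; values are rescaled from \code{range} to
#'   0..\code{maxval}.
#' @param path file path.
#' @param maxval maximum gray value (default 255).
#' @param range intensity range mapped onto 0..maxval (default the unit
#'   interval; pass \code{range(img)} to stretch).
#' @return `writePGM` returns `path` invisibly; `readPGM` returns a numeric
#'   matrix in [0, 1].
#' @export
writePGM <- function(img, path, maxval = 255L, range = c(0, 1)) {
  v <- round((clip(img, range[1], range[2]) - range[1]) /
               (range[2] - range[1]) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePGM
#' @export
readPGM <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tokens <- scan(text = txt[-1L], what = numeric(), quiet = TRUE)
  if (trimws(txt[1L]) != "P2") stop("only plain (P2) PGM is supported")
  W <- tokens[1L]; H <- tokens[2L]; maxval <- tokens[3L]
  vals <- tokens[-(1:3)]
  if (length(vals) != H * W) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = H, ncol = W, byrow = TRUE) / maxval
}

#' Write / read a grayscale matrix as PNG
#'
#' @param img numeric matrix in [0, 1].
#' @param path file path.
#' @return `writeImagePNG` returns `path` invisibly; `readImagePNG` a
#'   numeric matrix in [0, 1] (first channel of color images).
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(clip(img, 0, 1), path)
  invisible(path)
}

#' @rdname writeImagePNG
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x
}

#' Read a grayscale image (PGM or PNG) by extension
#' @param path file path ending in .pgm or .png.
#' @return Numeric matrix in [0, 1].
#' @export
readImage <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) readPGM(path)
  else if (grepl("\\.png$", path, ignore.case = TRUE)) readImagePNG(path)
  else stop("unsupported image format: ", path)
}
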