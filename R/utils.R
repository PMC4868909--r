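## Small numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

pos <- function(x) pmax(x, 0)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed
#'
#' Fans a single global seed out into per-component child seeds so that any
#' stage of a run can be re-seeded independently and reproducibly.
#'
#' @param seed global integer seed.
#' @param stream integer stream index.
#' @return An integer seed in \code{[1, 2^31 - 20]}.
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 9973) %% 2147483629 + 1)
}

## Index vector implementing a boundary policy for out-of-range positions.
boundaryIndex <- function(idx, n, boundary = c("reflect", "wrap", "replicate")) {
  boundary <- match.arg(boundary)
  if (boundary == "wrap") return(((idx - 1L) %% n) + 1L)
  if (boundary == "replicate") return(clip(idx, 1L, n))
  # reflect: 1 2 3 ... n n ... (mirror without repeating the edge sample twice
  # beyond a full period)
  period <- 2L * n
  j <- ((idx - 1L) %% period) + 1L
  j <- ifelse(j > n, period - j + 1L, j)
  j
}

## Separable 1-D convolution of a matrix along rows or columns with an odd,
## centered kernel and an explicit boundary policy. Kernels here are tiny
## (Gaussian radius ~3*sigma, Sobel radius 1), so direct summation is used.
convolve1d <- function(x, kernel, along = c("cols", "rows"),
                       boundary = "reflect") {
  along <- match.arg(along)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(x * kernel)
  out <- matrix(0, nrow(x), ncol(x))
  n <- if (along == "cols") ncol(x) else nrow(x)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- boundaryIndex(seq_len(n) + off, n, boundary)
    out <- out + kernel[k] * (if (along == "cols") x[, idx, drop = FALSE]
                              else x[idx, , drop = FALSE])
  }
  out
}

gaussianKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## 4-neighbour connected components of an integer label matrix; returns a
## matrix of component ids (1..k). Iterative flood fill, no recursion.
connectedComponents <- function(labels) {
  R <- nrow(labels); C <- ncol(labels)
  comp <- matrix(0L, R, C)
  k <- 0L
  queue <- integer(R * C)
  for (start in seq_len(R * C)) {
    if (comp[start] != 0L) next
    k <- k + 1L
    lab <- labels[start]
    qh <- 1L; qt <- 1L
    queue[1L] <- start
    comp[start] <- k
    while (qh <= qt) {
      p <- queue[qh]; qh <- qh + 1L
      r <- ((p - 1L) %% R) + 1L
      c <- ((p - 1L) %/% R) + 1L
      for (nb in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        rr <- nb[1L]; cc <- nb[2L]
        if (rr < 1L || rr > R || cc < 1L || cc > C) next
        q <- (cc - 1L) * R + rr
        if (comp[q] == 0L && labels[q] == lab) {
          comp[q] <- k
          qt <- qt + 1L
          queue[qt] <- q
        }
      }
    }
  }
  comp
}
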