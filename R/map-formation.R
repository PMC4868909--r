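# Phenomenological reaction-diffusion model of disparity-map formation on a
# cortical lattice: a multistable reaction term whose stable roots are the
# integer disparities 0..D-1, plus discrete Laplacian diffusion.

#' Multistable reaction drift
#'
#' The reaction is the negative gradient of a multi-well potential with
#' stable fixed points at every integer disparity 0..D-1 and unstable fixed
#' points at the half-integers between consecutive wells: with
#' \code{u = x - round(x)} (round clamped to 0..D-1),
#' \code{f = -u (1 - 4 u^2)} inside a well and \code{-u (4 u^2 - 1)} beyond
#' the outermost roots (a pull back toward the boundary root). The drift is
#' continuous, odd-symmetric about each root, and its sign always drives
#' \code{x} toward the nearest root.
#'
#' @param x numeric vector/matrix of disparity states.
#' @param D number of disparities (>= 2).
#' @return Drift of the same shape as \code{x}; zero exactly at the integer
#'   roots and half-integer separatrices.
#' @examples
#' reaction(2, 4)    # 0: stable root
#' reaction(1.5, 4)  # 0: separatrix
#' reaction(1.9, 4) > 0 # drifts toward 2
#' @export
reaction <- function(x, D) {
  D <- as.integer(D)
  if (D < 2L) stop("D must be >= 2")
  root <- clip(round(x), 0, D - 1L)
  u <- x - root
  inside <- abs(u) <= 0.5
  drift <- ifelse(inside, -u * (1 - 4 * u^2), -u * (4 * u^2 - 1))
  if (is.matrix(x)) matrix(drift, nrow(x), ncol(x)) else drift
}

#' Construct a reaction-diffusion lattice
#'
#' Sites are initialized uniformly at random in \code{[0, D-1]} (the
#' "random initial bias" of each developing cell).
#'
#' @param R,C lattice size.
#' @param D number of disparities.
#' @param alpha reaction constant; the explicit update is stable for
#'   \code{alpha < 1} with the unit-slope reaction used here.
#' @param dU diffusion constant; stable for \code{dU <= 0.25}.
#' @param seed seed for the initial state.
#' @param boundary \code{"reflect"} (default) or \code{"wrap"}.
#' @return An [RDLattice-class].
#' @export
rdLattice <- function(R, C, D = 4L, alpha = 0.5, dU = 0.04, seed = 1,
                      boundary = c("reflect", "wrap")) {
  boundary <- match.arg(boundary)
  set.seed(as.integer(seed))
  X <- matrix(stats::runif(R * C, 0, D - 1), R, C)
  new("RDLattice", X = X, alpha = alpha, dU = dU, D = as.integer(D),
      boundary = boundary)
}

## Discrete 4-neighbour Laplacian with reflect (zero-flux) or wrap boundary.
laplacian4 <- function(X, boundary) {
  R <- nrow(X); C <- ncol(X)
  up <- boundaryIndex(seq_len(R) - 1L, R,
                      if (boundary == "wrap") "wrap" else "replicate")
  dn <- boundaryIndex(seq_len(R) + 1L, R,
                      if (boundary == "wrap") "wrap" else "replicate")
  lf <- boundaryIndex(seq_len(C) - 1L, C,
                      if (boundary == "wrap") "wrap" else "replicate")
  rt <- boundaryIndex(seq_len(C) + 1L, C,
                      if (boundary == "wrap") "wrap" else "replicate")
  X[up, ] + X[dn, ] + X[, lf] + X[, rt] - 4 * X
}

checkStability <- function(lattice) {
  if (lattice@alpha >= 1)
    stop("explicit update unstable: alpha = ", lattice@alpha,
         " must be < 1 for the unit-slope reaction")
  if (lattice@dU > 0.25)
    stop("explicit update unstable: dU = ", lattice@dU, " must be <= 0.25")
}

checkDivergence <- function(lattice) {
  if (any(lattice@X < -1 | lattice@X > lattice@D))
    stop("lattice state escaped [-1, D]: reduce alpha (= ", lattice@alpha,
         ") or dU (= ", lattice@dU, ")")
}

#' Evolve the lattice without diffusion
#'
#' Explicit updates \code{X <- X + alpha * reaction(X)}; every site
#' converges independently to the nearest stable root of its initial value
#' (sites starting exactly on a separatrix stay there).
#'
#' @param lattice an [RDLattice-class].
#' @param steps number of update steps.
#' @return The evolved [RDLattice-class].
#' @export
evolveNoDiffusion <- function(lattice, steps = 200) {
  checkStability(lattice)
  for (i in seq_len(steps)) {
    lattice@X <- lattice@X + lattice@alpha * reaction(lattice@X, lattice@D)
    checkDivergence(lattice)
  }
  lattice
}

#' Evolve the lattice under reaction plus diffusion
#'
#' Explicit updates
#' \code{X <- X + alpha * reaction(X) + dU * laplacian(X)} (4-neighbour
#' Laplacian). Neighbourhood influence makes contiguous clusters of equal
#' disparity emerge, with gradual variation across cluster boundaries;
#' \code{dU = 0} reduces exactly to [evolveNoDiffusion()].
#'
#' @param lattice an [RDLattice-class].
#' @param steps number of update steps.
#' @return The evolved [RDLattice-class].
#' @export
evolveRD <- function(lattice, steps = 200) {
  checkStability(lattice)
  for (i in seq_len(steps)) {
    lattice@X <- lattice@X + lattice@alpha * reaction(lattice@X, lattice@D) +
      lattice@dU * laplacian4(lattice@X, lattice@boundary)
    checkDivergence(lattice)
  }
  lattice
}

#' Map-quality statistics: continuity, diversity, clusters
#'
#' Continuity is the mean absolute state difference over 4-neighbour pairs
#' (lower = smoother); diversity is the fraction of the D disparities
#' represented after rounding each site to its nearest disparity; clusters
#' are 4-connected components of equal rounded disparity.
#'
#' @param lattice an [RDLattice-class] (typically evolved to steady state).
#' @return A [MapStats-class].
#' @export
mapStats <- function(lattice) {
  X <- lattice@X
  dh <- abs(X[, -1, drop = FALSE] - X[, -ncol(X), drop = FALSE])
  dv <- abs(X[-1, , drop = FALSE] - X[-nrow(X), , drop = FALSE])
  continuity <- mean(c(dh, dv))
  rounded <- clip(round(X), 0, lattice@D - 1L)
  diversity <- length(unique(as.vector(rounded))) / lattice@D
  labels <- connectedComponents(matrix(as.integer(rounded), nrow(X)))
  new("MapStats", continuity = continuity, diversity = diversity,
      clusterCount = max(labels), clusterLabels = labels)
}

#' Render a lattice to a D-level gray PGM
#'
#' @param lattice an [RDLattice-class].
#' @param path output PGM path.
#' @return The rounded disparity matrix, invisibly.
#' @export
latticeToPGM <- function(lattice, path) {
  rounded <- clip(round(lattice@X), 0, lattice@D - 1L)
  writePGM(rounded / (lattice@D - 1L), path)
  invisible(rounded)
}

#' Serialize a lattice state to / from CSV
#' @param lattice an [RDLattice-class].
#' @param path file path.
#' @return `writeLatticeCSV` returns `path` invisibly; `readLatticeCSV` the
#'   state matrix.
#' @export
writeLatticeCSV <- function(lattice, path) {
  utils::write.table(lattice@X, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeLatticeCSV
#' @export
readLatticeCSV <- function(path) {
  as.matrix(utils::read.table(path, sep = ","))
}
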