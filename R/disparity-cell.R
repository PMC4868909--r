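# A disparity-selective cell: an h x w receptive field of ts-WTA units with
# a common output node, trained on interlaced binocular patterns until it
# tunes to one disparity. Cells can be coupled diffusively so that clusters
# of equal preference form.

#' Construct a disparity-selective cell
#'
#' @param rf a [ReceptiveField-class] (see [initReceptiveField()]).
#' @param params shared [TsWtaParams-class].
#' @param rD,rF diffusive and feedback resistances (ohm, default 1000 as in
#'   the intra-cell RC network).
#' @param cD diffusion capacitance (farad, default 10e-12).
#' @return A [DisparityCell-class].
#' @export
disparityCell <- function(rf, params = tsWtaParams(),
                          rD = 1000, rF = 1000, cD = 10e-12) {
  new("DisparityCell", rf = rf, params = params, rD = rD, rF = rF, cD = cD,
      outputLevel = 0, diffusionLevel = 0,
      learnedDisparity = NA_integer_,
      trace = matrix(numeric(0), 0, 0))
}

## Response of a receptive field to a 0/1 bit matrix: mean over grid
## positions of the resource share drawn by the pattern-selected synapse.
responseToBits <- function(rf, bits, params) {
  s1 <- fieldShares(rf, params)
  params@iB * mean(bits * s1 + (1 - bits) * (1 - s1))
}

#' Response of a disparity cell to a stimulus
#'
#' Every grid position's ts-WTA unit is driven by the pattern bit (ON
#' synapse) and its complement (OFF synapse); the per-unit activations are
#' resource-capped and the cell output is their sum normalized by the grid
#' size, so the response lies in \code{[0, iB]} for any field size.
#'
#' @param cell a [DisparityCell-class].
#' @param pattern a [DisparityPattern-class] (or plain 0/1 matrix) with the
#'   same dimensions as the receptive field.
#' @return Dimensionless response in \code{[0, iB]}.
#' @export
cellResponse <- function(cell, pattern) {
  bits <- if (is(pattern, "DisparityPattern")) pattern@bits else pattern
  if (!all(dim(bits) == dim(cell@rf@vfg1)))
    stop("pattern dimensions must equal the receptive-field dimensions")
  responseToBits(cell@rf, bits, cell@params)
}

## One training presentation: update every unit given the scalar feedback
## level routed to the field. Vectorized form of applyPulse over the grid.
presentPattern <- function(rf, bits, feedback, params) {
  dAct <- -params@etaInj * pos(feedback - params@thetaFb) +
    params@etaTun * pos(params@thetaFb - feedback)
  rf@vfg1 <- clip(rf@vfg1 + bits * dAct + (1 - bits) * params@etaLeak,
                  params@vfgMin, params@vfgMax)
  rf@vfg2 <- clip(rf@vfg2 + (1 - bits) * dAct + bits * params@etaLeak,
                  params@vfgMin, params@vfgMax)
  rf
}

## Check that a pattern set contains each disparity's base pattern and its
## complement; returns the list of base patterns sorted by disparity.
checkPatternSet <- function(patternSet) {
  isC <- vapply(patternSet, function(p) p@isComplement, logical(1))
  d <- vapply(patternSet, function(p) p@disparity, integer(1))
  base <- sort(d[!isC]); comp <- sort(d[isC])
  if (length(base) == 0L || !identical(base, comp))
    stop("pattern set must contain each disparity pattern together with ",
         "its complement (ts-WTA needs alternating ON/OFF drive)")
  patternSet[order(isC, d)][seq_along(base)]
}

## Index of each pattern's complement partner within the set.
complementIndex <- function(patternSet) {
  isC <- vapply(patternSet, function(p) p@isComplement, logical(1))
  d <- vapply(patternSet, function(p) p@disparity, integer(1))
  vapply(seq_along(patternSet), function(i) {
    j <- which(d == d[i] & isC != isC[i])
    if (length(j) != 1L)
      stop("pattern set must pair each pattern with exactly one complement")
    j
  }, integer(1))
}

## Winner-selective feedback levels for one epoch: the stimulus currently
## evoking the maximum response receives the full injection drive (1), its
## complement the full tunneling drive (0), and every other stimulus the
## neutral threshold level. This is the behavioral abstraction of the
## cell-level winner-take-all that the intra-cell diffusive grid and the
## feedback devices perform: only the best-matching stimulus is reinforced
## on the floating gates, and its anti-pattern is actively unlearned.
feedbackLevels <- function(responses, partner, thetaFb) {
  lv <- rep(thetaFb, length(responses))
  iw <- which.max(responses)
  lv[iw] <- 1
  lv[partner[iw]] <- 0
  lv
}

#' Train a disparity cell on a pattern set
#'
#' Patterns (each disparity plus its complement) are presented in
#' random-inside-epoch order for \code{epochs} epochs. Each epoch the cell's
#' responses to all stimuli are computed and fed back to every ts-WTA unit
#' through the winner-selective feedback path: the stimulus the cell
#' responds most to receives the full injection drive, its complement the
#' full tunneling drive, and every other stimulus the neutral threshold
#' level (see the package vignette for why the feedback path must operate
#' on the cell's response relative to its own response range). The stimulus
#' evoking the maximum response is thereby the one the cell eventually
#' learns. A complement carries the same disparity as its base pattern
#' (complementing and shifting commute), so after training
#' \code{learnedDisparity} is the argmax of the polarity-aware tuning curve
#' (NA if the maximum is not unique) and \code{trace} holds the per-epoch
#' polarity-maximum response to each disparity.
#'
#' @param cell a [DisparityCell-class].
#' @param patternSet list of [DisparityPattern-class] objects: D disparity
#'   patterns and their D complements (see [makePatternSet()]).
#' @param epochs number of epochs (default 80).
#' @param seed seed controlling the presentation order.
#' @return The trained [DisparityCell-class].
#' @examples
#' ps <- makePatternSet(9, 9, 4, seed = 7)
#' cell <- disparityCell(initReceptiveField(9, 9, seed = 1))
#' cell <- trainCell(cell, ps, epochs = 20, seed = 1)
#' @export
trainCell <- function(cell, patternSet, epochs = 80, seed = 1) {
  basePatterns <- checkPatternSet(patternSet)
  partner <- complementIndex(patternSet)
  D <- length(basePatterns)
  params <- cell@params
  rf <- cell@rf
  for (p in patternSet)
    if (!all(dim(p@bits) == dim(rf@vfg1)))
      stop("pattern dimensions must equal the receptive-field dimensions")
  bitsList <- lapply(patternSet, function(p) p@bits)
  set.seed(as.integer(seed))
  trace <- matrix(NA_real_, epochs, D,
                  dimnames = list(NULL, paste0("d", seq_len(D) - 1L)))
  dOf <- vapply(patternSet, function(p) p@disparity, integer(1))
  lastResponse <- 0
  for (ep in seq_len(epochs)) {
    R0 <- vapply(bitsList, function(b) responseToBits(rf, b, params),
                 numeric(1))
    lv <- feedbackLevels(R0, partner, params@thetaFb)
    for (i in sample.int(length(bitsList))) {
      rf <- presentPattern(rf, bitsList[[i]], lv[i], params)
      lastResponse <- R0[i]
    }
    R1 <- vapply(bitsList, function(b) responseToBits(rf, b, params),
                 numeric(1))
    trace[ep, ] <- vapply(seq_len(D) - 1L,
                          function(d) max(R1[dOf == d]), numeric(1))
  }
  cell@rf <- rf
  cell@outputLevel <- lastResponse
  cell@diffusionLevel <- lastResponse
  cell@trace <- trace
  cell@learnedDisparity <- uniqueArgmax(tuningCurve(cell, patternSet))
  cell
}

## Argmax of a tuning curve, NA unless unique (tolerance for float noise).
uniqueArgmax <- function(curve, tol = 1e-9) {
  r <- curve@responses
  top <- which(r > max(r) - tol)
  if (length(top) == 1L) curve@disparities[top] else NA_integer_
}

#' Tuning curve of a cell over a probe bank
#'
#' Responses of the cell to one probe per disparity. When the bank contains
#' both polarities of a disparity (pattern and complement -- which encode
#' the same disparity), the response reported for that disparity is the
#' maximum over the two polarities.
#'
#' @param cell a [DisparityCell-class].
#' @param patternBank list of probe [DisparityPattern-class] objects.
#' @return A [TuningCurve-class] of responses indexed by probe disparity.
#' @export
tuningCurve <- function(cell, patternBank) {
  if (length(patternBank) == 0L) stop("probe bank is empty")
  d <- vapply(patternBank, function(p) p@disparity, integer(1))
  r <- vapply(patternBank, function(p) cellResponse(cell, p), numeric(1))
  ud <- sort(unique(d))
  rr <- vapply(ud, function(dd) max(r[d == dd]), numeric(1))
  new("TuningCurve", disparities = ud, responses = rr)
}

#' Half-width at half-height of a tuning curve
#'
#' Linear-interpolated distance (in disparity units) from the unique peak to
#' the point where the response falls to \code{(max + min) / 2}, averaged
#' over the two sides when both are defined, one side otherwise. A curve
#' that never drops below half-height has an undefined width beyond its
#' support; \code{NA} is returned with a warning. A flat curve (no unique
#' maximum) is an error.
#'
#' @param curve a [TuningCurve-class].
#' @return Half-width at half-height, or NA when undefined beyond support.
#' @examples
#' tc <- new("TuningCurve", disparities = 0:2, responses = c(0, 1, 0))
#' hwhh(tc) # 0.5
#' @export
hwhh <- function(curve) {
  d <- as.numeric(curve@disparities); r <- curve@responses
  if (length(r) < 2L || diff(range(r)) < 1e-12)
    stop("hwhh undefined for a flat tuning curve (no unique maximum)")
  peak <- which.max(r)
  if (sum(r > max(r) - 1e-12) > 1L)
    stop("hwhh requires a unique tuning maximum")
  half <- (max(r) + min(r)) / 2
  sideWidth <- function(idx) {
    # walk from the peak outward along idx until the response crosses half
    prev <- peak
    for (i in idx) {
      if (r[i] <= half) {
        frac <- (r[prev] - half) / (r[prev] - r[i])
        return(abs(d[prev] - d[peak]) + frac * abs(d[i] - d[prev]))
      }
      prev <- i
    }
    NA_real_
  }
  left <- if (peak > 1L) sideWidth(seq(peak - 1L, 1L)) else NA_real_
  right <- if (peak < length(r)) sideWidth(seq(peak + 1L, length(r))) else NA_real_
  w <- c(left, right)
  if (all(is.na(w))) {
    warning("tuning curve never falls to half-height: hwhh undefined beyond support")
    return(NA_real_)
  }
  mean(w, na.rm = TRUE)
}

# ---------------------------------------------------------------------------
# Diffusive coupling between cells
# ---------------------------------------------------------------------------

#' Couple disparity cells through their diffusion nodes
#'
#' Builds the quasi-static resistive mixing matrix of an ensemble: each
#' cell's output node drives its diffusion node through the feedback
#' resistance \code{rF}, and diffusion nodes of neighbouring cells are tied
#' by a coupling resistor \code{rCouple}. Solving Kirchhoff's current law at
#' steady state gives diffusion levels \code{Dn = M O} for outputs
#' \code{O}. The buffer contract means output nodes are never back-driven.
#'
#' @param cells list of [DisparityCell-class] objects.
#' @param topology n x n 0/1 adjacency matrix (undirected, no self-loops).
#' @param rCouple inter-cell diffusive resistance (ohm, default 100 as in
#'   the two-cell clustering experiment); \code{Inf} decouples the cells.
#' @return List with the mixing matrix \code{M} and the inputs, of class
#'   \code{"CoupledEnsemble"} (a plain list).
#' @export
coupleCells <- function(cells, topology, rCouple = 100) {
  n <- length(cells)
  topology <- as.matrix(topology)
  if (!all(dim(topology) == c(n, n)))
    stop("topology must be an n x n adjacency matrix")
  if (any(topology != t(topology)))
    stop("topology must be undirected (symmetric)")
  if (any(diag(topology) != 0))
    stop("self-loops are not allowed in the coupling topology")
  if (rCouple <= 0) stop("rCouple must be > 0")
  gF <- vapply(cells, function(cl) 1 / cl@rF, numeric(1))
  gC <- if (is.finite(rCouple)) topology / rCouple else topology * 0
  # KCL at diffusion node i: gF_i (D_i - O_i) + sum_j gC_ij (D_i - D_j) = 0
  A <- diag(gF + rowSums(gC)) - gC
  M <- solve(A, diag(gF, n))
  structure(list(cells = cells, topology = topology, rCouple = rCouple,
                 mixing = M),
            class = "CoupledEnsemble")
}

#' Train a coupled ensemble of disparity cells
#'
#' Per presentation, every cell's output is its response to the pattern;
#' the diffusion-node levels are the quasi-static resistive mix of those
#' outputs, and each cell's ts-WTA units receive its *diffusion* level as
#' feedback. The more strongly biased cell thereby influences the
#' development of its neighbours and clusters of equal disparity preference
#' form.
#'
#' @param ensemble result of [coupleCells()].
#' @param patternSet as in [trainCell()].
#' @param epochs,seed as in [trainCell()].
#' @return The ensemble with trained cells (list element \code{cells}).
#' @export
trainEnsemble <- function(ensemble, patternSet, epochs = 80, seed = 1) {
  checkPatternSet(patternSet)
  partner <- complementIndex(patternSet)
  cells <- ensemble$cells
  n <- length(cells)
  M <- ensemble$mixing
  bitsList <- lapply(patternSet, function(p) p@bits)
  set.seed(as.integer(seed))
  for (ep in seq_len(epochs)) {
    # outputs of every cell for every stimulus, mixed through the resistor
    # network into per-cell diffusion levels; each cell's winner-selective
    # feedback then works on its *diffusion* levels, so a strongly biased
    # neighbour can steer which stimulus gets reinforced
    O <- vapply(bitsList, function(b)
      vapply(cells, function(cl) responseToBits(cl@rf, b, cl@params),
             numeric(1)), numeric(n))
    O <- matrix(O, nrow = n)
    Dn <- M %*% O
    lv <- t(apply(Dn, 1, feedbackLevels, partner = partner,
                  thetaFb = cells[[1]]@params@thetaFb))
    for (i in sample.int(length(bitsList))) {
      for (k in seq_len(n)) {
        cells[[k]]@rf <- presentPattern(cells[[k]]@rf, bitsList[[i]],
                                        lv[k, i], cells[[k]]@params)
        cells[[k]]@outputLevel <- O[k, i]
        cells[[k]]@diffusionLevel <- Dn[k, i]
      }
    }
  }
  for (k in seq_len(n)) {
    tc <- tuningCurve(cells[[k]], patternSet)
    cells[[k]]@learnedDisparity <- uniqueArgmax(tc)
  }
  ensemble$cells <- cells
  ensemble
}
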