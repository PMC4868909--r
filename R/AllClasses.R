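#' @import methods
NULL

# ---------------------------------------------------------------------------
# ts-WTA core classes
# ---------------------------------------------------------------------------

#' Parameters of a time-staggered winner-take-all synapse pair
#'
#' Behavioral parameters governing one competing pair of floating-gate
#' synapses. Voltages are in volts; the activation scale is dimensionless.
#'
#' @slot vOn gate level of an active (ON) input pulse, volts (default -1).
#' @slot vOff gate level of an inactive (OFF) input, volts (default +6).
#' @slot pulseWidth pulse width in seconds (default 0.02).
#' @slot vfgMin,vfgMax admissible floating-gate voltage range, volts. Lower
#'   floating-gate voltage means a stronger synapse.
#' @slot iB total activation budget of the cell (dimensionless stand-in for
#'   the bias current shared by the two synapses).
#' @slot etaInj strengthening (injection) rate, volts per unit of
#'   supra-threshold feedback per pulse.
#' @slot etaTun weakening (tunneling) rate, volts per unit of sub-threshold
#'   feedback per pulse.
#' @slot etaLeak passive weakening of the unstimulated synapse, volts per
#'   pulse.
#' @slot thetaFb feedback threshold separating net strengthening from net
#'   weakening, in activation units (must lie inside (0, iB)).
#' @slot kappa efficacy steepness (per volt); efficacy decays as
#'   \code{exp(-kappa * (vfg - vfgMin))}.
#' @slot eliminationFraction a competition is decided once the loser's
#'   efficacy falls below this fraction of the winner's.
#' @seealso [tsWtaParams()], [efficacy()], [applyPulse()]
#' @export
setClass("TsWtaParams",
  representation(
    vOn = "numeric", vOff = "numeric", pulseWidth = "numeric",
    vfgMin = "numeric", vfgMax = "numeric", iB = "numeric",
    etaInj = "numeric", etaTun = "numeric", etaLeak = "numeric",
    thetaFb = "numeric", kappa = "numeric", eliminationFraction = "numeric"
  )
)

setValidity("TsWtaParams", function(object) {
  msg <- character()
  if (object@pulseWidth <= 0) msg <- c(msg, "pulseWidth must be > 0")
  if (object@vfgMin >= object@vfgMax) msg <- c(msg, "vfgMin must be < vfgMax")
  if (any(c(object@etaInj, object@etaTun, object@etaLeak) < 0))
    msg <- c(msg, "rates etaInj, etaTun, etaLeak must be >= 0")
  if (object@iB <= 0) msg <- c(msg, "iB must be > 0")
  if (object@kappa <= 0) msg <- c(msg, "kappa must be > 0")
  if (object@thetaFb <= 0 || object@thetaFb >= object@iB)
    msg <- c(msg, "thetaFb must lie inside the attainable activation range (0, iB)")
  if (object@kappa * (object@vfgMax - object@vfgMin) < log(100))
    msg <- c(msg, "kappa * (vfgMax - vfgMin) must be >= log(100) so that the weakest synapse has <= 1% of the strongest efficacy")
  if (object@eliminationFraction <= 0 || object@eliminationFraction >= 1)
    msg <- c(msg, "eliminationFraction must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct ts-WTA parameters
#'
#' Returns the default behavioral parameter set of the simulator. The rate
#' constants were fixed once, by a design-time calibration against the two
#' competition laws (equal stimulation: the stronger-biased synapse wins;
#' a >= 3x stimulation ratio overrides a <= 0.1 V bias gap); see the package
#' vignette for the calibration argument.
#'
#' @param vOn,vOff,pulseWidth input pulse levels (V) and width (s).
#' @param vfgMin,vfgMax admissible floating-gate range (V).
#' @param iB activation budget (resource level).
#' @param etaInj,etaTun,etaLeak learning rates (V per pulse, scaled by the
#'   feedback excess for the stimulated synapse).
#' @param thetaFb feedback threshold (activation units).
#' @param kappa efficacy steepness (per volt).
#' @param eliminationFraction decision criterion for [runCompetition()].
#' @return A [TsWtaParams-class] object.
#' @examples
#' p <- tsWtaParams()
#' efficacy(p@vfgMin, p) / efficacy(p@vfgMax, p) # large: strong vs eliminated
#' @export
tsWtaParams <- function(vOn = -1, vOff = 6, pulseWidth = 0.02,
                        vfgMin = 4.0, vfgMax = 6.0, iB = 1,
                        etaInj = 0.05, etaTun = 0.05, etaLeak = 0.004,
                        thetaFb = 0.2, kappa = 6,
                        eliminationFraction = 0.05) {
  new("TsWtaParams",
      vOn = vOn, vOff = vOff, pulseWidth = pulseWidth,
      vfgMin = vfgMin, vfgMax = vfgMax, iB = iB,
      etaInj = etaInj, etaTun = etaTun, etaLeak = etaLeak,
      thetaFb = thetaFb, kappa = kappa,
      eliminationFraction = eliminationFraction)
}

setMethod("show", "TsWtaParams", function(object) {
  cat("TsWtaParams: vfg in [", object@vfgMin, ",", object@vfgMax,
      "] V, iB =", object@iB, ", thetaFb =", object@thetaFb,
      ", kappa =", object@kappa, "\n")
  cat("  rates: etaInj =", object@etaInj, ", etaTun =", object@etaTun,
      ", etaLeak =", object@etaLeak, "\n")
})

#' State of one ts-WTA synapse pair
#'
#' @slot vfg1,vfg2 floating-gate voltages (V) of synapse 1 and synapse 2.
#'   The lower voltage is the stronger synapse.
#' @seealso [tsWtaState()], [runCompetition()]
#' @export
setClass("TsWtaState", representation(vfg1 = "numeric", vfg2 = "numeric"))

#' @rdname TsWtaState-class
#' @param vfg1,vfg2 initial floating-gate voltages (V).
#' @param params parameters used to validate the admissible range.
#' @export
tsWtaState <- function(vfg1, vfg2, params = tsWtaParams()) {
  if (vfg1 < params@vfgMin || vfg1 > params@vfgMax ||
      vfg2 < params@vfgMin || vfg2 > params@vfgMax)
    stop("floating-gate voltages must lie in [vfgMin, vfgMax]")
  new("TsWtaState", vfg1 = vfg1, vfg2 = vfg2)
}

setMethod("show", "TsWtaState", function(object) {
  cat("TsWtaState: vfg1 =", object@vfg1, "V, vfg2 =", object@vfg2, "V\n")
})

#' Outcome of a ts-WTA competition
#'
#' @slot winner one of \code{"S1"}, \code{"S2"}, \code{"UNDECIDED"}.
#' @slot trajectory (n+1) x 2 matrix of (vfg1, vfg2) after each pulse,
#'   including the initial state in row 1.
#' @slot pulsesToDecision pulse index at which the elimination criterion was
#'   first met (NA if undecided).
#' @export
setClass("CompetitionOutcome",
  representation(winner = "character", trajectory = "matrix",
                 pulsesToDecision = "integer"))

setMethod("show", "CompetitionOutcome", function(object) {
  cat("CompetitionOutcome:", object@winner,
      if (!is.na(object@pulsesToDecision))
        paste0("(decided at pulse ", object@pulsesToDecision, ")") else "",
      "\n")
  n <- nrow(object@trajectory)
  cat("  final vfg: (", object@trajectory[n, 1], ",",
      object@trajectory[n, 2], ") V after", n - 1L, "pulses\n")
})

# ---------------------------------------------------------------------------
# Disparity cell classes
# ---------------------------------------------------------------------------

#' Receptive field of a disparity-selective cell
#'
#' An h x w grid of ts-WTA synapse pairs covering a spliced binocular window
#' (left-eye subfield of width \code{wL} next to a right-eye subfield of
#' width \code{wR}, \code{w = wL + wR}, near-even split).
#'
#' @slot vfg1,vfg2 h x w matrices of floating-gate voltages (V) of the two
#'   synapses at every grid position (synapse 1 is driven by the ON bit of a
#'   stimulus, synapse 2 by its complement).
#' @slot wL,wR widths (columns) of the left and right subfields.
#' @slot initRange the (low, high) voltage range used at initialization.
#' @seealso [initReceptiveField()], [representableDisparities()]
#' @export
setClass("ReceptiveField",
  representation(vfg1 = "matrix", vfg2 = "matrix",
                 wL = "integer", wR = "integer", initRange = "numeric"))

setValidity("ReceptiveField", function(object) {
  msg <- character()
  if (!all(dim(object@vfg1) == dim(object@vfg2)))
    msg <- c(msg, "vfg1 and vfg2 must have identical dimensions")
  if (ncol(object@vfg1) != object@wL + object@wR)
    msg <- c(msg, "total width must equal wL + wR")
  if (abs(object@wL - object@wR) > 1L)
    msg <- c(msg, "|wL - wR| must be <= 1 (near-even split)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ReceptiveField", function(object) {
  cat("ReceptiveField:", nrow(object@vfg1), "x", ncol(object@vfg1),
      "ts-WTA units (", object@wL, "left |", object@wR, "right )\n")
})

#' A disparity-selective cell
#'
#' A receptive field of ts-WTA units plus the cell-level circuit constants:
#' the output node (driving), the diffusion node (fed one-way from the
#' output through a buffer), and the resistances/capacitance of the RC
#' feedback network.
#'
#' @slot rf a [ReceptiveField-class].
#' @slot params the [TsWtaParams-class] shared by every unit.
#' @slot rD,rF diffusive and feedback resistances (ohm, default 1000).
#' @slot cD diffusion capacitance (farad, default 10e-12). Not integrated in
#'   time: the RC time constant (~10 ns) is negligible against the 0.02 s
#'   pulse width, so the network is solved quasi-statically.
#' @slot outputLevel,diffusionLevel last computed node levels (dimensionless
#'   activation units). The diffusion node never drives the output node.
#' @slot learnedDisparity preferred disparity after training (NA before
#'   training or when the tuning maximum is not unique).
#' @slot trace per-epoch training trace: matrix of responses to each probe
#'   disparity (epochs x D), or a 0-row matrix before training.
#' @seealso [disparityCell()], [trainCell()], [tuningCurve()]
#' @export
setClass("DisparityCell",
  representation(rf = "ReceptiveField", params = "TsWtaParams",
                 rD = "numeric", rF = "numeric", cD = "numeric",
                 outputLevel = "numeric", diffusionLevel = "numeric",
                 learnedDisparity = "integer", trace = "matrix"))

setValidity("DisparityCell", function(object) {
  msg <- character()
  if (object@rD <= 0 || object@rF <= 0) msg <- c(msg, "rD and rF must be > 0")
  if (object@cD <= 0) msg <- c(msg, "cD must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DisparityCell", function(object) {
  cat("DisparityCell:", nrow(object@rf@vfg1), "x", ncol(object@rf@vfg1),
      "units;", "learned disparity:",
      if (is.na(object@learnedDisparity)) "none (untrained/ambiguous)"
      else object@learnedDisparity, "\n")
})

#' Tuning curve of a disparity cell
#'
#' @slot disparities integer probe disparities.
#' @slot responses non-negative responses, one per probe disparity.
#' @seealso [tuningCurve()], [hwhh()]
#' @export
setClass("TuningCurve",
  representation(disparities = "integer", responses = "numeric"))

setValidity("TuningCurve", function(object) {
  msg <- character()
  if (length(object@disparities) != length(object@responses))
    msg <- c(msg, "disparities and responses must have the same length")
  if (any(object@responses < 0)) msg <- c(msg, "responses must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TuningCurve", function(object) {
  cat("TuningCurve over disparities", paste(object@disparities, collapse = " "),
      "\n  responses:", paste(signif(object@responses, 3), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# Synthetic data classes
# ---------------------------------------------------------------------------

#' A binary interlaced disparity stimulus
#'
#' A binocular stimulus: the left subfield occupies the first \code{wL}
#' columns and the right subfield the remaining \code{wR} columns; the right
#' subfield content is the left content shifted horizontally by the
#' disparity (zero-fill at vacated columns). ON bits stand for the high
#' (+6 V) pulse and OFF bits for the low (-1 V) pulse driven into the
#' complementary synapse.
#'
#' @slot bits h x (wL+wR) binary (0/1) matrix.
#' @slot wL,wR subfield widths.
#' @slot disparity integer disparity label (0-based).
#' @slot isComplement TRUE if this is the bitwise complement of the base
#'   pattern for its disparity.
#' @seealso [makeDisparityPattern()], [makePatternSet()]
#' @export
setClass("DisparityPattern",
  representation(bits = "matrix", wL = "integer", wR = "integer",
                 disparity = "integer", isComplement = "logical"))

setValidity("DisparityPattern", function(object) {
  msg <- character()
  if (!all(object@bits %in% c(0, 1))) msg <- c(msg, "bits must be 0/1")
  if (ncol(object@bits) != object@wL + object@wR)
    msg <- c(msg, "bits width must equal wL + wR")
  if (object@disparity < 0L) msg <- c(msg, "disparity must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DisparityPattern", function(object) {
  cat("DisparityPattern: d =", object@disparity,
      if (object@isComplement) "(complement)" else "",
      ";", nrow(object@bits), "x", ncol(object@bits),
      "(", object@wL, "|", object@wR, ")\n")
})

#' A rectified stereo image pair with ground truth
#'
#' Grayscale images in [0, 1]; disparity is purely horizontal (epipolar
#' rows). The right image is the left image shifted per-region by the
#' ground-truth disparity; columns with no unique source are flagged
#' occluded.
#'
#' @slot left,right H x W grayscale matrices.
#' @slot groundTruth H x W integer disparity map (left-referenced).
#' @slot occlusion H x W logical; TRUE where the right image had to be
#'   filled because no (or no unique) left-image source existed.
#' @seealso [makeStereoPair()], [disparityMap()]
#' @export
setClass("StereoPair",
  representation(left = "matrix", right = "matrix",
                 groundTruth = "matrix", occlusion = "matrix"))

setValidity("StereoPair", function(object) {
  msg <- character()
  d <- dim(object@left)
  if (!all(dim(object@right) == d) || !all(dim(object@groundTruth) == d) ||
      !all(dim(object@occlusion) == d))
    msg <- c(msg, "left, right, groundTruth and occlusion must share dimensions")
  if (any(object@groundTruth < 0)) msg <- c(msg, "ground-truth disparities must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StereoPair", function(object) {
  cat("StereoPair:", nrow(object@left), "x", ncol(object@left),
      "; disparities", paste(sort(unique(as.vector(object@groundTruth))),
                             collapse = " "), "\n")
})

#' A per-pixel disparity map with validity flags
#'
#' @slot values H x W integer matrix of estimated disparities.
#' @slot validMask H x W logical; FALSE at border pixels (window did not fit
#'   without padding) and at tie/degenerate pixels.
#' @seealso [disparityMap()], [averageError()]
#' @export
setClass("DisparityMap",
  representation(values = "matrix", validMask = "matrix"))

setValidity("DisparityMap", function(object) {
  if (!all(dim(object@values) == dim(object@validMask)))
    "values and validMask must share dimensions" else TRUE
})

setMethod("show", "DisparityMap", function(object) {
  cat("DisparityMap:", nrow(object@values), "x", ncol(object@values), ";",
      sum(object@validMask), "valid pixels\n")
})

# ---------------------------------------------------------------------------
# Reaction-diffusion classes
# ---------------------------------------------------------------------------

#' A reaction-diffusion lattice of disparity states
#'
#' Each site holds a real disparity state evolving under a multistable
#' reaction term (stable roots at the integers 0..D-1, unstable separatrices
#' at the half-integers) plus, optionally, discrete Laplacian diffusion.
#'
#' @slot X R x C real state matrix.
#' @slot alpha reaction constant (> 0; explicit-Euler stability needs
#'   \code{alpha < 1} for the unit-slope reaction used here).
#' @slot dU diffusion constant (>= 0; stability needs \code{dU <= 0.25}).
#' @slot D number of disparities (stable roots), >= 2.
#' @slot boundary \code{"reflect"} (cortical sheet edge) or \code{"wrap"}.
#' @seealso [rdLattice()], [evolveRD()], [mapStats()]
#' @export
setClass("RDLattice",
  representation(X = "matrix", alpha = "numeric", dU = "numeric",
                 D = "integer", boundary = "character"))

setValidity("RDLattice", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@dU < 0) msg <- c(msg, "dU must be >= 0")
  if (object@D < 2L) msg <- c(msg, "D must be >= 2")
  if (!object@boundary %in% c("reflect", "wrap"))
    msg <- c(msg, "boundary must be 'reflect' or 'wrap'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RDLattice", function(object) {
  cat("RDLattice:", nrow(object@X), "x", ncol(object@X), "; D =", object@D,
      ", alpha =", object@alpha, ", dU =", object@dU,
      ", boundary =", object@boundary, "\n")
})

#' Quality statistics of a disparity map lattice
#'
#' @slot continuity mean absolute difference across 4-neighbour pairs.
#' @slot diversity fraction of the D disparities present (rounded states).
#' @slot clusterCount number of 4-connected components of equal rounded
#'   disparity.
#' @slot clusterLabels R x C integer component ids.
#' @seealso [mapStats()]
#' @export
setClass("MapStats",
  representation(continuity = "numeric", diversity = "numeric",
                 clusterCount = "integer", clusterLabels = "matrix"))

setValidity("MapStats", function(object) {
  msg <- character()
  if (object@diversity < 0 || object@diversity > 1)
    msg <- c(msg, "diversity must lie in [0, 1]")
  if (object@clusterCount < 1L) msg <- c(msg, "clusterCount must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MapStats", function(object) {
  cat("MapStats: continuity =", signif(object@continuity, 4),
      ", diversity =", object@diversity,
      ",", object@clusterCount, "clusters\n")
})
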