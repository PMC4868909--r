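# Behavioral model of one time-staggered winner-take-all (ts-WTA) synapse
# pair: two floating-gate synapses compete over time for a fixed activation
# budget. Injection (strengthening) lowers the floating-gate voltage,
# tunneling (weakening) raises it; an unstimulated synapse slowly leaks
# toward elimination.

#' Synaptic efficacy of a floating-gate synapse
#'
#' Efficacy is a strictly decreasing, continuous function of the
#' floating-gate voltage: a saturating exponential
#' \code{exp(-kappa * (vfg - vfgMin))}, mirroring subthreshold pFET behavior
#' qualitatively. At \code{vfgMax} the efficacy is at most 1% of the
#' efficacy at \code{vfgMin} (enforced by the parameter validity).
#'
#' @param vfg floating-gate voltage(s), V; must lie in
#'   \code{[vfgMin, vfgMax]}.
#' @param params a [TsWtaParams-class] object.
#' @return Dimensionless efficacy in (0, 1], 1 at \code{vfgMin}.
#' @examples
#' p <- tsWtaParams()
#' efficacy(4.8, p) > efficacy(5.1, p) # stronger bias, higher efficacy
#' @export
efficacy <- function(vfg, params = tsWtaParams()) {
  if (any(vfg < params@vfgMin - 1e-12) || any(vfg > params@vfgMax + 1e-12))
    stop("vfg outside the admissible range [vfgMin, vfgMax]")
  exp(-params@kappa * (vfg - params@vfgMin))
}

#' Activation of a ts-WTA cell for one input pulse
#'
#' The two synapses are driven by complementary patterns, so at most one
#' input is ON at a time. The active synapse draws the shared bias resource
#' in proportion to its efficacy relative to the pair's total efficacy, and
#' the activation is capped at the resource level \code{iB}:
#' \code{A = min(iB, iB * e_active / (e_active + e_other))}.
#' With no active input the activation is 0; simultaneous activation of
#' both inputs violates the complementary-drive contract and is an error.
#'
#' @param state a [TsWtaState-class].
#' @param input1,input2 logical/0-1 pulse bits for synapse 1 and synapse 2.
#' @param params a [TsWtaParams-class].
#' @return Activation in \code{[0, iB]}.
#' @export
cellActivation <- function(state, input1, input2, params = tsWtaParams()) {
  a1 <- as.logical(input1); a2 <- as.logical(input2)
  if (a1 && a2)
    stop("complementarity broken: both synapses pulsed simultaneously ",
         "(ts-WTA requires time-staggered drive)")
  if (!a1 && !a2) return(0)
  e1 <- efficacy(state@vfg1, params)
  e2 <- efficacy(state@vfg2, params)
  eAct <- if (a1) e1 else e2
  min(params@iB, params@iB * eAct / (e1 + e2))
}

#' Apply one learning pulse to a ts-WTA synapse pair
#'
#' The stimulated synapse strengthens (its floating-gate voltage drops) when
#' the feedback exceeds the threshold \code{thetaFb} and weakens otherwise,
#' with threshold-linear magnitude; the unstimulated synapse passively
#' weakens by \code{etaLeak}. Voltages are clipped to the admissible range.
#'
#' @param state a [TsWtaState-class].
#' @param active which synapse is pulsed, \code{"S1"} or \code{"S2"}.
#' @param feedbackLevel non-negative feedback (activation units) gating
#'   injection versus tunneling.
#' @param params a [TsWtaParams-class].
#' @return The updated [TsWtaState-class].
#' @export
applyPulse <- function(state, active = c("S1", "S2"), feedbackLevel,
                       params = tsWtaParams()) {
  active <- match.arg(active)
  if (feedbackLevel < 0) stop("feedbackLevel must be >= 0")
  dAct <- -params@etaInj * pos(feedbackLevel - params@thetaFb) +
    params@etaTun * pos(params@thetaFb - feedbackLevel)
  if (active == "S1") {
    v1 <- state@vfg1 + dAct
    v2 <- state@vfg2 + params@etaLeak
  } else {
    v1 <- state@vfg1 + params@etaLeak
    v2 <- state@vfg2 + dAct
  }
  new("TsWtaState",
      vfg1 = clip(v1, params@vfgMin, params@vfgMax),
      vfg2 = clip(v2, params@vfgMin, params@vfgMax))
}

#' Build an alternating stimulation schedule
#'
#' One "cycle" pulses synapse 1 once and synapse 2 \code{ratio} times,
#' time-staggered (never simultaneous). \code{ratio = 1} is the equal
#' alternating schedule.
#'
#' @param cycles number of cycles.
#' @param ratio pulses delivered to synapse 2 per pulse to synapse 1.
#' @return Integer vector of synapse indices (1 or 2), one per pulse.
#' @export
alternatingSchedule <- function(cycles, ratio = 1L) {
  stopifnot(cycles >= 1, ratio >= 1)
  rep(c(1L, rep(2L, ratio)), cycles)
}

#' Run a ts-WTA competition over a stimulation schedule
#'
#' The schedule stimulates the two synapses in non-overlapping pulses. For
#' each pulse the feedback level is the cell's own activation for that pulse
#' (self-reinforcement in the standalone cell). Two laws emerge: with equal
#' stimulation the synapse with the stronger initial bias (lower vfg) wins;
#' with sufficiently unequal stimulation (ratio >= 3 against a bias gap of
#' <= 0.1 V under the default parameters) the more-stimulated synapse wins.
#'
#' @param state initial [TsWtaState-class].
#' @param schedule integer vector of synapse indices (1/2) as produced by
#'   [alternatingSchedule()], or a 2-column 0/1 matrix of per-pulse drive
#'   bits (a row with both bits set is an error: drive must be
#'   time-staggered).
#' @param params a [TsWtaParams-class].
#' @return A [CompetitionOutcome-class]. The winner is declared once the
#'   loser's efficacy falls below \code{eliminationFraction} times the
#'   winner's; otherwise \code{"UNDECIDED"}.
#' @examples
#' p <- tsWtaParams()
#' out <- runCompetition(tsWtaState(4.9, 5.3, p), alternatingSchedule(250), p)
#' out@winner # "S1": lower initial floating-gate voltage wins
#' @export
runCompetition <- function(state, schedule, params = tsWtaParams()) {
  if (is.matrix(schedule)) {
    if (ncol(schedule) != 2L) stop("schedule matrix must have two columns")
    if (any(schedule[, 1] != 0 & schedule[, 2] != 0))
      stop("schedule contains simultaneous pulses; ts-WTA requires ",
           "uncorrelated, time-staggered drive")
    if (any(schedule[, 1] == 0 & schedule[, 2] == 0))
      stop("schedule contains empty pulse slots")
    schedule <- ifelse(schedule[, 1] != 0, 1L, 2L)
  }
  if (!all(schedule %in% c(1L, 2L)))
    stop("schedule must contain synapse indices 1 and 2 only")
  n <- length(schedule)
  traj <- matrix(NA_real_, n + 1L, 2L,
                 dimnames = list(NULL, c("vfg1", "vfg2")))
  traj[1L, ] <- c(state@vfg1, state@vfg2)
  decided <- NA_integer_
  frac <- params@eliminationFraction
  for (i in seq_len(n)) {
    act <- if (schedule[i] == 1L) "S1" else "S2"
    fb <- cellActivation(state, schedule[i] == 1L, schedule[i] == 2L, params)
    state <- applyPulse(state, act, fb, params)
    traj[i + 1L, ] <- c(state@vfg1, state@vfg2)
    if (is.na(decided)) {
      e1 <- efficacy(state@vfg1, params); e2 <- efficacy(state@vfg2, params)
      if (min(e1, e2) < frac * max(e1, e2)) decided <- i
    }
  }
  e1 <- efficacy(state@vfg1, params)
  e2 <- efficacy(state@vfg2, params)
  winner <- if (e2 < frac * e1) "S1" else if (e1 < frac * e2) "S2"
            else "UNDECIDED"
  if (winner == "UNDECIDED") decided <- NA_integer_
  new("CompetitionOutcome", winner = winner, trajectory = traj,
      pulsesToDecision = decided)
}
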