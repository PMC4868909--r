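# Run configuration, serialization, the training driver, and the
# parameter-sweep robustness harness.

#' Default run configuration
#'
#' A named list covering every stage: geometry (h, w and disparity count),
#' ts-WTA parameters, training protocol (80 epochs, random-inside-epoch),
#' pipeline options, reaction-diffusion options, and output paths. The
#' single \code{seed} fans out to per-component child seeds (see
#' [childSeed()]) so any stage is independently reproducible.
#'
#' @param seed global seed.
#' @return Named list (a run configuration).
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    geometry = list(h = 9L, w = 9L, D = 4L),
    tswta = list(vOn = -1, vOff = 6, pulseWidth = 0.02,
                 vfgMin = 4, vfgMax = 6, iB = 1,
                 etaInj = 0.05, etaTun = 0.05, etaLeak = 0.004,
                 thetaFb = 0.2, kappa = 6, eliminationFraction = 0.05),
    training = list(epochs = 80L, schedule = "random-inside-epoch",
                    patternStyle = "random_dot", bias = 0.15,
                    initRange = c(4.8, 5.5)),
    pipeline = list(sigma = 0, edges = FALSE, border = "replicate",
                    texture = "ramp", patternStyle = "ramp"),
    rd = list(alpha = 0.5, dU = 0.04, steps = 200L, boundary = "reflect"),
    output = list(dir = "stereoWTA-out"),
    logLevel = "info"
  )
}

#' Validate a run configuration against module preconditions
#'
#' @param config run configuration list.
#' @return TRUE invisibly; otherwise an error describing every violated
#'   precondition.
#' @export
validateRunConfig <- function(config) {
  msg <- character()
  g <- config$geometry
  if (is.null(g$h) || g$h < 1L) msg <- c(msg, "geometry$h must be >= 1")
  if (is.null(g$w) || g$w < 2L) msg <- c(msg, "geometry$w must be >= 2")
  if (!is.null(g$w) && g$w >= 2L && !is.null(g$D) &&
      g$D > representableDisparities(g$w))
    msg <- c(msg, paste0("geometry$D = ", g$D, " exceeds representableDisparities(",
                         g$w, ") = ", representableDisparities(g$w)))
  p <- try(do.call(tsWtaParams, config$tswta), silent = TRUE)
  if (inherits(p, "try-error"))
    msg <- c(msg, paste("tswta:", attr(p, "condition")$message))
  tr <- config$training
  if (is.null(tr$epochs) || tr$epochs < 1L) msg <- c(msg, "training$epochs must be >= 1")
  if (!is.null(tr$initRange) && tr$initRange[1] >= tr$initRange[2])
    msg <- c(msg, "training$initRange must be (low, high)")
  if (config$pipeline$sigma < 0) msg <- c(msg, "pipeline$sigma must be >= 0")
  rd <- config$rd
  if (rd$alpha <= 0 || rd$alpha >= 1) msg <- c(msg, "rd$alpha must be in (0, 1)")
  if (rd$dU < 0 || rd$dU > 0.25) msg <- c(msg, "rd$dU must be in [0, 0.25]")
  if (!rd$boundary %in% c("reflect", "wrap"))
    msg <- c(msg, "rd$boundary must be 'reflect' or 'wrap'")
  if (length(msg)) stop("invalid configuration:\n  ",
                        paste(msg, collapse = "\n  "))
  invisible(TRUE)
}

#' Read / write a run configuration as YAML
#'
#' @param config run configuration list.
#' @param path YAML file path.
#' @return `writeRunConfig` returns `path` invisibly; `readRunConfig` the
#'   configuration list (validated).
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  config <- yaml::read_yaml(path)
  validateRunConfig(config)
  config
}

#' Train a disparity-cell bank from a configuration
#'
#' Builds the pattern set and a bank of D cells (one per disparity),
#' trains them, and writes the developed fields and tuning curves as CSV
#' (plus PGM renderings) under the configured output directory.
#' Reproducible: the same configuration and seed give byte-identical
#' outputs.
#'
#' @param config run configuration (see [defaultRunConfig()]).
#' @param writeOutputs logical; write CSV/PGM artifacts (default TRUE).
#' @return Invisibly, a list with elements \code{bank} (trained cells),
#'   \code{patterns}, and \code{curves} (tuning-curve data.frame).
#' @export
runTrain <- function(config = defaultRunConfig(), writeOutputs = TRUE) {
  validateRunConfig(config)
  g <- config$geometry
  params <- do.call(tsWtaParams, config$tswta)
  patterns <- makePatternSet(g$h, g$w, g$D,
                             style = config$training$patternStyle,
                             seed = childSeed(config$seed, 1))
  bank <- makeCellBank(patterns, params,
                       epochs = config$training$epochs,
                       bias = config$training$bias,
                       seed = childSeed(config$seed, 2),
                       initRange = config$training$initRange)
  base <- checkPatternSet(patterns)
  curves <- do.call(rbind, lapply(seq_along(bank), function(i) {
    tc <- tuningCurve(bank[[i]], base)
    data.frame(cell = i - 1L, disparity = tc@disparities,
               response = tc@responses)
  }))
  if (writeOutputs) {
    dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(bank)) {
      writeFieldCSV(bank[[i]]@rf,
                    file.path(config$output$dir, sprintf("field_d%d.csv", i - 1L)))
      renderField(bank[[i]]@rf, params,
                  file.path(config$output$dir, sprintf("field_d%d.pgm", i - 1L)))
    }
    utils::write.csv(curves, file.path(config$output$dir, "tuning_curves.csv"),
                     row.names = FALSE)
    if (config$logLevel != "quiet")
      message("trained ", length(bank), " cells -> ", config$output$dir)
  }
  invisible(list(bank = bank, patterns = patterns, curves = curves))
}

# ---------------------------------------------------------------------------
# Parameter-sweep robustness harness
# ---------------------------------------------------------------------------

## Registered behavioral invariants, each a function(params, seeds) -> logical.
## L1: equal stimulation, >= 0.1 V bias gap -> stronger-biased synapse wins.
## L2: >= 3x stimulation overrides a <= 0.1 V adverse bias gap.
## elimination: a persistently sub-threshold synapse is actively driven to
##   the top rail by tunneling on its own pulses (leak acts only on the
##   inactive partner, so this fails whenever etaTun = 0).
## resource_cap: activation never exceeds iB anywhere on the trajectory.
## clipping: no trajectory leaves [vfgMin, vfgMax].
sweepInvariants <- function() {
  drawL1 <- function(params) {
    gap <- stats::runif(1, 0.1, 0.5)
    v1 <- stats::runif(1, 4.8, 5.5 - gap)
    tsWtaState(v1, v1 + gap, params)
  }
  runs <- function(params, seeds, draw, ratio, check) {
    all(vapply(seq_len(seeds), function(s) {
      set.seed(s)
      st <- draw(params)
      out <- runCompetition(st, alternatingSchedule(250, ratio), params)
      check(out)
    }, logical(1)))
  }
  list(
    L1 = function(params, seeds)
      runs(params, seeds, drawL1, 1L, function(out) out@winner == "S1"),
    L2 = function(params, seeds)
      runs(params, seeds, function(params) {
        gap <- stats::runif(1, 0, 0.1)
        v1 <- stats::runif(1, 4.8, 5.4)
        tsWtaState(v1, v1 + gap, params)   # S2 weaker but stimulated 3x
      }, 3L, function(out) out@winner == "S2"),
    elimination = function(params, seeds)
      all(vapply(seq_len(seeds), function(s) {
        set.seed(s)
        st <- drawL1(params)
        for (i in seq_len(500)) st <- applyPulse(st, "S2", 0, params)
        st@vfg2 >= params@vfgMax - 1e-6
      }, logical(1))),
    resource_cap = function(params, seeds)
      runs(params, seeds, drawL1, 1L, function(out) {
        tr <- out@trajectory
        acts <- params@iB * exp(-params@kappa * (tr - params@vfgMin))
        all(acts / rowSums(acts) * params@iB <= params@iB + 1e-12)
      }),
    clipping = function(params, seeds)
      runs(params, seeds, drawL1, 1L, function(out)
        all(out@trajectory >= params@vfgMin - 1e-12 &
            out@trajectory <= params@vfgMax + 1e-12))
  )
}

#' Specify a parameter sweep
#'
#' @param parameters named list of numeric vectors: the grid of ts-WTA
#'   parameter values to sweep (full factorial).
#' @param seeds number of seeded runs per grid point.
#' @param invariants names of registered invariants to check; one or more
#'   of \code{"L1"}, \code{"L2"}, \code{"elimination"},
#'   \code{"resource_cap"}, \code{"clipping"}.
#' @return A \code{"SweepSpec"} list.
#' @export
sweepSpec <- function(parameters, seeds = 10L,
                      invariants = c("L1", "L2", "elimination",
                                     "resource_cap", "clipping")) {
  known <- names(sweepInvariants())
  bad <- setdiff(invariants, known)
  if (length(bad)) stop("unknown invariant name(s): ",
                        paste(bad, collapse = ", "))
  if (!length(parameters) || is.null(names(parameters)))
    stop("parameters must be a named list of numeric vectors")
  bad <- setdiff(names(parameters), names(formals(tsWtaParams)))
  if (length(bad)) stop("unknown ts-WTA parameter(s): ",
                        paste(bad, collapse = ", "))
  structure(list(parameters = parameters, seeds = as.integer(seeds),
                 invariants = invariants), class = "SweepSpec")
}

#' Run a parameter-variation stress sweep
#'
#' Evaluates each registered invariant at every grid point of the sweep
#' with the requested number of seeded competitions, summarizing the
#' robustness of the behavioral parameter set to parameter variation.
#'
#' @param spec a [sweepSpec()].
#' @param baseParams baseline [TsWtaParams-class] whose non-swept values are
#'   kept.
#' @return A data.frame: one row per grid point with the swept parameter
#'   values, one logical column per invariant, and \code{passAll}.
#' @export
runSweep <- function(spec, baseParams = tsWtaParams()) {
  if (!inherits(spec, "SweepSpec")) stop("spec must come from sweepSpec()")
  grid <- expand.grid(spec$parameters, KEEP.OUT.ATTRS = FALSE)
  registry <- sweepInvariants()[spec$invariants]
  res <- matrix(NA, nrow(grid), length(registry),
                dimnames = list(NULL, names(registry)))
  for (i in seq_len(nrow(grid))) {
    args <- as.list(grid[i, , drop = FALSE])
    params <- baseParams
    for (nm in names(args)) slot(params, nm) <- as.numeric(args[[nm]])
    ok <- try(validObject(params), silent = TRUE)
    for (j in seq_along(registry)) {
      res[i, j] <- if (inherits(ok, "try-error")) FALSE
                   else registry[[j]](params, spec$seeds)
    }
  }
  out <- cbind(grid, as.data.frame(res))
  out$passAll <- apply(res, 1, all)
  out
}
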