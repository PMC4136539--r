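#' @include AllClasses.R
NULL

.defaultLabels <- function(n) {
  if (n <= length(.BODY_PARTS)) .BODY_PARTS[seq_len(n)]
  else paste0("module_", seq_len(n))
}

#' Construct a grooming-simulator configuration
#'
#' Builds a validated \linkS4class{GroomConfig}. Mode-dependent defaults
#' follow the published model variants: under \code{sgm} the sensory weights
#' default to a strictly decreasing ramp from 2 down to 1 (so that weight gaps
#' dominate the 0.1-wide initial dust noise); under \code{uim} the strict
#' upper triangle of the inhibition matrix is filled with \code{-0.5}; under
#' \code{flat} the weights are all 1 and there is no inhibition.
#'
#' @param mode hierarchy variant: \code{"flat"} (no hierarchy), \code{"sgm"}
#'   (sensory gain) or \code{"uim"} (unidirectional inhibition).
#' @param nModules number of body-cleaning modules N (5 for body-only runs, 4
#'   in the leg-rubbing scenario).
#' @param sensoryWeights per-module sensory weights w^s; defaults by mode.
#' @param inhibitionWeight nonpositive scalar w for the strict upper triangle
#'   of the inhibition matrix; defaults by mode.
#' @param dustBase,dustNoise initial dust is \code{dustBase + U(0, dustNoise)}.
#' @param dustRemoval dust removed from the winner per iteration (dr).
#' @param nIterations number of iterations to simulate.
#' @param seed integer seed for the single random stream.
#' @param clampedModules indices held at \code{clampValue} (constitutive
#'   activation); empty by default.
#' @param clampValue clamp level; defaults to \code{dustBase + dustNoise}.
#' @param uimRecurrence \code{"stateless"} (activation recomputed from current
#'   dust, the default) or \code{"literal"} (activation iterated from the
#'   initial dust only).
#' @param legsEnabled enable the two leg-rubbing pairs.
#' @param legIncrement dust transferred onto the assigned leg pair per
#'   body-cleaning iteration.
#' @param legThreshold stationary activation threshold for rubbing (same for
#'   both pairs).
#' @param legDustRemoval dust removed from a pair per rubbing iteration.
#' @param anteriorBoundary body-module indices <= boundary dirty the front
#'   pair, larger ones the hind pair.
#' @param moduleLabels labels for the body modules; defaults to the hierarchy
#'   eye > antenna > abdomen > wing > thorax truncated to N.
#' @return a validated \linkS4class{GroomConfig}.
#' @examples
#' cfg <- groomConfig("uim", nIterations = 200, seed = 1)
#' cfg
#' @export
groomConfig <- function(mode = c("flat", "sgm", "uim"),
                        nModules = 5L,
                        sensoryWeights = NULL,
                        inhibitionWeight = NULL,
                        dustBase = 0.9,
                        dustNoise = 0.1,
                        dustRemoval = 0.05,
                        nIterations = 300L,
                        seed = 1L,
                        clampedModules = integer(),
                        clampValue = dustBase + dustNoise,
                        uimRecurrence = c("stateless", "literal"),
                        legsEnabled = FALSE,
                        legIncrement = 0.05,
                        legThreshold = 0.8,
                        legDustRemoval = 0.05,
                        anteriorBoundary = 3L,
                        moduleLabels = NULL) {
  mode <- match.arg(mode)
  uimRecurrence <- match.arg(uimRecurrence)
  nModules <- as.integer(nModules)
  if (is.null(sensoryWeights)) {
    sensoryWeights <- if (mode == "sgm") {
      if (nModules == 1L) 2 else seq(2, 1, length.out = nModules)
    } else rep(1, nModules)
  }
  if (is.null(inhibitionWeight))
    inhibitionWeight <- if (mode == "uim") -0.5 else 0
  if (is.null(moduleLabels)) moduleLabels <- .defaultLabels(nModules)
  new("GroomConfig",
      mode = mode, nModules = nModules,
      sensoryWeights = as.numeric(sensoryWeights),
      inhibitionWeight = as.numeric(inhibitionWeight),
      dustBase = dustBase, dustNoise = dustNoise, dustRemoval = dustRemoval,
      nIterations = as.integer(nIterations), seed = as.integer(seed),
      clampedModules = as.integer(sort(unlist(clampedModules))),
      clampValue = clampValue, uimRecurrence = uimRecurrence,
      legsEnabled = legsEnabled, legIncrement = legIncrement,
      legThreshold = legThreshold, legDustRemoval = legDustRemoval,
      anteriorBoundary = as.integer(anteriorBoundary),
      moduleLabels = moduleLabels)
}

#' Inhibition weight matrix of a configuration
#'
#' Returns the N x N matrix W with diagonal 1, strict upper triangle equal to
#' the configured inhibition weight (each module inhibits all modules below it
#' in the hierarchy) and strict lower triangle 0.
#'
#' @param config a \linkS4class{GroomConfig}.
#' @return an N x N numeric matrix.
#' @examples
#' weightMatrix(groomConfig("uim", nModules = 3))
#' @export
weightMatrix <- function(config) {
  stopifnot(is(config, "GroomConfig"))
  n <- config@nModules
  W <- diag(n)
  W[upper.tri(W)] <- config@inhibitionWeight
  dimnames(W) <- list(config@moduleLabels, config@moduleLabels)
  W
}

#' Construct an ethogram
#'
#' @param labels character vector of behavior labels, one per timestep.
#' @param timestep duration of a timestep in seconds (1 for model iterations).
#' @param subjectId identifier for the animal or run.
#' @param vocabulary declared label set; defaults to the labels observed, in
#'   order of first appearance.
#' @return an \linkS4class{Ethogram}.
#' @examples
#' eth <- Ethogram(c("eye", "eye", "antenna"))
#' findBouts(eth)
#' @export
Ethogram <- function(labels, timestep = 1, subjectId = "subject",
                     vocabulary = unique(labels)) {
  new("Ethogram", labels = as.character(labels), timestep = timestep,
      subjectId = subjectId, vocabulary = as.character(vocabulary))
}

#' Canonical simulation scenarios
#'
#' Returns the six named configurations used throughout the package's
#' examples and tests, mirroring the published simulation scenarios:
#' \describe{
#'   \item{flat}{five modules, equal dust sensitivity, no inhibition; module
#'     selection is driven purely by the initial dust noise.}
#'   \item{sensoryGain}{five modules with strictly decreasing sensory gain.}
#'   \item{inhibition}{five modules with unidirectional lateral inhibition
#'     (w = -0.5).}
#'   \item{clampClean}{constitutive activation of the mid-hierarchy module
#'     (index 3) with no dust anywhere else.}
#'   \item{clampDusty}{constitutive activation of module 3 with all body
#'     parts fully dusted, under unidirectional inhibition.}
#'   \item{legRubbing}{four body modules plus the two leg pairs, under
#'     unidirectional inhibition.}
#' }
#'
#' @param seed seed applied to every scenario (default 1).
#' @return named list of \linkS4class{GroomConfig} objects.
#' @examples
#' names(scenarioConfigs())
#' @export
scenarioConfigs <- function(seed = 1L) {
  list(
    flat = groomConfig("flat", nModules = 5, nIterations = 300L, seed = seed),
    sensoryGain = groomConfig("sgm", nModules = 5, nIterations = 300L, seed = seed),
    inhibition = groomConfig("uim", nModules = 5, nIterations = 300L, seed = seed),
    clampClean = groomConfig("uim", nModules = 5, nIterations = 100L, seed = seed,
                             dustBase = 0, dustNoise = 0, clampedModules = 3L,
                             clampValue = 1),
    clampDusty = groomConfig("uim", nModules = 5, nIterations = 300L, seed = seed,
                             clampedModules = 3L),
    legRubbing = groomConfig("uim", nModules = 4, nIterations = 400L, seed = seed,
                             legsEnabled = TRUE)
  )
}
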