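#' @import methods
NULL

.MODES <- c("flat", "sgm", "uim")
.RECURRENCES <- c("stateless", "literal")
.BODY_PARTS <- c("eye", "antenna", "abdomen", "wing", "thorax")
.LEG_LABELS <- c("front_leg_rub", "hind_leg_rub")

#' GroomConfig: parameters of the grooming simulator
#'
#' Holds every parameter of the hierarchical-suppression simulator: the
#' hierarchy variant (\code{mode}), the number of body-cleaning modules, the
#' per-module sensory weights, the unidirectional inhibition weight, dust
#' initialisation and removal constants, the set of constitutively activated
#' (clamped) modules, leg-rubbing parameters and the iteration count and seed.
#'
#' Modules are indexed 1..N in hierarchy order (index 1 is the most superior
#' module; for five-module runs the labels default to eye, antenna, abdomen,
#' wing, thorax).
#'
#' @slot mode one of \code{"flat"}, \code{"sgm"} (sensory gain model) or
#'   \code{"uim"} (unidirectional inhibition model).
#' @slot nModules number of body-cleaning modules N.
#' @slot sensoryWeights numeric vector of length N; strictly decreasing for
#'   \code{sgm}, all ones otherwise.
#' @slot inhibitionWeight nonpositive scalar filling the strict upper triangle
#'   of the inhibition matrix under \code{uim}; 0 otherwise.
#' @slot dustBase,dustNoise initial dust is \code{dustBase + U(0, dustNoise)}
#'   per module.
#' @slot dustRemoval constant dust amount removed from the winning module per
#'   iteration (dr).
#' @slot nIterations number of simulated timesteps.
#' @slot seed integer seed; all random draws flow from it.
#' @slot clampedModules integer indices whose dust is held at
#'   \code{clampValue} after every iteration (constitutive activation).
#' @slot clampValue dust level applied to clamped modules; defaults to
#'   \code{dustBase + dustNoise} (maximum dust).
#' @slot uimRecurrence \code{"stateless"} recomputes activation from current
#'   dust each iteration (a = dW); \code{"literal"} iterates a <- aW from the
#'   initial dust.
#' @slot legsEnabled,legIncrement,legThreshold,legDustRemoval leg-rubbing
#'   switch and parameters: dust added to the assigned leg pair per
#'   body-cleaning iteration, the stationary rubbing threshold, and dust
#'   removed per rubbing iteration.
#' @slot anteriorBoundary winners with index <= boundary dirty the front leg
#'   pair, larger indices the hind pair.
#' @slot moduleLabels character labels for the body modules.
#' @seealso [groomConfig()], [simulateGrooming()], [scenarioConfigs()]
#' @export
setClass("GroomConfig", representation(
  mode = "character",
  nModules = "integer",
  sensoryWeights = "numeric",
  inhibitionWeight = "numeric",
  dustBase = "numeric",
  dustNoise = "numeric",
  dustRemoval = "numeric",
  nIterations = "integer",
  seed = "integer",
  clampedModules = "integer",
  clampValue = "numeric",
  uimRecurrence = "character",
  legsEnabled = "logical",
  legIncrement = "numeric",
  legThreshold = "numeric",
  legDustRemoval = "numeric",
  anteriorBoundary = "integer",
  moduleLabels = "character"
))

setValidity("GroomConfig", function(object) {
  msg <- character()
  n <- object@nModules
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nModules must be a single positive integer")
  if (!(object@mode %in% .MODES))
    msg <- c(msg, sprintf("mode must be one of %s", paste(.MODES, collapse = ", ")))
  if (!(object@uimRecurrence %in% .RECURRENCES))
    msg <- c(msg, "uimRecurrence must be 'stateless' or 'literal'")
  if (length(object@sensoryWeights) != n)
    msg <- c(msg, "sensoryWeights must have length nModules")
  else {
    if (any(object@sensoryWeights <= 0))
      msg <- c(msg, "sensoryWeights must be positive")
    if (object@mode == "sgm" && n > 1L &&
        any(diff(object@sensoryWeights) >= 0))
      msg <- c(msg, "sgm sensoryWeights must be strictly decreasing")
    if (object@mode %in% c("flat", "uim") &&
        any(object@sensoryWeights != 1))
      msg <- c(msg, sprintf("%s mode requires all sensory weights equal to 1", object@mode))
  }
  if (object@inhibitionWeight > 0)
    msg <- c(msg, "inhibitionWeight must be nonpositive")
  if (object@mode %in% c("flat", "sgm") && object@inhibitionWeight != 0)
    msg <- c(msg, sprintf("%s mode requires inhibitionWeight == 0", object@mode))
  if (object@dustNoise < 0) msg <- c(msg, "dustNoise must be nonnegative")
  if (object@dustRemoval <= 0) msg <- c(msg, "dustRemoval must be positive")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be positive")
  if (length(object@clampedModules) &&
      (anyDuplicated(object@clampedModules) ||
       any(object@clampedModules < 1L | object@clampedModules > n)))
    msg <- c(msg, "clampedModules must be distinct indices in 1..nModules")
  if (object@legIncrement < 0) msg <- c(msg, "legIncrement must be nonnegative")
  if (object@legDustRemoval <= 0) msg <- c(msg, "legDustRemoval must be positive")
  if (length(object@moduleLabels) != n || anyDuplicated(object@moduleLabels))
    msg <- c(msg, "moduleLabels must be nModules distinct labels")
  if (any(object@moduleLabels %in% .LEG_LABELS))
    msg <- c(msg, "moduleLabels may not collide with the leg-rub labels")
  if (length(msg)) msg else TRUE
})

#' Ethogram: one behavior label per timestep
#'
#' The common currency of the simulator and the analysis functions: an ordered
#' sequence of mutually exclusive behavior labels, one per timestep, together
#' with the timestep duration and the label vocabulary.
#'
#' @slot labels character vector, one behavior per timestep.
#' @slot timestep duration of one step in seconds (1 for model iterations).
#' @slot subjectId identifier of the animal or simulation run.
#' @slot vocabulary declared label set; every label must belong to it.
#' @export
setClass("Ethogram", representation(
  labels = "character",
  timestep = "numeric",
  subjectId = "character",
  vocabulary = "character"
))

setValidity("Ethogram", function(object) {
  msg <- character()
  if (length(object@labels) == 0L) msg <- c(msg, "ethogram must be nonempty")
  if (anyNA(object@labels)) msg <- c(msg, "labels must not contain NA")
  if (!all(object@labels %in% object@vocabulary))
    msg <- c(msg, "all labels must be in the declared vocabulary")
  if (length(object@timestep) != 1L || object@timestep <= 0)
    msg <- c(msg, "timestep must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' GroomSim: result of a grooming simulation
#'
#' @slot ethogram [Ethogram-class] of winner labels, one per iteration.
#' @slot dustTrajectory nIterations x N matrix of post-iteration dust.
#' @slot activationTrajectory nIterations x N matrix of the activations used
#'   for selection at each iteration.
#' @slot legTrajectory nIterations x 2 matrix of post-iteration leg dust
#'   (0-row matrix when legs are disabled).
#' @slot initialDust,initialLegDust state before the first iteration.
#' @slot config the [GroomConfig-class] that produced the run.
#' @export
setClass("GroomSim", representation(
  ethogram = "Ethogram",
  dustTrajectory = "matrix",
  activationTrajectory = "matrix",
  legTrajectory = "matrix",
  initialDust = "numeric",
  initialLegDust = "numeric",
  config = "GroomConfig"
))

setValidity("GroomSim", function(object) {
  msg <- character()
  n <- object@config@nIterations
  if (length(object@ethogram@labels) != n)
    msg <- c(msg, "ethogram length must equal nIterations")
  if (nrow(object@dustTrajectory) != n || nrow(object@activationTrajectory) != n)
    msg <- c(msg, "trajectories must have nIterations rows")
  if (object@config@legsEnabled && nrow(object@legTrajectory) != n)
    msg <- c(msg, "legTrajectory must have nIterations rows when legs are enabled")
  if (any(object@dustTrajectory < 0)) msg <- c(msg, "dust must never be negative")
  if (length(msg)) msg else TRUE
})

#' TransitionMatrix: first-order transition structure of an ethogram
#'
#' Counts and row-normalised probabilities of transitions between behaviors.
#' By default transitions are counted between bouts (maximal runs), so the
#' diagonal of \code{counts} is identically zero. Rows with no outgoing
#' transitions are all-zero and flagged in \code{emptyRows} rather than
#' renormalised.
#'
#' @slot labels ordered label vocabulary.
#' @slot counts L x L integer matrix of transition counts.
#' @slot probabilities L x L matrix; each populated row sums to 1.
#' @slot emptyRows logical; TRUE for labels with no outgoing transitions.
#' @slot minDisplay display threshold carried along for graph export only;
#'   never alters the matrix.
#' @export
setClass("TransitionMatrix", representation(
  labels = "character",
  counts = "matrix",
  probabilities = "matrix",
  emptyRows = "logical",
  minDisplay = "numeric"
))

setValidity("TransitionMatrix", function(object) {
  msg <- character()
  L <- length(object@labels)
  if (!all(dim(object@counts) == c(L, L)) ||
      !all(dim(object@probabilities) == c(L, L)))
    msg <- c(msg, "counts and probabilities must be L x L")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be nonnegative integers")
  rs <- rowSums(object@probabilities)
  if (any(abs(rs[!object@emptyRows] - 1) > 1e-12))
    msg <- c(msg, "populated probability rows must sum to 1")
  if (any(rs[object@emptyRows] != 0))
    msg <- c(msg, "empty rows must be all zero")
  if (length(msg)) msg else TRUE
})

#' DecayFit: fitted dust-clearance curve and its half-clearance time
#'
#' @slot model \code{"exponential"}, \code{"sigmoidal"}, or
#'   \code{"interpolation"} when the parametric fit failed and the model-free
#'   fallback was used.
#' @slot parameters named parameter vector of the fitted curve.
#' @slot t50 time at which the fitted curve crosses half its fitted initial
#'   value.
#' @slot converged FALSE when the fallback was used.
#' @export
setClass("DecayFit", representation(
  model = "character",
  parameters = "numeric",
  t50 = "numeric",
  converged = "logical"
))

setValidity("DecayFit", function(object) {
  if (length(object@t50) != 1L || is.na(object@t50) || object@t50 <= 0)
    "t50 must be a single positive number" else TRUE
})

#' DustImage: binary dust raster for one body-part sample
#'
#' Pixels are 1 where dust is present and 0 where clean (the 0/255 grayscale
#' convention of raw micrographs is rescaled on read). Images in a stack are
#' assumed pre-registered to a common standard: dimensions must match exactly.
#'
#' @slot pixels integer matrix of 0/1 values (row-major raster, origin
#'   top-left).
#' @slot bodyPart,subjectId,timeMin sample annotation.
#' @export
setClass("DustImage", representation(
  pixels = "matrix",
  bodyPart = "character",
  subjectId = "character",
  timeMin = "numeric"
))

setValidity("DustImage", function(object) {
  if (!all(object@pixels %in% c(0, 1)))
    "pixels must be binary (0 = clean, 1 = dust)" else TRUE
})

#' RegionMask: binary region definition for dust counting
#'
#' @slot pixels binary matrix; 1 marks pixels belonging to the region.
#' @slot regionName label of the region.
#' @export
setClass("RegionMask", representation(
  pixels = "matrix",
  regionName = "character"
))

setValidity("RegionMask", function(object) {
  msg <- character()
  if (!all(object@pixels %in% c(0, 1))) msg <- c(msg, "mask pixels must be binary")
  if (sum(object@pixels) < 1) msg <- c(msg, "mask must contain at least one pixel")
  if (length(msg)) msg else TRUE
})

#' DustMap: per-pixel fraction of subjects with dust (groomogram)
#'
#' @slot fractions matrix of values in [0, 1]; each value is the fraction of
#'   subjects dusted at that pixel coordinate.
#' @slot nSubjects number of images averaged.
#' @export
setClass("DustMap", representation(
  fractions = "matrix",
  nSubjects = "integer"
))

setValidity("DustMap", function(object) {
  if (any(object@fractions < 0 | object@fractions > 1))
    "fractions must lie in [0, 1]" else TRUE
})
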