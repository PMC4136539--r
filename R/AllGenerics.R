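#' @include AllClasses.R
NULL

#' Accessors for simulation results and analysis objects
#'
#' Standard accessor generics: use these rather than reaching into slots.
#'
#' @param x a \linkS4class{GroomSim}, \linkS4class{Ethogram},
#'   \linkS4class{TransitionMatrix}, \linkS4class{DecayFit},
#'   \linkS4class{DustImage} or \linkS4class{DustMap} object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ethogram", function(x) standardGeneric("ethogram"))

#' @rdname accessors
#' @export
setGeneric("dustTrajectory", function(x) standardGeneric("dustTrajectory"))

#' @rdname accessors
#' @export
setGeneric("activationTrajectory", function(x) standardGeneric("activationTrajectory"))

#' @rdname accessors
#' @export
setGeneric("legTrajectory", function(x) standardGeneric("legTrajectory"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))

#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))

#' @rdname accessors
#' @export
setGeneric("t50", function(x) standardGeneric("t50"))

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Per-label bout statistics of an ethogram or cohort
#'
#' @param x an \linkS4class{Ethogram} or a list of them (a cohort).
#' @param ... passed on to methods.
#' @export
setGeneric("marginalProbability", function(x, ...) standardGeneric("marginalProbability"))

setMethod("ethogram", "GroomSim", function(x) x@ethogram)
setMethod("dustTrajectory", "GroomSim", function(x) x@dustTrajectory)
setMethod("activationTrajectory", "GroomSim", function(x) x@activationTrajectory)
setMethod("legTrajectory", "GroomSim", function(x) x@legTrajectory)
setMethod("modelConfig", "GroomSim", function(x) x@config)
setMethod("transitionCounts", "TransitionMatrix", function(x) x@counts)
setMethod("transitionProbs", "TransitionMatrix", function(x) x@probabilities)
setMethod("t50", "DecayFit", function(x) x@t50)
setMethod("pixels", "DustImage", function(x) x@pixels)
setMethod("pixels", "RegionMask", function(x) x@pixels)

#' @describeIn accessors behavior labels of an ethogram
#' @param object,... see \code{\link[base]{labels}}
#' @export
setMethod("labels", "Ethogram", function(object, ...) object@labels)

#' @describeIn accessors number of timesteps in an ethogram
#' @export
setMethod("length", "Ethogram", function(x) length(x@labels))

setMethod("show", "GroomConfig", function(object) {
  cat(sprintf("GroomConfig: mode=%s, N=%d, dr=%g, iterations=%d, seed=%d\n",
              object@mode, object@nModules, object@dustRemoval,
              object@nIterations, object@seed))
  cat(sprintf("  modules: %s\n", paste(object@moduleLabels, collapse = " > ")))
  if (length(object@clampedModules))
    cat(sprintf("  clamped at %g: %s\n", object@clampValue,
                paste(object@clampedModules, collapse = ", ")))
  if (object@legsEnabled)
    cat(sprintf("  legs: increment=%g threshold=%g removal=%g boundary=%d\n",
                object@legIncrement, object@legThreshold,
                object@legDustRemoval, object@anteriorBoundary))
  invisible(object)
})

setMethod("show", "GroomSim", function(object) {
  lab <- object@ethogram@labels
  cat(sprintf("GroomSim: %d iterations, mode=%s, N=%d\n",
              length(lab), object@config@mode, object@config@nModules))
  tab <- table(factor(lab, levels = object@ethogram@vocabulary))
  cat("  selections:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "Ethogram", function(object) {
  cat(sprintf("Ethogram '%s': %d steps of %gs, %d labels\n",
              object@subjectId, length(object@labels), object@timestep,
              length(unique(object@labels))))
  invisible(object)
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix over %d labels, %d transitions\n",
              length(object@labels), sum(object@counts)))
  print(round(object@probabilities, 3))
  invisible(object)
})

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit (%s%s): t50 = %.4g\n", object@model,
              if (object@converged) "" else ", fallback", object@t50))
  invisible(object)
})

setMethod("show", "DustMap", function(object) {
  cat(sprintf("DustMap %d x %d over %d subjects (mean fraction %.3f)\n",
              nrow(object@fractions), ncol(object@fractions),
              object@nSubjects, mean(object@fractions)))
  invisible(object)
})
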