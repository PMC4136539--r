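#' @include groomConfig.R
NULL

# Evaluate expr with a temporary seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Initial dust vector
#'
#' Draws the initial dust d_k = dustBase + r_k with r_k independent uniform on
#' [0, dustNoise], one draw per module in index order, then sets clamped
#' modules to the clamp value. The draw order (modules 1..N first, then any
#' later draws) is part of the package's seeding contract.
#'
#' @param config a \linkS4class{GroomConfig}.
#' @return numeric vector of length \code{nModules}.
#' @examples
#' initDust(groomConfig("flat", dustNoise = 0, seed = 1))
#' @export
initDust <- function(config) {
  stopifnot(is(config, "GroomConfig"))
  d <- config@dustBase + stats::runif(config@nModules, 0, config@dustNoise)
  d[config@clampedModules] <- config@clampValue
  names(d) <- config@moduleLabels
  d
}

#' Sensory-gain activation
#'
#' Elementwise product a_k = d_k * w^s_k: under the sensory gain model each
#' module's activation is its dust level scaled by its sensory weight.
#'
#' @param dust current dust vector d.
#' @param sensoryWeights weight vector w^s of the same length.
#' @return activation vector.
#' @examples
#' activationSGM(c(0.9, 0.9, 0.9), c(3, 2, 1))
#' @export
activationSGM <- function(dust, sensoryWeights) {
  if (length(dust) != length(sensoryWeights))
    stop("dust and sensoryWeights must have the same length")
  dust * sensoryWeights
}

#' Unidirectional-inhibition activation
#'
#' Applies the inhibition matrix W (diagonal 1, strict upper triangle w <= 0).
#' In the default \code{"stateless"} recurrence the activation is recomputed
#' from the current dust, a = dW, so that cleaning a body part lowers the
#' inhibition it exerts downstream. In the \code{"literal"} recurrence the
#' previous activation is propagated, a <- aW, and dust enters only through
#' the initial condition; it is provided for comparison (see the methods
#' vignette for why it cannot sustain a grooming progression).
#'
#' @param dust current dust vector d.
#' @param W inhibition matrix from [weightMatrix()].
#' @param prevActivation previous activation vector (literal mode only).
#' @param recurrence \code{"stateless"} or \code{"literal"}.
#' @return activation vector.
#' @examples
#' W <- weightMatrix(groomConfig("uim", nModules = 3))
#' activationUIM(c(1, 1, 1), W)  # 1, 0.5, 0
#' @export
activationUIM <- function(dust, W, prevActivation = NULL,
                          recurrence = c("stateless", "literal")) {
  recurrence <- match.arg(recurrence)
  n <- length(dust)
  if (!all(dim(W) == c(n, n))) stop("W must be length(dust) x length(dust)")
  src <- if (recurrence == "stateless") dust else {
    if (is.null(prevActivation)) dust else prevActivation
  }
  as.numeric(src %*% W)
}

#' Winner-take-all selection
#'
#' Selects the behavior executed this iteration. A leg pair wins if and only
#' if its activation is at or above the stationary rubbing threshold, strictly
#' above the activation of every body module, and strictly above the other
#' pair. Otherwise the body module with maximal activation wins, with ties
#' broken toward the lowest index (the hierarchically superior module). The
#' returned one-hot selection vector e marks the winning body module and is
#' all zeros when a leg pair wins.
#'
#' @param activation body-module activation vector a.
#' @param legActivation 2-vector of leg-pair activations (front, hind).
#' @param legThreshold stationary rubbing threshold.
#' @param legsEnabled whether leg pairs compete at all.
#' @param moduleLabels optional labels for the body modules.
#' @return list with \code{label}, \code{index} (body-module index, NA for a
#'   leg win), \code{isLeg}, \code{legPair} (1 front / 2 hind, NA for a body
#'   win) and the one-hot \code{selection} vector.
#' @examples
#' selectWinner(c(0.3, 0.9, 0.1))$label
#' @export
selectWinner <- function(activation, legActivation = c(0, 0),
                         legThreshold = Inf, legsEnabled = FALSE,
                         moduleLabels = NULL) {
  if (length(activation) == 0L) stop("activation must be nonempty")
  if (is.null(moduleLabels)) moduleLabels <- .defaultLabels(length(activation))
  if (legsEnabled) {
    for (p in 1:2) {
      other <- 3L - p
      if (legActivation[p] >= legThreshold &&
          legActivation[p] > max(activation) &&
          legActivation[p] > legActivation[other]) {
        return(list(label = .LEG_LABELS[p], index = NA_integer_,
                    isLeg = TRUE, legPair = p,
                    selection = integer(length(activation))))
      }
    }
  }
  ma <- which.max(activation)  # which.max breaks ties toward the lowest index
  e <- integer(length(activation))
  e[ma] <- 1L
  list(label = moduleLabels[ma], index = as.integer(ma), isLeg = FALSE,
       legPair = NA_integer_, selection = e)
}

#' Remove dust from the winning body module
#'
#' Subtracts the constant dr from the winner's dust, floored at zero, then
#' re-applies the clamp: constitutively activated modules are reset to the
#' clamp value after every iteration, so cleaning them has no lasting effect.
#'
#' @param dust dust vector.
#' @param winner index of the winning body module.
#' @param dr dust removed per iteration.
#' @param clamped indices of clamped modules.
#' @param clampValue level clamped modules are held at.
#' @return updated dust vector.
#' @export
removeDust <- function(dust, winner, dr, clamped = integer(),
                       clampValue = 1) {
  if (winner < 1L || winner > length(dust)) stop("winner index out of range")
  dust[winner] <- max(dust[winner] - dr, 0)
  dust[clamped] <- clampValue
  dust
}

#' Update leg dust after an iteration
#'
#' Body-cleaning iterations transfer a small constant amount of dust onto the
#' leg pair doing the cleaning: modules with index at or below the anterior
#' boundary dirty the front pair, the rest the hind pair. A leg-rubbing
#' iteration removes \code{legDustRemoval} from the rubbing pair, floored at
#' zero. Leg activation is the leg dust itself (proportionality constant 1).
#'
#' @param legDust 2-vector of leg dust (front, hind).
#' @param winner body-module index, or a leg-rub label
#'   (\code{"front_leg_rub"} / \code{"hind_leg_rub"}).
#' @param config a \linkS4class{GroomConfig} with legs enabled.
#' @return updated 2-vector of leg dust.
#' @export
updateLegs <- function(legDust, winner, config) {
  if (is.character(winner)) {
    p <- match(winner, .LEG_LABELS)
    if (is.na(p)) stop("unknown leg label: ", winner)
    legDust[p] <- max(legDust[p] - config@legDustRemoval, 0)
  } else {
    pair <- if (winner <= config@anteriorBoundary) 1L else 2L
    legDust[pair] <- legDust[pair] + config@legIncrement
  }
  legDust
}

#' Run the hierarchical-suppression grooming simulation
#'
#' Executes the three-layer model: per-module dust drives a sensory layer, the
#' hierarchical layer shapes activations (by sensory gain, unidirectional
#' inhibition, or not at all), and a winner-take-all layer executes the single
#' most active module each iteration, removing a constant amount of dust from
#' the corresponding body part. Optional leg pairs accumulate dust while they
#' clean and rub it off once sufficiently dirty, and clamped modules model
#' constitutive activation. Identical configurations with identical seeds
#' produce identical results.
#'
#' When legs are enabled the leg pairs start dusted like the body modules
#' (two further uniform draws after the N body draws): the modelled fly is
#' coated in dust all over, which is what lets rubbing appear from the
#' earliest cleaning bouts.
#'
#' @param config a \linkS4class{GroomConfig}.
#' @param initialDust optional length-N override of the initial body dust
#'   (skips the corresponding random draws; clamps still apply).
#' @param initialLegDust optional length-2 override of the initial leg dust.
#' @return a \linkS4class{GroomSim}.
#' @examples
#' sim <- simulateGrooming(groomConfig("sgm", nIterations = 150, seed = 7))
#' firstSelection(sim)
#' @export
simulateGrooming <- function(config, initialDust = NULL, initialLegDust = NULL) {
  validObject(config)
  n <- config@nModules
  iters <- config@nIterations
  legs <- config@legsEnabled
  W <- if (config@mode == "uim") weightMatrix(config) else NULL

  withSeed(config@seed, {
    d <- if (is.null(initialDust)) initDust(config) else {
      stopifnot(length(initialDust) == n)
      x <- as.numeric(initialDust)
      x[config@clampedModules] <- config@clampValue
      names(x) <- config@moduleLabels
      x
    }
    dl <- if (!legs) numeric(0)
      else if (is.null(initialLegDust))
        config@dustBase + stats::runif(2, 0, config@dustNoise)
      else as.numeric(initialLegDust)
  })
  d0 <- d
  dl0 <- dl

  dustTraj <- matrix(NA_real_, iters, n,
                     dimnames = list(NULL, config@moduleLabels))
  actTraj <- dustTraj
  legTraj <- if (legs) matrix(NA_real_, iters, 2,
                              dimnames = list(NULL, .LEG_LABELS))
             else matrix(numeric(0), 0, 2)
  winners <- character(iters)
  aPrev <- d  # literal UIM recurrence seeds activation with the initial dust

  for (i in seq_len(iters)) {
    a <- switch(config@mode,
      flat = as.numeric(d),
      sgm = activationSGM(d, config@sensoryWeights),
      uim = activationUIM(d, W, prevActivation = aPrev,
                          recurrence = config@uimRecurrence))
    al <- if (legs) dl else c(0, 0)  # activation proportional to leg dust
    win <- selectWinner(a, al, config@legThreshold, legs, config@moduleLabels)
    if (win$isLeg) {
      dl <- updateLegs(dl, win$label, config)
    } else {
      if (!(win$index %in% config@clampedModules))
        d[win$index] <- max(d[win$index] - config@dustRemoval, 0)
      d[config@clampedModules] <- config@clampValue
      if (legs) dl <- updateLegs(dl, win$index, config)
    }
    winners[i] <- win$label
    dustTraj[i, ] <- d
    actTraj[i, ] <- a
    if (legs) legTraj[i, ] <- dl
    aPrev <- a
  }

  vocab <- c(config@moduleLabels, if (legs) .LEG_LABELS)
  new("GroomSim",
      ethogram = Ethogram(winners, timestep = 1,
                          subjectId = sprintf("sim_seed%d", config@seed),
                          vocabulary = vocab),
      dustTrajectory = dustTraj, activationTrajectory = actTraj,
      legTrajectory = legTraj, initialDust = d0, initialLegDust = dl0,
      config = config)
}

#' First-selection iteration of each body module
#'
#' @param sim a \linkS4class{GroomSim}.
#' @return named integer vector: first iteration at which each body module
#'   won (NA if never selected).
#' @export
firstSelection <- function(sim) {
  stopifnot(is(sim, "GroomSim"))
  lab <- sim@ethogram@labels
  out <- vapply(sim@config@moduleLabels,
                function(m) {
                  i <- which(lab == m)
                  if (length(i)) i[1L] else NA_integer_
                }, integer(1))
  out
}

#' Final dust levels of a run
#'
#' @param sim a \linkS4class{GroomSim}.
#' @return named numeric vector of dust after the last iteration.
#' @export
finalDust <- function(sim) {
  stopifnot(is(sim, "GroomSim"))
  sim@dustTrajectory[nrow(sim@dustTrajectory), ]
}

#' First iteration at which all unclamped body dust is gone
#'
#' Convenience predicate for run length: the first iteration after which
#' every unclamped module's dust is zero (within 1e-12), or NA if the run
#' never clears.
#'
#' @param sim a \linkS4class{GroomSim}.
#' @return integer iteration index or NA.
#' @export
firstClearIteration <- function(sim) {
  stopifnot(is(sim, "GroomSim"))
  keep <- setdiff(seq_len(sim@config@nModules), sim@config@clampedModules)
  if (!length(keep)) return(1L)
  clear <- rowSums(sim@dustTrajectory[, keep, drop = FALSE] > 1e-12) == 0
  i <- which(clear)
  if (length(i)) i[1L] else NA_integer_
}
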