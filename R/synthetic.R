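#' @include simulate.R ethogram.R dustmaps.R
NULL

#' Generate a Markov ethogram with known transition structure
#'
#' Emits a label-per-timestep ethogram built from \code{nBouts} maximal runs:
#' bout labels follow a first-order Markov chain with the supplied
#' row-stochastic, zero-diagonal transition matrix (starting from the first
#' label), and bout lengths are geometric with the given per-label mean
#' (memoryless, the minimal assumption consistent with first-order transition
#' analysis). The ground truth is returned next to the data.
#'
#' @param P row-stochastic transition matrix with zero diagonal; row/column
#'   names are used as labels (defaults to LETTERS).
#' @param nBouts number of bouts to generate.
#' @param dwell mean bout length per label (scalar or per-label vector),
#'   >= 1.
#' @param seed integer seed.
#' @return list with \code{ethogram} (an \linkS4class{Ethogram}),
#'   \code{boutLabels}, and the ground-truth \code{P} and \code{dwell}.
#' @examples
#' P <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' generateMarkovEthogram(P, nBouts = 6, dwell = 1, seed = 1)$ethogram
#' @export
generateMarkovEthogram <- function(P, nBouts, dwell = 3, seed = 1L) {
  P <- as.matrix(P)
  L <- nrow(P)
  if (ncol(P) != L) stop("P must be square")
  if (any(diag(P) != 0)) stop("P must have a zero diagonal")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8))
    stop("P must be row-stochastic")
  labs <- rownames(P)
  if (is.null(labs)) labs <- LETTERS[seq_len(L)]
  dimnames(P) <- list(labs, labs)
  dwell <- rep_len(dwell, L)
  if (any(dwell < 1)) stop("dwell must be >= 1")
  names(dwell) <- labs

  withSeed(seed, {
    states <- integer(nBouts)
    states[1L] <- 1L
    for (b in seq_len(nBouts - 1L))
      states[b + 1L] <- sample.int(L, 1L, prob = P[states[b], ])
    lens <- vapply(states, function(s) {
      m <- dwell[s]
      if (m == 1) 1L else 1L + stats::rgeom(1L, 1 / m)
    }, integer(1))
  })
  list(ethogram = Ethogram(rep(labs[states], lens), subjectId = "synthetic",
                           vocabulary = labs),
       boutLabels = labs[states], P = P, dwell = dwell)
}

#' Generate a stack of binary dust images with known dust probability
#'
#' Each pixel of each image is independently dust-positive with the
#' probability given by \code{pMap}, emulating a registered stack of
#' binarized body-part photographs with a known underlying dust pattern.
#'
#' @param pMap matrix of per-pixel dust probabilities in [0, 1].
#' @param nSubjects number of images.
#' @param seed integer seed.
#' @param bodyPart annotation applied to all images.
#' @return list with \code{stack} (list of \linkS4class{DustImage}) and the
#'   ground-truth \code{pMap}.
#' @export
generateDustImageStack <- function(pMap, nSubjects, seed = 1L,
                                   bodyPart = "body_part") {
  pMap <- as.matrix(pMap)
  if (any(pMap < 0 | pMap > 1)) stop("pMap values must lie in [0, 1]")
  withSeed(seed, {
    stack <- lapply(seq_len(nSubjects), function(i) {
      px <- matrix(stats::rbinom(length(pMap), 1L, as.vector(pMap)),
                   nrow = nrow(pMap))
      DustImage(px, bodyPart = bodyPart,
                subjectId = sprintf("synthetic_%02d", i))
    })
  })
  list(stack = stack, pMap = pMap)
}

#' Generate a dust-decay time series with known half-clearance time
#'
#' Evaluates an exponential or sigmoidal (4-parameter logistic, lower
#' asymptote 0) decay with known t50 at the given time points and adds
#' Gaussian noise clipped to [0, 1].
#'
#' @param f0 initial dust fraction.
#' @param t50True ground-truth half-clearance time (> 0).
#' @param model \code{"exponential"} or \code{"sigmoidal"}.
#' @param noiseSd standard deviation of the additive noise.
#' @param timepoints numeric vector of measurement times.
#' @param seed integer seed.
#' @param steepness sigmoid slope; the default (10 / t50True) makes the curve
#'   effectively start at f0 so its midpoint coincides with t50.
#' @return list with \code{times}, \code{fractions}, and the ground truth
#'   (\code{f0}, \code{t50True}, \code{model}).
#' @examples
#' s <- generateDecaySeries(1, 7, "exponential", 0, 0:7 * 2)
#' t50(fitT50(s$times, s$fractions))
#' @export
generateDecaySeries <- function(f0, t50True, model = c("exponential", "sigmoidal"),
                                noiseSd = 0, timepoints = 0:7, seed = 1L,
                                steepness = 10 / t50True) {
  model <- match.arg(model)
  if (t50True <= 0) stop("t50True must be positive")
  clean <- switch(model,
    exponential = f0 * exp(-log(2) / t50True * timepoints),
    sigmoidal = .sigmoid4p(timepoints, 0, f0, t50True, steepness))
  fractions <- if (noiseSd > 0) {
    withSeed(seed, pmin(pmax(clean + stats::rnorm(length(clean), 0, noiseSd), 0), 1))
  } else clean
  list(times = timepoints, fractions = fractions,
       f0 = f0, t50True = t50True, model = model)
}
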