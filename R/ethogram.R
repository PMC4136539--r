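#' @include groomConfig.R
NULL

#' Find bouts (maximal runs) in an ethogram
#'
#' A bout is a maximal run of consecutive timesteps with the same label, so
#' consecutive bouts always differ and bout lengths sum to the ethogram
#' length.
#'
#' @param ethogram an \linkS4class{Ethogram}.
#' @return data.frame with columns \code{label}, \code{start} (1-based
#'   timestep of the bout's first step) and \code{length}.
#' @examples
#' findBouts(Ethogram(c("A", "A", "B", "B", "A")))
#' @export
findBouts <- function(ethogram) {
  stopifnot(is(ethogram, "Ethogram"))
  r <- rle(ethogram@labels)
  data.frame(label = r$values,
             start = cumsum(c(1L, r$lengths[-length(r$lengths)])),
             length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Bout frequency, optionally per time interval
#'
#' Counts bout starts per behavior label. With \code{interval} given, counts
#' are binned by the timestep containing each bout's start (a bout belongs to
#' exactly one interval, the one its start falls in).
#'
#' @param ethogram an \linkS4class{Ethogram}.
#' @param interval optional interval length in timesteps.
#' @return without \code{interval}: named integer vector over the vocabulary.
#'   With it: interval x label integer matrix (rows named by interval index).
#' @examples
#' eth <- Ethogram(c("A", "A", "B", "B", "A"))
#' boutFrequency(eth)
#' boutFrequency(eth, interval = 2)
#' @export
boutFrequency <- function(ethogram, interval = NULL) {
  stopifnot(is(ethogram, "Ethogram"))
  bouts <- findBouts(ethogram)
  vocab <- ethogram@vocabulary
  if (is.null(interval)) {
    tab <- table(factor(bouts$label, levels = vocab))
    out <- as.integer(tab)
    names(out) <- vocab
    return(out)
  }
  if (interval <= 0) stop("interval must be positive")
  nInt <- ceiling(length(ethogram@labels) / interval)
  bin <- (bouts$start - 1L) %/% as.integer(interval) + 1L
  m <- table(factor(bin, levels = seq_len(nInt)),
             factor(bouts$label, levels = vocab))
  out <- matrix(as.integer(m), nrow = nInt,
                dimnames = list(interval = seq_len(nInt), label = vocab))
  out
}

#' @describeIn marginalProbability fraction of total bouts per label for one
#'   ethogram; fractions sum to 1.
#' @export
setMethod("marginalProbability", "Ethogram", function(x, ...) {
  counts <- boutFrequency(x)
  total <- sum(counts)
  if (total == 0L) stop("ethogram contains no bouts")
  counts / total
})

#' @describeIn marginalProbability cohort variant: the mean of the per-subject
#'   bout fractions across a list of ethograms sharing a vocabulary.
#' @export
setMethod("marginalProbability", "list", function(x, ...) {
  stopifnot(length(x) > 0L, all(vapply(x, is, logical(1), "Ethogram")))
  vocab <- x[[1L]]@vocabulary
  for (e in x)
    if (!identical(e@vocabulary, vocab))
      stop("all ethograms in a cohort must share a vocabulary")
  per <- vapply(x, marginalProbability, numeric(length(vocab)))
  rowMeans(per)
})

#' First-order transition probabilities between behaviors
#'
#' Counts transitions between consecutive bouts (the default) or consecutive
#' raw timesteps, and normalises each row by its total outgoing transitions,
#' so the probability of going from behavior i to all other behaviors sums
#' to 1. Under the bout convention self-transitions are impossible and the
#' count diagonal is identically zero. Rows with no outgoing transitions are
#' left all-zero and flagged, never renormalised. \code{minDisplay} is a
#' display threshold carried along for graph export
#' ([writeTransitionGraph()]); it does not alter the matrix.
#'
#' @param ethogram an \linkS4class{Ethogram}.
#' @param minDisplay display threshold stored on the result (default 0).
#' @param unit \code{"bout"} (default) or \code{"timestep"}.
#' @return a \linkS4class{TransitionMatrix}.
#' @examples
#' tm <- transitionProbabilities(Ethogram(c("A", "B", "A", "C")))
#' transitionProbs(tm)["A", ]
#' @export
transitionProbabilities <- function(ethogram, minDisplay = 0,
                                    unit = c("bout", "timestep")) {
  stopifnot(is(ethogram, "Ethogram"))
  unit <- match.arg(unit)
  seqs <- if (unit == "bout") findBouts(ethogram)$label else ethogram@labels
  if (length(seqs) < 2L)
    stop("need at least 2 ", unit, "s to count transitions")
  vocab <- ethogram@vocabulary
  f <- factor(seqs, levels = vocab)
  counts <- table(from = f[-length(f)], to = f[-1L])
  counts <- matrix(as.integer(counts), nrow = length(vocab),
                   dimnames = list(vocab, vocab))
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  new("TransitionMatrix", labels = vocab, counts = counts,
      probabilities = probs, emptyRows = rs == 0,
      minDisplay = minDisplay)
}

#' Change from control
#'
#' Elementwise experimental minus control for a pair of per-label metric
#' tables (bout frequencies, time fractions, ...). Positive values mean an
#' increase over control. The two tables must cover the same labels.
#'
#' @param experimental,control named numeric vectors over matching label
#'   vocabularies.
#' @return named numeric vector of differences, in the experimental table's
#'   label order.
#' @examples
#' changeFromControl(c(A = 5, B = 1), c(B = 2, A = 3))
#' @export
changeFromControl <- function(experimental, control) {
  if (is.null(names(experimental)) || is.null(names(control)) ||
      !setequal(names(experimental), names(control)) ||
      length(experimental) != length(control))
    stop("experimental and control must cover the same labels")
  experimental - control[names(experimental)]
}
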