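#' @include AllClasses.R
NULL

#' Construct a binary dust image
#'
#' @param pixels binary matrix (1 = dust, 0 = clean).
#' @param bodyPart,subjectId,timeMin sample annotation.
#' @return a \linkS4class{DustImage}.
#' @export
DustImage <- function(pixels, bodyPart = "body_part", subjectId = "subject",
                      timeMin = 0) {
  storage.mode(pixels) <- "integer"
  new("DustImage", pixels = pixels, bodyPart = bodyPart,
      subjectId = subjectId, timeMin = timeMin)
}

#' Construct a region mask
#'
#' @param pixels binary matrix; 1 marks region membership.
#' @param regionName region label.
#' @return a \linkS4class{RegionMask}.
#' @export
RegionMask <- function(pixels, regionName = "region") {
  storage.mode(pixels) <- "integer"
  new("RegionMask", pixels = pixels, regionName = regionName)
}

#' Binarize a raw intensity image into a dust image
#'
#' Replaces the manual colour-range isolation of raw photographs: a pixel is
#' dust-positive when the chosen channel exceeds \code{cutoff}. Deterministic,
#' and idempotent on already-binary input for any cutoff in (0, 1).
#'
#' @param raw numeric matrix (single channel) or 3-d array (rows x cols x
#'   channels).
#' @param cutoff dust-positive threshold on the channel intensity.
#' @param channel channel index used when \code{raw} has three dimensions.
#' @param ... annotation passed to [DustImage()].
#' @return a \linkS4class{DustImage}.
#' @examples
#' binarize(matrix(c(0, 0.2, 0.9, 1), 2), cutoff = 0.5)
#' @export
binarize <- function(raw, cutoff = 0.5, channel = 1L, ...) {
  if (length(dim(raw)) == 3L) raw <- raw[, , channel]
  if (length(dim(raw)) != 2L) stop("raw must be a matrix or 3-d array")
  if (anyNA(raw)) stop("raw image contains NA")
  DustImage((raw > cutoff) * 1L, ...)
}

#' Average projection of a dust-image stack (groomogram)
#'
#' Per-pixel mean of the binary images across subjects: each value of the
#' resulting map is the fraction of subjects with dust at that pixel
#' coordinate. All images must share dimensions and body part (stacks are
#' assumed pre-registered; no resampling is performed).
#'
#' @param stack nonempty list of \linkS4class{DustImage} objects.
#' @return a \linkS4class{DustMap}.
#' @examples
#' a <- DustImage(matrix(c(1L, 0L, 0L, 0L), 2))
#' b <- DustImage(matrix(c(1L, 1L, 0L, 0L), 2))
#' averageProjection(list(a, b))
#' @export
averageProjection <- function(stack) {
  if (!length(stack)) stop("stack must contain at least one image")
  stopifnot(all(vapply(stack, is, logical(1), "DustImage")))
  dims <- dim(stack[[1L]]@pixels)
  part <- stack[[1L]]@bodyPart
  for (img in stack) {
    if (!all(dim(img@pixels) == dims))
      stop("all images in a stack must share dimensions")
    if (!identical(img@bodyPart, part))
      stop("all images in a stack must share a body part")
  }
  acc <- Reduce(`+`, lapply(stack, function(img) img@pixels))
  new("DustMap", fractions = acc / length(stack),
      nSubjects = length(stack))
}

#' Fraction of dust pixels within a masked region
#'
#' Number of dust-positive pixels inside the mask divided by the total number
#' of pixels the mask contains.
#'
#' @param image a \linkS4class{DustImage}.
#' @param mask a \linkS4class{RegionMask} of identical dimensions.
#' @return fraction in [0, 1].
#' @export
regionDustFraction <- function(image, mask) {
  stopifnot(is(image, "DustImage"), is(mask, "RegionMask"))
  if (!all(dim(image@pixels) == dim(mask@pixels)))
    stop("image and mask dimensions must match")
  inside <- mask@pixels == 1L
  sum(image@pixels[inside]) / sum(inside)
}

#' Normalize a dust-fraction time course
#'
#' Two published normalisations of per-sample region dust fractions:
#' \describe{
#'   \item{zero_time}{each sample's fraction is divided by the mean of the
#'     zero-time-point samples for its body part, so the t = 0 group has mean
#'     exactly 1 by construction.}
#'   \item{max_mean}{fractions are divided by the maximum per-time-point mean
#'     for the body part, so the dirtiest time point normalises to 1.}
#' }
#' Optionally, pairs of regions (e.g. ventral and dorsal abdomen) can be
#' merged after normalisation by averaging their normalized values per
#' subject and time point.
#'
#' @param fractions data.frame with columns \code{subject_id},
#'   \code{body_part}, \code{time_min} and \code{fraction}.
#' @param mode \code{"zero_time"} or \code{"max_mean"}.
#' @param mergeRegions optional named list, e.g.
#'   \code{list(abdomen = c("abdomen_ventral", "abdomen_dorsal"))}.
#' @return the input data.frame with a \code{normalized} column (and merged
#'   body parts when requested).
#' @export
normalizeTimecourse <- function(fractions, mode = c("zero_time", "max_mean"),
                                mergeRegions = NULL) {
  mode <- match.arg(mode)
  need <- c("subject_id", "body_part", "time_min", "fraction")
  if (!all(need %in% names(fractions)))
    stop("fractions must have columns ", paste(need, collapse = ", "))
  out <- fractions
  out$normalized <- NA_real_
  for (bp in unique(out$body_part)) {
    sel <- out$body_part == bp
    denom <- if (mode == "zero_time") {
      t0 <- sel & out$time_min == 0
      if (!any(t0)) stop("no zero-time samples for body part ", bp)
      mean(out$fraction[t0])
    } else {
      means <- tapply(out$fraction[sel], out$time_min[sel], mean)
      max(means)
    }
    if (denom == 0) stop("zero normalisation denominator for body part ", bp)
    out$normalized[sel] <- out$fraction[sel] / denom
  }
  if (!is.null(mergeRegions)) {
    for (nm in names(mergeRegions)) {
      parts <- mergeRegions[[nm]]
      sel <- out$body_part %in% parts
      if (!any(sel)) next
      merged <- stats::aggregate(
        normalized ~ subject_id + time_min, data = out[sel, ], FUN = mean)
      merged$body_part <- nm
      merged$fraction <- NA_real_
      out <- rbind(out[!sel, ],
                   merged[, c("subject_id", "body_part", "time_min",
                              "fraction", "normalized")])
    }
    rownames(out) <- NULL
  }
  out
}
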