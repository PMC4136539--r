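#' @include AllClasses.R
NULL

.sigmoid4p <- function(t, lower, upper, midpoint, slope) {
  lower + (upper - lower) / (1 + exp(slope * (t - midpoint)))
}

#' Fit a dust-clearance curve and extract its half-clearance time (t50)
#'
#' Least-squares fit of either an exponential decay f(t) = f0 * exp(-k t) or
#' a 4-parameter logistic ("sigmoidal": lower and upper asymptotes, midpoint,
#' slope) to a dust-fraction time course. t50 is the time at which the fitted
#' curve crosses half of its fitted value at t = 0 (for the exponential this
#' is the closed form ln(2)/k), i.e. the time it takes to clean fifty percent
#' of the body part. t50 is defined on the fitted curve, not the raw first
#' sample. If the parametric fit fails or has no half-crossing, a model-free
#' fallback linearly interpolates the raw series and a warning is issued.
#'
#' @param times increasing numeric vector of measurement times.
#' @param fractions dust fractions in [0, 1] at those times.
#' @param model \code{"exponential"} or \code{"sigmoidal"}.
#' @return a \linkS4class{DecayFit}.
#' @examples
#' tt <- 0:7
#' fitT50(tt, exp(-log(2) * tt))  # t50 = 1
#' @export
fitT50 <- function(times, fractions, model = c("exponential", "sigmoidal")) {
  model <- match.arg(model)
  if (length(times) < 4L) stop("need at least 4 time points")
  if (length(times) != length(fractions)) stop("times and fractions differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  if (fractions[length(fractions)] > fractions[1L])
    warning("series ends above its starting value; data may not be decay-like")

  df <- data.frame(t = times, f = fractions)
  fit <- NULL
  if (model == "exponential") {
    pos <- df$f > 0
    k0 <- if (sum(pos) >= 2) {
      sl <- stats::coef(stats::lm(log(f) ~ t, data = df[pos, ]))[2L]
      max(-as.numeric(sl), 1e-6)
    } else 1
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ f0 * exp(-k * t), data = df,
                        start = list(f0 = max(df$f), k = k0),
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      return(new("DecayFit", model = "exponential",
                 parameters = c(f0 = unname(p["f0"]), k = unname(p["k"])),
                 t50 = log(2) / unname(p["k"]), converged = TRUE))
    }
  } else {
    rng <- range(df$f)
    m0 <- stats::approx(df$f, df$t, xout = mean(rng), ties = "ordered")$y
    if (is.na(m0)) m0 <- stats::median(df$t)
    fit <- tryCatch(
      minpack.lm::nlsLM(f ~ .sigmoid4p(t, lower, upper, midpoint, slope),
                        data = df,
                        start = list(lower = rng[1L], upper = rng[2L],
                                     midpoint = m0,
                                     slope = 4 / max(diff(range(df$t)), 1e-6) * 5),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      f0 <- .sigmoid4p(0, p["lower"], p["upper"], p["midpoint"], p["slope"])
      y <- f0 / 2
      # closed-form crossing of the fitted logistic with f0/2
      ratio <- (p["upper"] - p["lower"]) / (y - p["lower"])
      if (is.finite(ratio) && ratio > 1) {
        t50v <- unname(p["midpoint"] + log(ratio - 1) / p["slope"])
        if (is.finite(t50v) && t50v > 0)
          return(new("DecayFit", model = "sigmoidal",
                     parameters = c(lower = unname(p["lower"]),
                                    upper = unname(p["upper"]),
                                    midpoint = unname(p["midpoint"]),
                                    slope = unname(p["slope"])),
                     t50 = t50v, converged = TRUE))
      }
    }
  }

  # model-free fallback: first linear-interpolated crossing of half the
  # initial raw value
  warning("parametric fit failed; using linear-interpolation fallback")
  half <- fractions[1L] / 2
  below <- which(fractions <= half)
  if (!length(below)) stop("series never reaches half its initial value")
  j <- below[1L]
  t50v <- if (j == 1L) times[1L] else
    times[j - 1L] + (fractions[j - 1L] - half) /
      (fractions[j - 1L] - fractions[j]) * (times[j] - times[j - 1L])
  if (t50v <= 0) t50v <- min(times[times > 0], na.rm = TRUE)
  new("DecayFit", model = "interpolation",
      parameters = c(half = half), t50 = t50v, converged = FALSE)
}

#' Evaluate a fitted decay curve
#'
#' @param fit a \linkS4class{DecayFit} from [fitT50()].
#' @param times numeric vector of times.
#' @return fitted dust fractions (NA for the interpolation fallback, which
#'   has no parametric curve).
#' @export
predictDecay <- function(fit, times) {
  stopifnot(is(fit, "DecayFit"))
  p <- fit@parameters
  switch(fit@model,
    exponential = p["f0"] * exp(-p["k"] * times),
    sigmoidal = .sigmoid4p(times, p["lower"], p["upper"], p["midpoint"], p["slope"]),
    rep(NA_real_, length(times)))
}
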