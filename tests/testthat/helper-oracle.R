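# Independent straight-line oracle for one simulator iteration.
# Deliberately written with explicit loops and scalar arithmetic, sharing no
# code with the package, so it can serve as a cross-check of simulateGrooming.

oracleStep <- function(d, aPrev, dl, cfg) {
  n <- cfg@nModules
  a <- numeric(n)
  for (j in seq_len(n)) {
    if (cfg@mode == "flat") {
      a[j] <- d[j]
    } else if (cfg@mode == "sgm") {
      a[j] <- d[j] * cfg@sensoryWeights[j]
    } else if (cfg@uimRecurrence == "stateless") {
      s <- 0
      if (j > 1) for (k in 1:(j - 1)) s <- s + d[k]
      a[j] <- d[j] + cfg@inhibitionWeight * s
    } else {
      s <- 0
      if (j > 1) for (k in 1:(j - 1)) s <- s + aPrev[k]
      a[j] <- aPrev[j] + cfg@inhibitionWeight * s
    }
  }
  winner <- NULL
  if (cfg@legsEnabled) {
    if (dl[1] >= cfg@legThreshold && dl[1] > max(a) && dl[1] > dl[2])
      winner <- "front_leg_rub"
    else if (dl[2] >= cfg@legThreshold && dl[2] > max(a) && dl[2] > dl[1])
      winner <- "hind_leg_rub"
  }
  if (is.null(winner)) {
    ma <- 1L
    for (j in seq_len(n)) if (a[j] > a[ma]) ma <- j
    winner <- cfg@moduleLabels[ma]
    if (!(ma %in% cfg@clampedModules)) {
      d[ma] <- d[ma] - cfg@dustRemoval
      if (d[ma] < 0) d[ma] <- 0
    }
    for (c in cfg@clampedModules) d[c] <- cfg@clampValue
    if (cfg@legsEnabled) {
      p <- if (ma <= cfg@anteriorBoundary) 1L else 2L
      dl[p] <- dl[p] + cfg@legIncrement
    }
  } else {
    p <- if (winner == "front_leg_rub") 1L else 2L
    dl[p] <- dl[p] - cfg@legDustRemoval
    if (dl[p] < 0) dl[p] <- 0
  }
  list(d = d, a = a, dl = dl, label = winner)
}

# Full-run oracle starting from given initial state.
oracleRun <- function(cfg, d0, dl0 = c(0, 0)) {
  d <- d0
  d[cfg@clampedModules] <- cfg@clampValue
  dl <- dl0
  aPrev <- d
  labs <- character(cfg@nIterations)
  dust <- matrix(NA_real_, cfg@nIterations, cfg@nModules)
  act <- dust
  leg <- matrix(NA_real_, cfg@nIterations, 2)
  for (i in seq_len(cfg@nIterations)) {
    st <- oracleStep(d, aPrev, dl, cfg)
    d <- st$d; dl <- st$dl; aPrev <- st$a
    labs[i] <- st$label
    dust[i, ] <- d; act[i, ] <- st$a; leg[i, ] <- dl
  }
  list(labels = labs, dust = dust, activation = act, leg = leg)
}

# Random small configurations for property tests.
randomConfig <- function(seed, maxIter = 60L) {
  set.seed(seed)
  mode <- sample(c("flat", "sgm", "uim"), 1)
  n <- sample(2:5, 1)
  clamped <- if (runif(1) < 0.3) sample.int(n, 1) else integer()
  groomConfig(mode, nModules = n,
              dustRemoval = runif(1, 0.02, 0.2),
              dustNoise = sample(c(0, 0.1), 1),
              nIterations = sample(10:maxIter, 1),
              seed = sample.int(1e6, 1),
              clampedModules = clamped,
              uimRecurrence = sample(c("stateless", "literal"), 1),
              legsEnabled = runif(1) < 0.4)
}

# Alternation counts used by the leg-rubbing checks: triples starting at
# module m, then a leg rub, then any body module.
legAlternations <- function(lab, m, bodyLabels) {
  legs <- c("front_leg_rub", "hind_leg_rub")
  i <- which(lab == m)
  i <- i[i <= length(lab) - 2L]
  sum(lab[i + 1L] %in% legs & lab[i + 2L] %in% bodyLabels)
}
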