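# Property-style checks of the simulator over randomly generated
# configurations and seeds.

test_that("dust is conserved: final = max(initial - dr * unclamped wins, 0)", {
  for (i in 1:60) {
    cfg <- randomConfig(i)
    s <- simulateGrooming(cfg)
    wins <- table(factor(labels(ethogram(s)), levels = cfg@moduleLabels))
    fin <- finalDust(s)
    for (k in seq_len(cfg@nModules)) {
      if (k %in% cfg@clampedModules) {
        expect_equal(unname(fin[k]), cfg@clampValue)
      } else {
        expect_equal(unname(fin[k]),
                     max(s@initialDust[k] - cfg@dustRemoval * wins[k], 0),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("unclamped dust is monotonically nonincreasing and never negative", {
  for (i in 1:20) {
    cfg <- randomConfig(i + 500)
    s <- simulateGrooming(cfg)
    traj <- rbind(s@initialDust, dustTrajectory(s))
    expect_true(all(traj >= 0))
    unclamped <- setdiff(seq_len(cfg@nModules), cfg@clampedModules)
    expect_true(all(apply(traj[, unclamped, drop = FALSE], 2,
                          function(x) all(diff(x) <= 1e-12))))
  }
})

test_that("the simulator agrees with an independent straight-line oracle", {
  for (i in 1:100) {
    cfg <- randomConfig(i + 1000, maxIter = 30L)
    s <- simulateGrooming(cfg)
    o <- oracleRun(cfg, s@initialDust,
                   if (cfg@legsEnabled) s@initialLegDust else c(0, 0))
    expect_identical(labels(ethogram(s)), o$labels)
    expect_equal(unname(dustTrajectory(s)), o$dust, tolerance = 1e-12)
    expect_equal(unname(activationTrajectory(s)), o$activation,
                 tolerance = 1e-12)
    if (cfg@legsEnabled)
      expect_equal(unname(legTrajectory(s)), o$leg, tolerance = 1e-12)
  }
})

test_that("hierarchy variants select each module for the first time in index order", {
  for (mode in c("sgm", "uim")) {
    for (sd in 1:20) {
      s <- simulateGrooming(groomConfig(mode, nIterations = 150L, seed = sd))
      expect_false(is.unsorted(firstSelection(s), strictly = TRUE))
    }
  }
})

test_that("the flat model is permutation-equivariant in the initial dust", {
  cfg <- groomConfig("flat", nIterations = 40L, seed = 5,
                     moduleLabels = paste0("m", 1:5))
  d0 <- withr::with_seed(5, 0.9 + runif(5, 0, 0.1))
  base <- labels(ethogram(simulateGrooming(cfg, initialDust = d0)))
  for (sd in 1:5) {
    perm <- withr::with_seed(sd, sample(5))
    permuted <- labels(ethogram(simulateGrooming(cfg, initialDust = d0[perm])))
    # module i of the permuted run carries module perm[i]'s dust, so its
    # ethogram must be the base ethogram relabelled through perm
    mapped <- paste0("m", perm[match(permuted, cfg@moduleLabels)])
    expect_identical(mapped, base)
  }
})

test_that("first winners in the flat model are uniform across modules over seeds", {
  first <- vapply(1:100, function(sd) {
    labels(ethogram(simulateGrooming(
      groomConfig("flat", nIterations = 1L, seed = sd))))[1]
  }, character(1))
  tab <- table(factor(first, levels = groomConfig("flat")@moduleLabels))
  expect_true(all(tab > 0))
  expect_lt(max(tab) / 100, 0.4)
})

test_that("constitutive suppression: no module below the clamp is ever selected", {
  for (m in 2:4) {
    cfg <- groomConfig("uim", clampedModules = m, nIterations = 200L, seed = m)
    lab <- labels(ethogram(simulateGrooming(cfg)))
    inferior <- cfg@moduleLabels[seq(m + 1, 5)]
    expect_false(any(lab %in% inferior))
  }
})

test_that("the literal inhibition recurrence freezes the top module's activation", {
  cfg <- groomConfig("uim", uimRecurrence = "literal", nIterations = 60L,
                     seed = 2)
  s <- simulateGrooming(cfg)
  act <- activationTrajectory(s)
  # dust removal never feeds back into activation, so the top module's
  # activation is constant no matter how much it cleans...
  expect_equal(diff(range(act[, 1])), 0)
  expect_identical(unique(labels(ethogram(s))[1:3]), cfg@moduleLabels[1])
  # ...and repeated multiplication by W diverges polynomially, leaving the
  # dust range entirely: the recurrence cannot sustain a grooming sequence
  expect_gt(max(abs(act)), 10)
})

test_that("leg rubbing interleaves with body cleaning without disturbing the body order", {
  cfg <- scenarioConfigs()$legRubbing
  s <- simulateGrooming(cfg)
  lab <- labels(ethogram(s))
  expect_false(is.unsorted(firstSelection(s), strictly = TRUE))
  for (m in cfg@moduleLabels)
    expect_gte(legAlternations(lab, m, cfg@moduleLabels), 1)
  # cyclic structure: a body bout is followed by rubbing far more often than
  # by any other body module, and rubbing returns to body cleaning
  tm <- transitionProbs(transitionProbabilities(ethogram(s)))
  legs <- c("front_leg_rub", "hind_leg_rub")
  for (m in cfg@moduleLabels) {
    toLeg <- sum(tm[m, legs])
    toOtherBody <- max(tm[m, setdiff(cfg@moduleLabels, m)])
    expect_gt(toLeg, toOtherBody)
  }
  expect_gt(sum(tm[legs, cfg@moduleLabels]) / 2, 0.9)
})

test_that("the clearance predicate reports when all unclamped dust is gone", {
  cfg <- groomConfig("sgm", nIterations = 200L, seed = 9)
  s <- simulateGrooming(cfg)
  i <- firstClearIteration(s)
  expect_false(is.na(i))
  expect_true(all(dustTrajectory(s)[i, ] <= 1e-12))
  expect_gt(max(dustTrajectory(s)[i - 1, ]), 0)
  short <- simulateGrooming(groomConfig("sgm", nIterations = 10L, seed = 9))
  expect_true(is.na(firstClearIteration(short)))
})
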