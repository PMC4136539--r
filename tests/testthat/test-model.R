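test_that("initial dust is dustBase plus bounded uniform noise, clamp applied", {
  cfg <- groomConfig("flat", dustNoise = 0)
  expect_equal(unname(withr::with_seed(1, initDust(cfg))), rep(0.9, 5))

  cfg <- groomConfig("flat")
  d <- withr::with_seed(42, initDust(cfg))
  expect_true(all(d >= 0.9 & d <= 1.0))
  expect_identical(withr::with_seed(7, initDust(cfg)),
                   withr::with_seed(7, initDust(cfg)))

  cfg <- groomConfig("uim", clampedModules = 2L)
  d <- withr::with_seed(1, initDust(cfg))
  expect_identical(unname(d[2]), 1.0)
})

test_that("sensory-gain activation is the elementwise dust-weight product", {
  expect_equal(activationSGM(c(0.5, 0.5), c(1, 1)), c(0.5, 0.5))
  expect_equal(activationSGM(c(0.9, 0.9, 0.9), c(3, 2, 1)), c(2.7, 1.8, 0.9))
  # equal dust with decreasing weights always favours the top module
  a <- activationSGM(rep(0.95, 5), seq(2, 1, length.out = 5))
  expect_identical(which.max(a), 1L)
  expect_error(activationSGM(c(1, 1), 1), "same length")
})

test_that("unidirectional inhibition subtracts superior modules' dust", {
  W0 <- diag(2)
  expect_equal(activationUIM(c(0.3, 0.7), W0), c(0.3, 0.7))
  cfg <- groomConfig("uim", nModules = 2)
  expect_equal(activationUIM(c(1, 1), weightMatrix(cfg)), c(1, 0.5))
  cfg3 <- groomConfig("uim", nModules = 3)
  expect_equal(activationUIM(c(1, 1, 1), weightMatrix(cfg3)), c(1, 0.5, 0))
  # literal recurrence propagates activation, not dust
  expect_equal(
    activationUIM(c(0, 0, 0), weightMatrix(cfg3),
                  prevActivation = c(1, 1, 1), recurrence = "literal"),
    c(1, 0.5, 0))
  expect_error(activationUIM(c(1, 1), weightMatrix(cfg3)), "length")
})

test_that("winner-take-all picks the maximal module; ties go to the superior one", {
  w <- selectWinner(c(0.3, 0.9, 0.1), moduleLabels = c("m1", "m2", "m3"))
  expect_identical(w$label, "m2")
  expect_identical(w$selection, c(0L, 1L, 0L))

  tie <- selectWinner(c(0.5, 0.5))
  expect_identical(tie$index, 1L)
  expect_error(selectWinner(numeric(0)), "nonempty")
})

test_that("leg pairs win only when above threshold, every body part and each other", {
  a <- rep(0.4, 4)
  w <- selectWinner(a, legActivation = c(0.95, 0.1), legThreshold = 0.8,
                    legsEnabled = TRUE)
  expect_identical(w$label, "front_leg_rub")
  expect_true(w$isLeg)
  expect_identical(w$selection, rep(0L, 4))
  # below threshold: body wins even though legs beat the body activations
  w <- selectWinner(a, legActivation = c(0.7, 0.1), legThreshold = 0.8,
                    legsEnabled = TRUE)
  expect_false(w$isLeg)
  # above threshold but below a body part: body wins
  w <- selectWinner(c(0.99, 0.4), legActivation = c(0.9, 0.1),
                    legThreshold = 0.8, legsEnabled = TRUE)
  expect_false(w$isLeg)
  # must also exceed the other pair
  w <- selectWinner(a, legActivation = c(0.9, 0.9), legThreshold = 0.8,
                    legsEnabled = TRUE)
  expect_false(w$isLeg)
  w <- selectWinner(a, legActivation = c(0.9, 0.95), legThreshold = 0.8,
                    legsEnabled = TRUE)
  expect_identical(w$label, "hind_leg_rub")
})

test_that("dust removal subtracts dr, floors at zero and re-applies clamps", {
  expect_equal(removeDust(c(0.9, 0.9), 1, 0.1), c(0.8, 0.9))
  expect_equal(removeDust(0.05, 1, 0.1), 0)
  expect_equal(removeDust(c(0.5, 1.0), 2, 0.1, clamped = 2L, clampValue = 1),
               c(0.5, 1.0))
  expect_error(removeDust(c(0.5), 2, 0.1), "out of range")
})

test_that("leg dust bookkeeping follows the anterior/posterior assignment", {
  cfg <- groomConfig("uim", nModules = 4, legsEnabled = TRUE)
  expect_equal(updateLegs(c(0, 0), 1, cfg), c(0.05, 0))
  expect_equal(updateLegs(c(0, 0), 3, cfg), c(0.05, 0))
  expect_equal(updateLegs(c(0, 0), 4, cfg), c(0, 0.05))
  expect_equal(updateLegs(c(0.03, 0), "front_leg_rub", cfg), c(0, 0))
  expect_equal(updateLegs(c(0.5, 0.2), "hind_leg_rub", cfg), c(0.5, 0.15))
})

test_that("noise-free flat model cleans in a deterministic round-robin", {
  cfg <- groomConfig("flat", dustNoise = 0, dustRemoval = 0.1,
                     nIterations = 10L, seed = 1)
  lab <- labels(ethogram(simulateGrooming(cfg)))
  expect_identical(lab, rep(cfg@moduleLabels, 2))
})

test_that("simulation is deterministic under a fixed seed and one behavior is emitted per iteration", {
  cfg <- groomConfig("uim", nIterations = 120L, seed = 11, legsEnabled = FALSE)
  s1 <- simulateGrooming(cfg)
  s2 <- simulateGrooming(cfg)
  expect_identical(labels(ethogram(s1)), labels(ethogram(s2)))
  expect_identical(dustTrajectory(s1), dustTrajectory(s2))
  expect_length(labels(ethogram(s1)), 120L)
  expect_true(all(labels(ethogram(s1)) %in% cfg@moduleLabels))
})

test_that("a clamped module with no dust elsewhere is executed exclusively, in every mode", {
  for (mode in c("flat", "sgm", "uim")) {
    cfg <- groomConfig(mode, dustBase = 0, dustNoise = 0, clampedModules = 3L,
                       clampValue = 1, nIterations = 50L, seed = 3)
    lab <- labels(ethogram(simulateGrooming(cfg)))
    expect_identical(unique(lab), cfg@moduleLabels[3])
  }
})

test_that("clamping under full dust and inhibition silences all inferior modules", {
  cfg <- scenarioConfigs()$clampDusty
  s <- simulateGrooming(cfg)
  lab <- labels(ethogram(s))
  expect_false(any(lab %in% cfg@moduleLabels[4:5]))
  # once the superiors stop, the clamped module wins every iteration
  lastSup <- max(which(lab %in% cfg@moduleLabels[1:2]))
  expect_true(all(lab[(lastSup + 1):length(lab)] == cfg@moduleLabels[3]))
})
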