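test_that("binarize thresholds a channel and is idempotent on binary input", {
  raw <- matrix(c(0, 0.2, 0.9, 1), 2)
  img <- binarize(raw, cutoff = 0.5)
  expect_identical(pixels(img), matrix(c(0L, 0L, 1L, 1L), 2))

  expect_identical(pixels(binarize(matrix(0, 3, 3))), matrix(0L, 3, 3))
  bin <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(pixels(binarize(bin, cutoff = 0.3)),
                   pixels(binarize(pixels(binarize(bin, cutoff = 0.3)) * 1,
                                   cutoff = 0.7)))

  arr <- array(0, c(2, 2, 3)); arr[1, 1, 2] <- 0.9
  expect_identical(sum(pixels(binarize(arr, channel = 2))), 1L)
  expect_error(binarize(matrix(NA_real_, 2, 2)), "NA")
})

test_that("average projection equals hand-computed per-pixel fractions", {
  a <- DustImage(matrix(c(1L, 0L, 0L, 0L), 2))
  b <- DustImage(matrix(c(1L, 1L, 0L, 0L), 2))
  c3 <- DustImage(matrix(c(1L, 1L, 1L, 0L), 2))
  m <- averageProjection(list(a, b, c3))
  expect_equal(m@fractions, matrix(c(1, 2 / 3, 1 / 3, 0), 2))
  expect_identical(m@nSubjects, 3L)

  # idempotence and permutation invariance
  expect_equal(averageProjection(list(a, a))@fractions, pixels(a) * 1.0,
               ignore_attr = TRUE)
  expect_equal(averageProjection(list(c3, a, b))@fractions, m@fractions)

  expect_error(averageProjection(list()), "at least one")
  expect_error(averageProjection(list(a, DustImage(matrix(0L, 3, 3)))),
               "dimensions")
})

test_that("a large random stack's mean tracks the planted dust probability", {
  g <- generateDustImageStack(matrix(0.4, 12, 12), nSubjects = 31, seed = 4)
  m <- averageProjection(g$stack)
  se <- sqrt(0.4 * 0.6 / (31 * 144))
  expect_lt(abs(mean(m@fractions) - 0.4), 3 * se)
  expect_true(all(m@fractions >= 0 & m@fractions <= 1))
})

test_that("region dust fractions are exact planted ratios and monotone", {
  px <- matrix(0L, 10, 10)
  px[1:3, ] <- 1L  # 30 of the first 100... restrict with mask below
  img <- DustImage(px)
  mask <- RegionMask(matrix(1L, 10, 10))
  expect_equal(regionDustFraction(img, mask), 0.30)

  expect_equal(regionDustFraction(DustImage(matrix(1L, 4, 4)),
                                  RegionMask(matrix(1L, 4, 4))), 1)
  expect_equal(regionDustFraction(DustImage(matrix(0L, 4, 4)),
                                  RegionMask(matrix(1L, 4, 4))), 0)

  # adding dust pixels never decreases the fraction
  px2 <- px; px2[4, 1:5] <- 1L
  expect_gte(regionDustFraction(DustImage(px2), mask),
             regionDustFraction(img, mask))

  expect_error(regionDustFraction(img, RegionMask(matrix(1L, 3, 3))),
               "dimensions")
  expect_error(RegionMask(matrix(0L, 3, 3)), "at least one")
})

test_that("time-course normalisation matches both published conventions", {
  df <- data.frame(
    subject_id = c("s1", "s2", "s3", "s1", "s2"),
    body_part = "wing",
    time_min = c(0, 0, 5, 5, 10),
    fraction = c(0.8, 1.0, 0.45, 0.45, 0.09))
  z <- normalizeTimecourse(df, "zero_time")
  expect_equal(z$normalized[3], 0.5)  # 0.45 / mean(0.8, 1.0)
  expect_equal(mean(z$normalized[z$time_min == 0]), 1)

  mm <- normalizeTimecourse(df, "max_mean")
  # max per-time mean is the t = 0 mean (0.9), so t = 0 normalises to 1
  expect_equal(mean(mm$normalized[mm$time_min == 0]), 1)
  expect_equal(mm$normalized[5], 0.1)

  df0 <- df; df0$time_min <- df0$time_min + 1
  expect_error(normalizeTimecourse(df0, "zero_time"), "zero-time")
})

test_that("ventral and dorsal abdomen merge by averaging normalized values", {
  df <- data.frame(
    subject_id = rep(c("s1", "s2"), each = 4),
    body_part = rep(c("abdomen_ventral", "abdomen_dorsal"), 4),
    time_min = rep(c(0, 0, 5, 5), 2),
    fraction = c(0.8, 0.4, 0.4, 0.1, 0.8, 0.4, 0.2, 0.3))
  out <- normalizeTimecourse(df, "zero_time",
                             mergeRegions = list(abdomen = c(
                               "abdomen_ventral", "abdomen_dorsal")))
  expect_setequal(unique(out$body_part), "abdomen")
  s1t5 <- out$normalized[out$subject_id == "s1" & out$time_min == 5]
  expect_equal(s1t5, mean(c(0.4 / 0.8, 0.1 / 0.4)))
})
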