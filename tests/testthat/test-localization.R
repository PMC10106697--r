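# Polarity metrics: the centroid of a half-disc sits 4R/(3*pi) ~ 0.42 R from
# the center, which anchors the expected rho of a polar pattern.

test_that("half-disc signal is polar: rho near 0.42, coverage near half", {
  mask <- discMask(8, 0.2, size = 64)
  X <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  ch <- matrix(0, 64, 64)
  ch[mask & X > 34] <- 100          # slightly under one half of the nucleus
  m <- polarityMetrics(ch, mask, 0.2, backgroundMean = 0, backgroundSd = 0.1)
  expect_gte(m$rho, 0.3)
  expect_lte(m$coverage, 0.55)
  expect_equal(m$rho, 4 / (3 * pi), tolerance = 0.1)
  m$level <- 1
  expect_identical(classifyPattern(m), "polar")
})

test_that("uniform signal is whole-nucleus; zero signal is absent", {
  mask <- discMask(8, 0.2, size = 64)
  ch <- matrix(0, 64, 64); ch[mask] <- 100
  m <- polarityMetrics(ch, mask, 0.2, backgroundMean = 0, backgroundSd = 0.1)
  expect_lt(m$rho, 0.05)
  expect_gt(m$coverage, 0.95)
  m$level <- 1
  expect_identical(classifyPattern(m), "whole")

  z <- polarityMetrics(matrix(0, 64, 64), mask, 0.2,
                       backgroundMean = 0, backgroundSd = 0.1)
  expect_identical(z$coverage, 0)
  z$level <- 0
  expect_identical(classifyPattern(z), "absent")
})

test_that("the pattern decision list is first-match and total", {
  m <- function(rho = 0, coverage = 0, punct = 0, level = 1)
    list(rho = rho, coverage = coverage, punctateness = punct, level = level)
  expect_identical(classifyPattern(m(level = 0.01)), "absent")
  expect_identical(classifyPattern(m(coverage = 0.05, punct = 3)), "dots")
  expect_identical(classifyPattern(m(rho = 0.5, coverage = 0.4)), "polar")
  expect_identical(classifyPattern(m(coverage = 0.95)), "whole")
  expect_identical(classifyPattern(m(coverage = 0.7)), "stripe")
  expect_identical(classifyPattern(m(coverage = 0.3, punct = 9)), "punctate")
  expect_identical(classifyPattern(m(coverage = 0.3, punct = 0)), "diffuse")
  ## dots beat polar when both could fire
  expect_identical(classifyPattern(m(rho = 0.5, coverage = 0.05, punct = 2)), "dots")
})

test_that("SPC-I substages follow the joint Sycp3/Pcna rules", {
  s <- function(pattern, coverage = NA, rho = NA)
    list(pattern = pattern, coverage = coverage, rho = rho)
  p <- function(pattern, coverage = NA, level = 1)
    list(pattern = pattern, coverage = coverage, level = level)
  ## leptotene: co-polar on the same side
  expect_identical(stageSpc1(s("polar", 0.4, 0.5), p("polar", 0.4), 20)$subtype, "L")
  ## early zygotene: complementary side
  expect_identical(stageSpc1(s("polar", 0.4, 0.5), p("polar", 0.4), 175)$subtype, "EZ")
  ## mid vs late zygotene by stripe coverage, punctate Pcna
  expect_identical(stageSpc1(s("stripe", 0.55), p("punctate", 0.06, 0.5), NA)$subtype, "MZ")
  expect_identical(stageSpc1(s("stripe", 0.78), p("punctate", 0.04, 0.2), NA)$subtype, "LZ")
  ## near the coverage boundary the decreasing Pcna level decides
  expect_identical(stageSpc1(s("stripe", 0.64), p("punctate", 0.05, 0.55), NA)$subtype, "MZ")
  expect_identical(stageSpc1(s("stripe", 0.66), p("punctate", 0.05, 0.2), NA)$subtype, "LZ")
  ## pachytene: whole-nucleus Sycp3, Pcna gone
  expect_identical(stageSpc1(s("whole", 0.98), p("absent", 0, 0))$subtype, "P")
  ## non-meiotic Sycp3 is not an SPC-I
  expect_error(stageSpc1(s("dots", 0.05), p("high", 1)), class = "notSpc1Error")
})

test_that("rendered SPC-I stages are staged perfectly without noise", {
  plan <- data.frame(
    label = c("SPC-I(L)", "SPC-I(EZ)", "SPC-I(MZ)", "SPC-I(LZ)", "SPC-I(P)",
              rep("SPG-A(2,4,8-cell)", 3)),
    size = c(rep(8L, 5), rep(8L, 3)))
  cfg <- sceneConfig(plan, imageSize = c(1280L, 1280L), noiseSd = 0, seed = 43)
  sc <- generateScene(cfg, defaultProfilesFixture())
  res <- runPipeline(sc)
  mt <- matchTruth(res$features, sceneTruth(sc))
  tlab <- sceneTruth(sc)$label[mt$truth_id]
  spc <- grepl("SPC-I", tlab)
  expect_identical(res$calls$label[spc], tlab[spc])
})
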