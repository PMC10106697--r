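# The clay-ball model: packed-sphere cysts and their largest planar section.

test_that("degenerate packings are exact", {
  c1 <- packCyst(1)
  expect_identical(nCells(c1), 1L)
  expect_identical(cystCenters(c1), matrix(0, 1, 3))
  expect_identical(ballRadius(c1), 0.5)
  expect_identical(largestSectionCount(c1)$count, 1L)

  ## kissing pair: centers exactly one diameter apart
  c2 <- packCyst(2, seed = 4)
  expect_equal(as.numeric(dist(cystCenters(c2))), 1, tolerance = 1e-9)
  expect_identical(largestSectionCount(c2)$count, 2L)

  ## units scale linearly with the cell diameter
  c2b <- packCyst(2, cellDiameter = 3.5, seed = 4)
  expect_equal(as.numeric(dist(cystCenters(c2b))), 3.5, tolerance = 1e-6)
})

test_that("the cyst ball tracks the nominal minimal radius", {
  cy <- packCyst(32, seed = 6)
  nominal <- (32 / 0.6)^(1/3) / 2 * 1.02
  ## random compression jams slightly before the nominal density, so the
  ## achieved radius sits at, or a little above, the nominal minimal ball
  expect_gte(ballRadius(cy), nominal - 1e-9)
  expect_lt(ballRadius(cy), 1.15 * nominal)
  ## hard-core and containment hold (also enforced by the class validity)
  expect_gte(min(dist(cystCenters(cy))), 1 - 1e-6)
  expect_lte(max(sqrt(rowSums(cystCenters(cy)^2))), ballRadius(cy) - 0.5 + 1e-6)
  expect_error(packCyst(16, packingFraction = 0.8),
               class = "infeasiblePackingError")
})

test_that("packing is deterministic given the seed", {
  expect_identical(cystCenters(packCyst(16, seed = 11)),
                   cystCenters(packCyst(16, seed = 11)))
  expect_false(identical(cystCenters(packCyst(16, seed = 11)),
                         cystCenters(packCyst(16, seed = 12))))
})

test_that("a co-planar arrangement is counted whole", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  centers <- cbind(3 * cos(th), 3 * sin(th), 0)
  cy <- new("Cyst3D", nCells = 8L, cellDiameter = 1, centers = centers,
            ballRadius = 4, packingFraction = 0.6)
  expect_identical(largestSectionCount(cy)$count, 8L)
})

test_that("section counts are bounded and increase with the cyst generation", {
  set.seed(1)
  means <- vapply(c(2, 4, 8, 16, 32, 64, 128, 256), function(n) {
    counts <- simulateSectionCounts(n, reps = 12, seed = 100 + n)
    expect_true(all(counts >= 1 & counts <= n))
    mean(counts)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("the analytic slab expectation matches independent numeric integration", {
  ## independent oracle: integrate the slab cross-section numerically
  numOracle <- function(n, phi, d = 1) {
    R <- (n / phi)^(1/3) * d / 2
    e <- n * integrate(function(z) pi * (R^2 - z^2), -d/2, d/2)$value /
      (4 / 3 * pi * R^3)
    min(max(e, 1), n)
  }
  expect_identical(expectedSectionCount(1), 1)
  for (n in c(4, 16, 32, 256))
    for (phi in c(0.5, 0.6, 0.64))
      expect_equal(expectedSectionCount(n, phi), numOracle(n, phi), tolerance = 1e-6)
  expect_equal(expectedSectionCount(32, 0.64), 12.7, tolerance = 0.05)
  expect_equal(expectedSectionCount(256, 0.64), 51.8, tolerance = 0.1)
})

test_that("simulated sections exceed the uniform-slab expectation by a decaying margin", {
  ## packed cysts confine centers inside the ball and layer them against the
  ## wall, so central sections catch more cells than the uniform-density
  ## expectation; the excess shrinks as the cyst grows
  ratios <- vapply(c(16, 64, 256), function(n) {
    mean(simulateSectionCounts(n, reps = 25, seed = 300 + n)) /
      expectedSectionCount(n)
  }, 0)
  expect_true(all(ratios > 1))
  expect_true(all(ratios < 1.3))
  expect_true(ratios[3] < ratios[1])
})

test_that("generation inference maps the published anchors to 32 and 256 cells", {
  g3 <- inferGeneration(14.3)
  expect_identical(g3$nearest_n, 32L)
  expect_identical(g3$label, "SPG-B(16,32-cell)")
  g4 <- inferGeneration(54.9)
  expect_identical(g4$nearest_n, 256L)
  expect_identical(g4$label, "SPG-B(64,128,256-cell)")
  g1 <- inferGeneration(1)
  expect_identical(g1$nearest_n, 1L)
  expect_identical(g1$label, "SPG-A(1-cell)")
})

test_that("inference round-trips the simulated means", {
  for (n in c(16L, 32L, 64L, 128L, 256L)) {
    m <- mean(simulateSectionCounts(n, reps = 25, seed = 500 + n))
    expect_identical(inferGeneration(m)$nearest_n, n)
  }
})

test_that("compareGroups is the classical pooled-variance t-test", {
  ## identical samples
  r <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r$t, 0)
  expect_identical(r$p, 1)
  expect_false(r$significant)

  ## hand-computed pooled formula for {1,2,3} vs {1,2,3,4}
  a <- c(1, 2, 3); b <- c(1, 2, 3, 4)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  tHand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  pHand <- 2 * pt(-abs(tHand), df = length(a) + length(b) - 2)
  r <- compareGroups(a, b)
  expect_equal(r$t, tHand, tolerance = 1e-12)
  expect_equal(r$p, pHand, tolerance = 1e-12)
  expect_identical(r$df, 5)

  ## zero-variance conventions
  expect_identical(compareGroups(c(2, 2), c(3, 3))$p, 0)
  expect_identical(compareGroups(c(2, 2), c(2, 2))$p, 1)
})
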