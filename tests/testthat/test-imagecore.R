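test_that("non-touching nuclei segment to one label each", {
  cfg <- sceneConfig(data.frame(label = rep("SPG-A(1-cell)", 20), size = 1L),
                     imageSize = c(1024L, 1024L), channels = "DAPI",
                     noiseSd = 0, seed = 3)
  sc <- generateScene(cfg, defaultProfilesFixture())
  lab <- segmentNuclei(sceneChannels(sc)[, , "DAPI"], 0.2)
  expect_identical(nucleusCount(lab), 20L)
})

test_that("watershed splits two overlapping discs", {
  ## two discs of diameter 6 um with centers 0.9 diameters apart
  ps <- 0.2
  img <- matrix(0, 128, 128)
  for (ctr in list(c(40, 50), c(40 + 0.9 * 30, 50))) {
    X <- matrix(seq_len(128), 128, 128, byrow = TRUE)
    Y <- t(X)
    img[(X - ctr[1])^2 + (Y - ctr[2])^2 <= 15^2] <- 100
  }
  lab <- segmentNuclei(img, ps)
  expect_identical(nucleusCount(lab), 2L)
})

test_that("blank and degenerate images give empty label maps", {
  expect_identical(nucleusCount(segmentNuclei(matrix(0, 64, 64), 0.2)), 0L)
  expect_identical(nucleusCount(segmentNuclei(matrix(7, 64, 64), 0.2)), 0L)
  expect_error(segmentNuclei(matrix(NaN, 8, 8), 0.2), "non-finite")
})

test_that("regions below the minimum area are discarded", {
  img <- matrix(0, 64, 64)
  img[30:31, 30:31] <- 100          # 4 px = 0.16 um2 at 0.2 um/px
  img[10:20, 10:20] <- 100          # 121 px = 4.8 um2
  lab <- segmentNuclei(img, 0.2, minArea = 2)
  expect_identical(nucleusCount(lab), 1L)
})

test_that("single-linkage chaining groups cysts by chained proximity", {
  ## chain of 3 points, 5 um apart, link 6 -> one cyst
  g <- groupCysts(rbind(c(0, 0), c(5, 0), c(10, 0)), linkDistance = 6)
  expect_identical(g$cyst_id, c(1L, 1L, 1L))
  ## two points 20 um apart -> singletons
  g2 <- groupCysts(rbind(c(0, 0), c(20, 0)), linkDistance = 6)
  expect_identical(g2$cyst_id, c(1L, 2L))
})

test_that("grouping is permutation invariant and coarsens monotonically", {
  set.seed(42)
  pts <- matrix(runif(60, 0, 100), ncol = 2)
  partitionOf <- function(ids) unname(split(seq_along(ids), ids))
  g <- groupCysts(pts, 12)
  perm <- sample(nrow(pts))
  gp <- groupCysts(pts[perm, ], 12)
  ## same partition after permuting input order
  back <- integer(nrow(pts)); back[perm] <- gp$cyst_id
  expect_true(setequal(lapply(partitionOf(g$cyst_id), sort),
                       lapply(partitionOf(back), sort)))
  ## increasing the link distance never increases the cyst count
  counts <- vapply(c(2, 5, 10, 20, 40, 80),
                   function(h) max(groupCysts(pts, h)$cyst_id), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("segmentation matches truth nuclei with recall and precision >= 0.98", {
  cfg <- sceneConfig(data.frame(label = rep("SPG-A(1-cell)", 30), size = 1L),
                     imageSize = c(1280L, 1280L), channels = "DAPI",
                     noiseSd = 5, seed = 17)
  sc <- generateScene(cfg, defaultProfilesFixture())
  lab <- segmentNuclei(sceneChannels(sc)[, , "DAPI"], 0.2)
  rec <- measureNuclei(lab, sceneChannels(sc))
  mt <- matchTruth(rec, sceneTruth(sc))
  tp <- sum(!is.na(mt$truth_id))
  expect_gte(tp / nrow(sceneTruth(sc)), 0.98)   # recall
  expect_gte(tp / nrow(rec), 0.98)              # precision
})

test_that("cyst assignment recovers the generator's cyst plan", {
  sc <- smallScene(label = c("SPG-A(2,4,8-cell)", "SPZ", "SPC-II"),
                   sizes = c(8L, 16L, 16L), imageSize = c(768L, 768L), seed = 23)
  rec <- measuredRecords(sc)
  mt <- matchTruth(rec, sceneTruth(sc))
  truthCyst <- sceneTruth(sc)$cyst_id[mt$truth_id]
  ok <- !is.na(truthCyst)
  ## the recovered partition must equal the planned partition
  tab <- table(found = rec$cyst_id[ok], planned = truthCyst[ok])
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})
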