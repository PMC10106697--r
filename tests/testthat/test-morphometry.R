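# The diameter convention is perimeter / pi, measured on a sub-pixel contour.

test_that("diameter is the perimeter over pi, not an area-equivalent", {
  ## a square of side s has perimeter 4s, so diameter must be 4s/pi --
  ## clearly distinct from the area-equivalent 2s/sqrt(pi)
  s_px <- 40; ps <- 0.2; s_um <- s_px * ps
  lab <- matrix(0L, 96, 96); lab[21:(20 + s_px), 21:(20 + s_px)] <- 1L
  dapi <- matrix(5, 96, 96); dapi[lab == 1L] <- 100
  rec <- measureNuclei(new("NucleusLabelMap", labels = lab, pixelSize = ps),
                       array(dapi, c(96, 96, 1), dimnames = list(NULL, NULL, "DAPI")))
  expect_equal(rec$diameter_um, 4 * s_um / pi, tolerance = 0.03 * 4 * s_um / pi)
  expect_identical(rec$diameter_um, rec$perimeter_um / pi)
})

test_that("an ideal disc of diameter 6.47 um is measured within 2%", {
  ps <- 0.2
  mask <- discMask(6.47, ps, size = 96)
  lab <- matrix(0L, 96, 96); lab[mask] <- 1L
  dapi <- matrix(5, 96, 96); dapi[mask] <- 100
  rec <- measureNuclei(new("NucleusLabelMap", labels = lab, pixelSize = ps),
                       array(dapi, c(96, 96, 1), dimnames = list(NULL, NULL, "DAPI")))
  expect_equal(rec$diameter_um, 6.47, tolerance = 0.02 * 6.47)
})

test_that("diameter bias on ideal discs and ellipses stays within 2%", {
  ps <- 0.2
  set.seed(7)
  for (dUm in c(3.2, 4.3, 6.4)) {       # >= 15 px across
    for (rep in 1:3) {
      q <- runif(1, 1, 1.4); th <- runif(1, 0, pi)
      mask <- discMask(dUm, ps, size = 96, q = q, theta = th)
      lab <- matrix(0L, 96, 96); lab[mask] <- 1L
      dapi <- matrix(5, 96, 96); dapi[mask] <- 100
      rec <- measureNuclei(new("NucleusLabelMap", labels = lab, pixelSize = ps),
                           array(dapi, c(96, 96, 1),
                                 dimnames = list(NULL, NULL, "DAPI")))
      ## truth: perimeter of the ellipse (Ramanujan) over pi
      a <- dUm / 2 * sqrt(q); b <- dUm / 2 / sqrt(q)
      h <- ((a - b) / (a + b))^2
      dTrue <- (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
      expect_equal(rec$diameter_um, dTrue, tolerance = 0.02 * dTrue)
    }
  }
})

test_that("nucleoli are counted as interior DAPI-dark blobs", {
  ps <- 0.2
  mask <- discMask(6, ps, size = 80)
  dapi <- matrix(5, 80, 80); dapi[mask] <- 100
  ## uniform disc: no nucleoli
  expect_identical(countNucleoli(dapi, mask, ps), 0L)
  ## punch three dark holes of ~0.9 um
  holes <- list(c(34, 34), c(46, 40), c(38, 48))
  X <- matrix(seq_len(80), 80, 80, byrow = TRUE); Y <- t(X)
  d3 <- dapi
  for (h in holes) d3[(X - h[1])^2 + (Y - h[2])^2 <= 2.3^2] <- 30
  expect_identical(countNucleoli(d3, mask, ps), 3L)
  ## a hole touching the boundary does not count
  d1 <- dapi
  d1[(X - 55)^2 + (Y - 40)^2 <= 2.3^2] <- 30   # at the rim
  expect_identical(countNucleoli(d1, mask, ps), 0L)
})

test_that("the reference-class nucleus census is recovered from rendered scenes", {
  ## the reference class renders exactly one large nucleolus per nucleus
  cfg <- sceneConfig(data.frame(label = "SPG-A(2,4,8-cell)", size = 8L),
                     imageSize = c(384L, 384L), channels = "DAPI",
                     noiseSd = 0, seed = 19)
  sc <- generateScene(cfg, defaultProfilesFixture())
  lab <- segmentNuclei(sceneChannels(sc)[, , "DAPI"], 0.2)
  rec <- measureNuclei(lab, sceneChannels(sc))
  expect_true(all(rec$nucleolus_count == 1L))
})

test_that("relative normalization divides by the reference mean", {
  mk <- function(dapi, ddx4) {
    rec <- data.frame(id = seq_along(dapi), cyst_id = 1L, cyst_size = 2L,
                      x_um = 0, y_um = 0, area_um2 = 10, perimeter_um = 10,
                      diameter_um = 10 / pi, nucleolus_count = 0L,
                      dapi_mean = dapi, dapi_rel = NA_real_,
                      ddx4_rel = NA_real_, piwil1_rel = NA_real_,
                      sycp3_rel = NA_real_, pcna_rel = NA_real_,
                      sycp3_pattern = NA_character_, pcna_pattern = NA_character_,
                      sycp3_rho = NA_real_, sycp3_coverage = NA_real_,
                      pcna_rho = NA_real_, pcna_coverage = NA_real_,
                      pcna_punctateness = NA_real_, polar_angle_sep_deg = NA_real_,
                      ddx4_mean = ddx4, piwil1_mean = NA_real_,
                      sycp3_mean = NA_real_, pcna_mean = NA_real_,
                      sycp3_punctateness = NA_real_)
    attr(rec, "background") <- c(DAPI = 0, Ddx4 = 0, Piwil1 = 0, Sycp3 = 0, Pcna = 0)
    rec
  }
  ## reference mean 50, query 112 -> query relative DAPI 2.24
  rec <- applyRelativeNormalization(mk(c(40, 60, 112), c(10, 10, 10)), c(1, 2))
  expect_equal(rec$dapi_rel, c(0.8, 1.2, 2.24))
  ## reference nuclei average exactly 1
  expect_equal(mean(rec$dapi_rel[1:2]), 1)
  ## scale invariance: everything times 10 gives identical rel values
  rec10 <- applyRelativeNormalization(mk(10 * c(40, 60, 112), 10 * c(10, 10, 10)), c(1, 2))
  expect_equal(rec10$dapi_rel, rec$dapi_rel)
  expect_equal(rec10$ddx4_rel, rec$ddx4_rel)
  ## empty reference set signals a classed error
  expect_error(applyRelativeNormalization(mk(1:3 * 10, 1:3), integer()),
               class = "missingReferenceError")
})

test_that("pipeline relative intensities are invariant to global scaling", {
  sc <- smallScene(label = c("SPG-B(16,32-cell)", "SPG-A(2,4,8-cell)"),
                   sizes = c(16L, 8L), imageSize = c(640L, 640L), seed = 29)
  runAt <- function(scale) {
    ch <- sceneChannels(sc) * scale
    lab <- segmentNuclei(ch[, , "DAPI"], 0.2)
    rec <- assignCystsToRecords(measureNuclei(lab, ch))
    rec <- applyRelativeNormalization(rec, selectReferenceNuclei(rec))
    ## order by position: segmentation label order is not part of the contract
    rec <- rec[order(round(rec$x_um), round(rec$y_um)), ]
    rec[, c("dapi_rel", "ddx4_rel", "pcna_rel")]
  }
  expect_equal(runAt(1), runAt(11.7), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("segment-and-measure recovers the generating profile", {
  ## reference-class-only scene: diameter within 3%, self-normalized DAPI = 1
  cfg <- sceneConfig(data.frame(label = "SPG-A(2,4,8-cell)", size = rep(8L, 6)),
                     imageSize = c(1024L, 1024L), noiseSd = 0, seed = 37)
  sc <- generateScene(cfg, defaultProfilesFixture())
  rec <- measuredRecords(sc)
  expect_equal(mean(rec$diameter_um), 5.74, tolerance = 0.03 * 5.74)
  rec <- applyRelativeNormalization(rec, rec$id)
  expect_equal(mean(rec$dapi_rel), 1, tolerance = 1e-9)
  expect_gt(sd(rec$dapi_rel), 0)   # per-nucleus spread is real
})
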