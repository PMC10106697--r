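test_that("identical config and seed give bit-identical scenes", {
  sc1 <- smallScene(seed = 99L)
  sc2 <- smallScene(seed = 99L)
  expect_identical(sceneChannels(sc1), sceneChannels(sc2))
  expect_identical(sceneTruth(sc1), sceneTruth(sc2))
  sc3 <- smallScene(seed = 100L)
  expect_false(identical(sceneChannels(sc1), sceneChannels(sc3)))
})

test_that("an empty plan renders pure background", {
  cfg <- sceneConfig(NULL, imageSize = c(128L, 128L), noiseSd = 0, seed = 1)
  sc <- generateScene(cfg, defaultProfilesFixture())
  expect_identical(nrow(sceneTruth(sc)), 0L)
  expect_true(all(sceneChannels(sc) == 10))
  ## with noise, channels fluctuate around the background level
  cfgN <- sceneConfig(NULL, imageSize = c(128L, 128L), noiseSd = 5, seed = 1)
  scN <- generateScene(cfgN, defaultProfilesFixture())
  expect_equal(mean(sceneChannels(scN)[, , "DAPI"]), 10, tolerance = 0.05)
})

test_that("spermatozoa carry no Ddx4 signal", {
  cfg <- sceneConfig(data.frame(label = "SPZ", size = 100L),
                     imageSize = c(640L, 640L), noiseSd = 0, seed = 5)
  sc <- generateScene(cfg, defaultProfilesFixture())
  expect_identical(nrow(sceneTruth(sc)), 100L)
  ## Ddx4 channel is flat background everywhere, including inside nuclei
  expect_true(all(sceneChannels(sc)[, , "Ddx4"] == 10))
  ## while DAPI clearly is not
  expect_gt(max(sceneChannels(sc)[, , "DAPI"]), 200)
})

test_that("noise-free foreground components match the ground truth census", {
  cfg <- sceneConfig(data.frame(label = rep("SPG-A(1-cell)", 25), size = 1L),
                     imageSize = c(1024L, 1024L), channels = "DAPI",
                     noiseSd = 0, seed = 8)
  sc <- generateScene(cfg, defaultProfilesFixture())
  bin <- sceneChannels(sc)[, , "DAPI"] > 30
  comp <- EBImage::bwlabel(EBImage::Image(bin * 1))
  expect_equal(as.integer(max(comp)), 25L)
  ## mean equivalent (area-based) diameter tracks the profile mean
  areas <- tabulate(EBImage::imageData(comp)[bin])
  dEq <- 2 * sqrt(areas * 0.2^2 / pi)
  expect_equal(mean(dEq), 6.47, tolerance = 0.03 * 6.47)
})

test_that("rendered mask means match the drawn DAPI and marker levels", {
  ## single nucleus, no noise: mask mean must equal the drawn level * base
  cfg <- sceneConfig(data.frame(label = "SPG-B(16,32-cell)", size = 16L),
                     imageSize = c(512L, 512L), noiseSd = 0, seed = 13)
  sc <- generateScene(cfg, defaultProfilesFixture())
  tr <- sceneTruth(sc)
  ch <- sceneChannels(sc)
  for (i in c(1, 8, 16)) {
    px <- round(tr$x_um[i] / 0.2) + 1; py <- round(tr$y_um[i] / 0.2) + 1
    r <- floor(tr$diameter_um[i] / 2 / 0.2 * 0.55)  # interior core
    win <- ch[(py - r):(py + r), (px - r):(px + r), "DAPI"]
    expect_equal(median(win) - 10, tr$dapi_rel[i] * 100, tolerance = 8)
  }
})

test_that("overcrowded plans are rejected with a classed error", {
  cfg <- sceneConfig(data.frame(label = rep("SPG-A(1-cell)", 80), size = 1L),
                     imageSize = c(128L, 128L), seed = 2)
  expect_error(generateScene(cfg, defaultProfilesFixture()),
               class = "overcrowdedSceneError")
})

test_that("plans are validated against the profile set", {
  ps <- defaultProfilesFixture()
  expect_error(generateScene(
    sceneConfig(data.frame(label = "nope", size = 4L)), ps), "not in profile set")
  expect_error(generateScene(
    sceneConfig(data.frame(label = "SPG-A(1-cell)", size = 4L)), ps),
    "not admissible")
})

test_that("scenes survive the TIFF/JSON round trip", {
  sc <- smallScene(sizes = c(4L, 8L), imageSize = c(512L, 512L), seed = 77)
  dir <- withr::local_tempdir()
  writeScene(sc, dir)
  expect_true(all(file.exists(file.path(dir,
    c("scene.tif", "truth.json", "scene_config.yaml")))))
  back <- readScene(dir)
  expect_equal(sceneTruth(back)$label, sceneTruth(sc)$label)
  expect_equal(sceneTruth(back)$x_um, sceneTruth(sc)$x_um, tolerance = 1e-6)
  ## 16-bit quantization: within one count
  expect_lt(max(abs(sceneChannels(back) - pmax(sceneChannels(sc), 0))), 0.51)
  expect_identical(sceneConfigOf(back)@channels, sceneConfigOf(sc)@channels)
})
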