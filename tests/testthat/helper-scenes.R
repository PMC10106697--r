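# Shared fixtures, all generated in code.

defaultProfilesFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeDefaultProfiles()
    cache
  }
})

# Small single-class scene (used by several modules).
smallScene <- function(label = "SPG-A(2,4,8-cell)", sizes = c(4L, 8L),
                       noiseSd = 5, seed = 42L, imageSize = c(384L, 384L),
                       channels = c("DAPI", "Ddx4", "Piwil1", "Sycp3", "Pcna")) {
  cfg <- sceneConfig(data.frame(label = label, size = sizes),
                     imageSize = imageSize, channels = channels,
                     noiseSd = noiseSd, seed = seed)
  generateScene(cfg, defaultProfilesFixture())
}

# Rasterize an ideal ellipse mask (axis ratio q, orientation theta) on a
# pixel grid; independent of the scene generator.
discMask <- function(diameterUm, pixelSize, size = 96L, q = 1, theta = 0) {
  ctr <- (size / 2) * pixelSize
  a <- diameterUm / 2 * sqrt(q); b <- diameterUm / 2 / sqrt(q)
  xs <- ((seq_len(size)) - 1) * pixelSize - ctr
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size)
  U <- X * cos(theta) + Y * sin(theta)
  V <- -X * sin(theta) + Y * cos(theta)
  (U / a)^2 + (V / b)^2 <= 1
}

# Measured records for a scene, segmented and cyst-grouped.
measuredRecords <- function(scene, ...) {
  lab <- segmentNuclei(sceneChannels(scene)[, , "DAPI"],
                       sceneConfigOf(scene)@pixelSize, ...)
  assignCystsToRecords(measureNuclei(lab, sceneChannels(scene)))
}

# Build a one-row normalized feature record from a profile's prototype values.
protoRecord <- function(label, profiles = defaultProfilesFixture()) {
  p <- profileTable(profiles)
  r <- as.list(p[p$label == label, ])
  spc <- grepl("^SPC-I\\(", label)
  cyst <- switch(label,
    "SPG-A(1-cell)" = 1L, "SPG-A(2,4,8-cell)" = 8L,
    "SPG-B(16,32-cell)" = 16L, "SPG-B(64,128,256-cell)" = 40L,
    "SPC-II" = 20L, "SPD" = 30L, "SPZ" = 40L, 12L)
  sycp3Cov <- if (!spc) NA_real_ else switch(r$sycp3_pattern,
    polar = 0.42, stripe = r$sycp3_coverage, whole = 0.98)
  sycp3Rho <- if (!spc) NA_real_ else switch(r$sycp3_pattern,
    polar = 0.5, stripe = 0.38, whole = 0.02)
  pcnaCov <- switch(r$pcna_pattern, polar = 0.42, complementary = 0.42,
                    punctate = 0.06, absent = 0, 0.98)
  pcnaPunct <- if (r$pcna_pattern == "punctate") 9 else 1
  sep <- switch(label, "SPC-I(L)" = 10, "SPC-I(EZ)" = 178, NA_real_)
  measuredPcna <- switch(r$pcna_pattern, polar = "polar",
                         complementary = "polar", punctate = "punctate",
                         absent = "absent", high = "whole", low = "whole")
  rec <- data.frame(
    id = 1L, cyst_id = 1L, cyst_size = cyst, x_um = 0, y_um = 0,
    area_um2 = pi * (r$diameter_mean / 2)^2,
    perimeter_um = pi * r$diameter_mean, diameter_um = r$diameter_mean,
    nucleolus_count = as.integer(round((r$nucleolus_min + r$nucleolus_max) / 2)),
    dapi_mean = r$dapi_rel_mean * 100, dapi_rel = r$dapi_rel_mean,
    ddx4_rel = r$ddx4, piwil1_rel = r$piwil1, sycp3_rel = r$sycp3,
    pcna_rel = r$pcna,
    sycp3_pattern = r$sycp3_pattern, pcna_pattern = measuredPcna,
    sycp3_rho = sycp3Rho, sycp3_coverage = sycp3Cov,
    pcna_rho = NA_real_, pcna_coverage = pcnaCov,
    pcna_punctateness = pcnaPunct, polar_angle_sep_deg = sep,
    ddx4_mean = r$ddx4 * 100, piwil1_mean = r$piwil1 * 100,
    sycp3_mean = r$sycp3 * 100, pcna_mean = r$pcna * 100,
    sycp3_punctateness = if (identical(r$sycp3_pattern, "dots")) 3 else 0,
    stringsAsFactors = FALSE)
  rec
}

# The mixed 12-class scene used by the end-to-end checks.
mixedScenePlan <- function() {
  data.frame(
    label = c(rep("SPG-A(1-cell)", 8), rep("SPG-A(2,4,8-cell)", 4),
              "SPG-B(16,32-cell)", "SPG-B(16,32-cell)", "SPG-B(64,128,256-cell)",
              rep(c("SPC-I(L)", "SPC-I(EZ)", "SPC-I(MZ)", "SPC-I(LZ)", "SPC-I(P)"),
                  each = 2),
              "SPC-II", "SPD", "SPZ"),
    size = c(rep(1L, 8), c(2L, 4L, 8L, 8L), 16L, 32L, 64L, rep(8L, 10),
             16L, 24L, 48L))
}

# Developmental adjacency: acceptable confusions are between neighbouring
# stages or within-type splits.
adjacentLabels <- function(a, b) {
  ord <- c("SPG-A(1-cell)", "SPG-A(2,4,8-cell)", "SPG-B(16,32-cell)",
           "SPG-B(64,128,256-cell)", "SPC-I(L)", "SPC-I(EZ)", "SPC-I(MZ)",
           "SPC-I(LZ)", "SPC-I(P)", "SPC-II", "SPD", "SPZ")
  abs(match(a, ord) - match(b, ord)) <= 1
}
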