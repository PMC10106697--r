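## Synthetic testis-section scenes.
##
## Scenes emulate the statistical structure the downstream analysis assumes:
## clonal cysts of 2^k cells placed without overlap, per-type nuclear
## diameter and DAPI distributions, per-type relative marker levels, and the
## subnuclear Sycp3/Pcna patterns of meiotic prophase. Intensities are in
## arbitrary detector counts with the reference class DAPI plateau at
## .BASE_INTENSITY counts.

.BASE_INTENSITY <- 100
.NUCLEOLUS_DARK <- 0.4   # nucleolus DAPI level relative to the plateau
.SPACING_FACTOR <- 1.30  # member center spacing / mean member diameter
.CYST_GAP_UM    <- 12    # minimal clearance between cyst hulls (um)

#' Configure a synthetic scene
#'
#' @param cystPlan data.frame with columns \code{label} (cell-type label) and
#'   \code{size} (cells in the cyst), one planned cyst per row; or NULL for an
#'   empty scene.
#' @param imageSize height and width in pixels.
#' @param pixelSize micrometres per pixel. The default 0.2 um/px corresponds
#'   to a 63x objective and keeps a 6.5 um nucleus about 32 px across.
#' @param channels ordered channel names, DAPI first.
#' @param noiseSd additive Gaussian noise sd in counts; the default is 5% of
#'   the reference-class nuclear DAPI plateau.
#' @param backgroundLevel flat background in counts.
#' @param illuminationGradient fractional slope of a multiplicative linear
#'   illumination ramp along x, applied identically to every channel.
#' @param seed integer RNG seed.
#' @return a validated \code{\linkS4class{SceneConfig}}.
#' @export
sceneConfig <- function(cystPlan = NULL,
                        imageSize = c(1024L, 1024L),
                        pixelSize = 0.2,
                        channels = c("DAPI", "Ddx4", "Piwil1", "Sycp3", "Pcna"),
                        noiseSd = 0.05 * .BASE_INTENSITY,
                        backgroundLevel = 10,
                        illuminationGradient = 0,
                        seed = 1L) {
  if (is.null(cystPlan))
    cystPlan <- data.frame(label = character(), size = integer())
  new("SceneConfig",
      imageSize = as.integer(imageSize), pixelSize = pixelSize,
      channels = channels, cystPlan = cystPlan,
      noiseSd = noiseSd, backgroundLevel = backgroundLevel,
      illuminationGradient = illuminationGradient, seed = as.integer(seed))
}

#' Render a synthetic multi-channel scene with ground truth
#'
#' Each planned cyst becomes a spatially clustered clone of elliptical nuclei
#' (axis ratio drawn in [1, 1.4]) whose equivalent diameter, DAPI level,
#' marker levels, nucleolus census and Sycp3/Pcna subnuclear pattern are drawn
#' from the label's profile. Marker plateaus are scaled so that the mean
#' intensity over the nucleus mask equals the drawn relative level times the
#' base intensity; DAPI is likewise compensated for the area darkened by
#' nucleoli, so profile means are recovered by mask-mean measurements.
#' Background, the optional multiplicative illumination ramp (applied to
#' signal plus background, identically in every channel) and additive
#' Gaussian noise are applied last. The scene is deterministic given the
#' config seed.
#'
#' @param config a \code{\linkS4class{SceneConfig}}.
#' @param profiles a \code{\linkS4class{ClassProfileSet}}.
#' @return a \code{\linkS4class{SceneBundle}}.
#' @examples
#' cfg <- sceneConfig(data.frame(label = "SPG-A(2,4,8-cell)", size = 8),
#'                    imageSize = c(256L, 256L), seed = 7)
#' sc <- generateScene(cfg, makeDefaultProfiles())
#' nrow(sceneTruth(sc))
#' @export
generateScene <- function(config, profiles) {
  stopifnot(is(config, "SceneConfig"), is(profiles, "ClassProfileSet"))
  plan <- config@cystPlan
  if (nrow(plan)) {
    bad <- setdiff(plan$label, profileLabels(profiles))
    if (length(bad)) stop("cystPlan labels not in profile set: ",
                          paste(bad, collapse = ", "))
    for (i in seq_len(nrow(plan)))
      if (!plan$size[i] %in% cystSizes(profiles, plan$label[i]))
        stop(sprintf("cyst size %d not admissible for %s",
                     plan$size[i], plan$label[i]))
  }
  withSeed(config@seed, .renderScene(config, profiles))
}

.renderScene <- function(config, profiles) {
  H <- config@imageSize[1]; W <- config@imageSize[2]
  ps <- config@pixelSize
  nc <- length(config@channels)
  channels <- array(0, dim = c(H, W, nc), dimnames = list(NULL, NULL, config@channels))

  plan <- config@cystPlan
  truth <- list()
  nucId <- 0L

  ## draw each cyst's member layout first, then place the cysts largest
  ## first (sequential rejection placement packs far better that way)
  cysts <- lapply(seq_len(nrow(plan)), function(ci) {
    lab <- plan$label[ci]
    n <- plan$size[ci]
    prof <- getProfile(profiles, lab)
    diam <- pmax(rnormTrunc(n, prof$diameter_mean, prof$diameter_sd), 0.5)
    layout <- .cystLayout(n, diam)
    rCyst <- if (n > 1) max(sqrt(rowSums(layout^2)) + diam / 2) else diam[1] / 2
    list(label = lab, n = n, prof = prof, diam = diam,
         layout = layout, rCyst = rCyst)
  })
  centers <- vector("list", nrow(plan))
  placed <- list()
  for (ci in order(vapply(cysts, `[[`, 0, "rCyst"), decreasing = TRUE)) {
    ctr <- .placeCyst(cysts[[ci]]$rCyst, placed, H, W, ps)
    if (is.null(ctr))
      stopWithClass("overcrowdedSceneError",
        "could not place cyst %d (%s, %d cells) without overlap: scene overcrowded",
        ci, cysts[[ci]]$label, cysts[[ci]]$n)
    placed[[length(placed) + 1L]] <- c(ctr, cysts[[ci]]$rCyst)
    centers[[ci]] <- ctr
  }

  for (ci in seq_len(nrow(plan))) {
    lab <- cysts[[ci]]$label
    n <- cysts[[ci]]$n
    prof <- cysts[[ci]]$prof
    diam <- cysts[[ci]]$diam
    layout <- cysts[[ci]]$layout
    ctr <- centers[[ci]]

    dapi <- rnormTrunc(n, prof$dapi_rel_mean, prof$dapi_rel_sd)
    dapi <- pmax(dapi, 0.05)

    for (k in seq_len(n)) {
      nucId <- nucId + 1L
      cx <- ctr[1] + layout[k, 1]; cy <- ctr[2] + layout[k, 2]
      nuc <- .drawNucleusParams(prof, diam[k], dapi[k])
      w <- .renderNucleus(config, cx, cy, nuc)
      for (chName in names(w$add))
        channels[w$ii, w$jj, chName] <- channels[w$ii, w$jj, chName] + w$add[[chName]]
      truth[[nucId]] <- data.frame(
        id = nucId, label = lab,
        subtype = .spc1Subtype(lab), cyst_id = ci,
        x_um = cx, y_um = cy, diameter_um = diam[k], dapi_rel = dapi[k],
        polar_angle = nuc$polarAngleDeg, stringsAsFactors = FALSE)
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = integer(), label = character(), subtype = character(),
               cyst_id = integer(), x_um = numeric(), y_um = numeric(),
               diameter_um = numeric(), dapi_rel = numeric(),
               polar_angle = numeric())

  ## background, illumination ramp, noise -- identically structured per channel
  grad <- 1 + config@illuminationGradient *
    (matrix(seq_len(W) - 1, H, W, byrow = TRUE) / (W - 1) - 0.5)
  for (c in seq_len(dim(channels)[3])) {
    img <- (channels[, , c] + config@backgroundLevel) * grad
    if (config@noiseSd > 0)
      img <- img + matrix(rnorm(H * W, 0, config@noiseSd), H, W)
    channels[, , c] <- img
  }

  new("SceneBundle", channels = channels, truth = truth, config = config)
}

.spc1Subtype <- function(label) {
  m <- regmatches(label, regexec("^SPC-I\\((L|EZ|MZ|LZ|P)\\)$", label))[[1]]
  if (length(m)) m[2] else NA_character_
}

## Member positions (um, relative to the cyst center) on a jittered
## golden-angle spiral with hard-core separation between nuclei.
.cystLayout <- function(n, diam) {
  if (n == 1L) return(matrix(0, 1, 2))
  spacing <- .SPACING_FACTOR * mean(diam)
  rot <- runif(1, 0, 2 * pi)
  c0 <- spacing / sqrt(pi)
  repeat {
    k <- seq_len(n)
    r <- c0 * sqrt(k - 0.5)
    phi <- k * 2.39996322972865332 + rot
    xy <- cbind(r * cos(phi), r * sin(phi))
    jit <- matrix(runif(2 * n, -0.04, 0.04) * spacing, n, 2)
    xy2 <- xy + jit
    ## hard-core check against the worst-case ellipse extent (axis ratio 1.4)
    need <- 0.62 * outer(diam, diam, "+")
    D <- as.matrix(stats::dist(xy2))
    ok2 <- all(D[upper.tri(D)] >= need[upper.tri(need)])
    if (ok2) return(xy2)
    D <- as.matrix(stats::dist(xy))
    if (all(D[upper.tri(D)] >= need[upper.tri(need)])) return(xy)
    c0 <- c0 * 1.05
  }
}

## Rejection placement of a cyst center; NULL when the scene is overcrowded.
.placeCyst <- function(rCyst, placed, H, W, ps, attempts = 1000L) {
  fw <- (W - 1) * ps; fh <- (H - 1) * ps
  margin <- rCyst + 1
  if (2 * margin >= min(fw, fh)) return(NULL)
  for (a in seq_len(attempts)) {
    x <- runif(1, margin, fw - margin)
    y <- runif(1, margin, fh - margin)
    ok <- TRUE
    for (p in placed) {
      if (sqrt((x - p[1])^2 + (y - p[2])^2) < rCyst + p[3] + .CYST_GAP_UM) {
        ok <- FALSE; break
      }
    }
    if (ok) return(c(x, y))
  }
  NULL
}

## Draw the per-nucleus generative parameters (shape, markers, pattern).
.drawNucleusParams <- function(prof, diam, dapiRel) {
  q <- runif(1, 1, 1.4)
  theta <- runif(1, 0, pi)
  cv <- 0.08
  lvl <- function(mu) if (mu <= 0) 0 else rnormTrunc(1, mu, cv * mu)
  markers <- c(Ddx4 = lvl(prof$ddx4), Piwil1 = lvl(prof$piwil1),
               Sycp3 = lvl(prof$sycp3), Pcna = lvl(prof$pcna))

  nNucl <- if (prof$nucleolus_max > 0)
    sample(prof$nucleolus_min:prof$nucleolus_max, 1L) else 0L
  nucleoli <- .layoutNucleoli(nNucl, diam, prof$nucleolus_rel_diam)

  alpha <- runif(1, 0, 360)
  stripeCov <- if (!is.na(prof$sycp3_coverage))
    rnormTrunc(1, prof$sycp3_coverage, 0.02, trunc = 1.5) else NA_real_

  polarAngle <- if (prof$sycp3_pattern %in% c("polar", "stripe") ||
                    prof$pcna_pattern %in% c("polar", "complementary"))
    alpha else NA_real_

  list(diam = diam, q = q, theta = theta, dapiRel = dapiRel,
       markers = markers, nucleoli = nucleoli,
       sycp3Pattern = prof$sycp3_pattern, pcnaPattern = prof$pcna_pattern,
       stripeCov = stripeCov, alphaDeg = alpha, polarAngleDeg = polarAngle)
}

## Nucleolus centers (um, nucleus frame) and diameters; kept interior
## (within half the nuclear radius) and mutually separated.
.layoutNucleoli <- function(n, diam, relDiam) {
  if (n == 0L) return(NULL)
  dN <- relDiam * diam
  rmax <- 0.5 * diam / 2
  pts <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    for (a in 1:50) {
      p <- runif(2, -rmax, rmax)
      if (sum(p^2) > rmax^2) next
      if (k > 1 && any(sqrt(rowSums(sweep(pts[seq_len(k - 1), , drop = FALSE],
                                          2, p)^2)) < dN * 1.2)) next
      pts[k, ] <- p; break
    }
    if (anyNA(pts[k, ])) pts[k, ] <- c(0, 0)
  }
  list(centers = pts, diameter = dN)
}

## Render one nucleus; returns the window indices and per-channel intensity
## increments so the caller can apply them in place.
.renderNucleus <- function(config, cx, cy, nuc) {
  ps <- config@pixelSize
  H <- config@imageSize[1]; W <- config@imageSize[2]
  ## nuclear "diameter" is the perimeter/pi convention, so scale the ellipse
  ## axes to make its perimeter exactly pi * diam (Ramanujan approximation)
  a <- (nuc$diam / 2) * sqrt(nuc$q)
  b <- (nuc$diam / 2) / sqrt(nuc$q)
  h <- ((a - b) / (a + b))^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  s <- pi * nuc$diam / perim
  a <- a * s; b <- b * s
  pad <- a + 2.5 * ps
  i0 <- max(1L, floor((cy - pad) / ps) + 1L); i1 <- min(H, ceiling((cy + pad) / ps) + 1L)
  j0 <- max(1L, floor((cx - pad) / ps) + 1L); j1 <- min(W, ceiling((cx + pad) / ps) + 1L)
  ii <- i0:i1; jj <- j0:j1
  y <- (ii - 1) * ps - cy
  x <- (jj - 1) * ps - cx
  X <- matrix(x, length(ii), length(jj), byrow = TRUE)
  Y <- matrix(y, length(ii), length(jj))
  ct <- cos(nuc$theta); st <- sin(nuc$theta)
  U <- X * ct + Y * st
  V <- -X * st + Y * ct
  g <- sqrt((U / a)^2 + (V / b)^2)
  dist <- (g - 1) * sqrt(a * b)          # approximate signed distance (um)
  cov <- pmin(pmax(0.5 - dist / ps, 0), 1)
  add <- list()
  if (!any(cov > 0)) return(list(ii = ii, jj = jj, add = add))

  base <- .BASE_INTENSITY
  nm <- config@channels

  ## DAPI with nucleolus compensation: mask mean equals dapiRel * base
  if ("DAPI" %in% nm) {
    dapi <- cov
    if (!is.null(nuc$nucleoli)) {
      for (k in seq_len(nrow(nuc$nucleoli$centers))) {
        nc <- nuc$nucleoli$centers[k, ]
        rn <- nuc$nucleoli$diameter / 2
        dn <- sqrt((X - nc[1])^2 + (Y - nc[2])^2) - rn
        covN <- pmin(pmax(0.5 - dn / ps, 0), 1)
        dapi <- dapi - (1 - .NUCLEOLUS_DARK) * covN * cov
      }
      comp <- sum(cov) / max(sum(dapi), 1e-9)
    } else comp <- 1
    add$DAPI <- nuc$dapiRel * base * comp * dapi
  }

  rEff <- nuc$diam / 2
  alpha <- nuc$alphaDeg * pi / 180
  S <- X * cos(alpha) + Y * sin(alpha)    # coordinate along the polarity axis

  patternCov <- function(pattern) {
    switch(pattern,
      absent = NULL,
      low = cov, high = cov, whole = cov, diffuse = cov,
      polar = cov * pmin(pmax(0.5 + (S - 0.15 * rEff) / ps, 0), 1),
      complementary = cov * pmin(pmax(0.5 + (-S - 0.15 * rEff) / ps, 0), 1),
      stripe = cov * pmin(pmax(0.5 + (S - chordForCoverage(nuc$stripeCov) * rEff) / ps, 0), 1),
      dots = .dotsCov(X, Y, cov, rEff, nDots = sample(2:4, 1), dotDiam = 0.55, ps = ps),
      punctate = .dotsCov(X, Y, cov, rEff, nDots = sample(8:12, 1), dotDiam = 0.45, ps = ps),
      stop("unknown pattern: ", pattern))
  }

  for (mk in list(c("Ddx4", "diffuse"), c("Piwil1", "diffuse"),
                  c("Sycp3", nuc$sycp3Pattern), c("Pcna", nuc$pcnaPattern))) {
    channel <- mk[1]; pattern <- mk[2]
    level <- nuc$markers[[channel]]
    if (!channel %in% nm || level <= 0 || pattern == "absent") next
    pc <- patternCov(pattern)
    if (is.null(pc) || sum(pc) <= 0) next
    plateau <- level * base * sum(cov) / sum(pc)   # mask mean == level * base
    add[[channel]] <- if (is.null(add[[channel]])) plateau * pc
                      else add[[channel]] + plateau * pc
  }

  list(ii = ii, jj = jj, add = add)
}

## Coverage image of small signal foci scattered in the nucleus interior.
.dotsCov <- function(X, Y, cov, rEff, nDots, dotDiam, ps) {
  out <- matrix(0, nrow(X), ncol(X))
  pts <- matrix(NA_real_, nDots, 2)
  rmax <- 0.7 * rEff
  minSep <- max(1.1, dotDiam * 2)
  for (k in seq_len(nDots)) {
    placedOk <- FALSE
    for (a in 1:60) {
      p <- runif(2, -rmax, rmax)
      if (sum(p^2) > rmax^2) next
      if (k > 1) {
        prev <- pts[seq_len(k - 1), , drop = FALSE]
        if (any(sqrt(rowSums(sweep(prev, 2, p)^2)) < minSep)) next
      }
      pts[k, ] <- p; placedOk <- TRUE; break
    }
    if (!placedOk) pts[k, ] <- runif(2, -rmax, rmax)
    dn <- sqrt((X - pts[k, 1])^2 + (Y - pts[k, 2])^2) - dotDiam / 2
    out <- out + pmin(pmax(0.5 - dn / ps, 0), 1)
  }
  pmin(out, 1) * cov
}

#' Write / read a scene to disk
#'
#' \code{writeScene} writes \code{scene.tif} (multi-page 16-bit TIFF, page
#' order equal to the config channel order), \code{truth.json} (ground truth,
#' coordinates in micrometres with origin at the top-left pixel center) and
#' \code{scene_config.yaml} into \code{dir}. \code{readScene} reads them back.
#' Intensities are stored as 16-bit counts; values are clipped to
#' [0, 65535] and rounded, so the round trip quantizes to one count.
#'
#' @param scene a \code{\linkS4class{SceneBundle}}.
#' @param dir output directory (created if needed).
#' @return \code{writeScene}: \code{dir} invisibly; \code{readScene}: a
#'   \code{\linkS4class{SceneBundle}}.
#' @export
writeScene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ch <- sceneChannels(scene)
  pages <- lapply(seq_len(dim(ch)[3]), function(c)
    round(pmin(pmax(ch[, , c], 0), 65535)) / 65535)
  tiff::writeTIFF(pages, file.path(dir, "scene.tif"), bits.per.sample = 16L)
  jsonlite::write_json(sceneTruth(scene), file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  cfg <- sceneConfigOf(scene)
  yaml::write_yaml(list(
    imageSize = cfg@imageSize, pixelSize = cfg@pixelSize,
    channels = cfg@channels,
    cystPlan = list(label = cfg@cystPlan$label, size = cfg@cystPlan$size),
    noiseSd = cfg@noiseSd, backgroundLevel = cfg@backgroundLevel,
    illuminationGradient = cfg@illuminationGradient, seed = cfg@seed),
    file.path(dir, "scene_config.yaml"))
  invisible(dir)
}

#' @rdname writeScene
#' @export
readScene <- function(dir) {
  y <- yaml::read_yaml(file.path(dir, "scene_config.yaml"))
  cfg <- sceneConfig(
    cystPlan = if (length(y$cystPlan$label))
      data.frame(label = unlist(y$cystPlan$label),
                 size = as.integer(unlist(y$cystPlan$size))) else NULL,
    imageSize = unlist(y$imageSize), pixelSize = y$pixelSize,
    channels = unlist(y$channels), noiseSd = y$noiseSd,
    backgroundLevel = y$backgroundLevel,
    illuminationGradient = y$illuminationGradient, seed = y$seed)
  pages <- tiff::readTIFF(file.path(dir, "scene.tif"), all = TRUE)
  ch <- array(0, c(dim(pages[[1]]), length(pages)),
              dimnames = list(NULL, NULL, cfg@channels))
  for (c in seq_along(pages)) ch[, , c] <- pages[[c]] * 65535
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  if (!length(tr))
    tr <- data.frame(id = integer(), label = character(), subtype = character(),
                     cyst_id = integer(), x_um = numeric(), y_um = numeric(),
                     diameter_um = numeric(), dapi_rel = numeric(),
                     polar_angle = numeric())
  new("SceneBundle", channels = ch, truth = tr, config = cfg)
}
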