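## Per-nucleus feature extraction.
##
## Diameter follows the perimeter convention used for testis morphometry:
## the nuclear perimeter is measured on a sub-pixel contour of the region
## boundary and divided by the circular constant pi. Intensities are
## arithmetic means over the nucleus mask; relative intensities divide by
## the mean over reference-class nuclei of the same image after subtracting
## the per-channel background estimate.

.FEATURE_COLS <- c("id", "cyst_id", "cyst_size", "x_um", "y_um", "area_um2",
                   "perimeter_um", "diameter_um", "nucleolus_count",
                   "dapi_mean", "dapi_rel", "ddx4_rel", "piwil1_rel",
                   "sycp3_rel", "pcna_rel", "sycp3_pattern", "pcna_pattern",
                   "sycp3_rho", "sycp3_coverage", "pcna_rho", "pcna_coverage",
                   "pcna_punctateness", "polar_angle_sep_deg")

.MARKERS <- c("Ddx4", "Piwil1", "Sycp3", "Pcna")

#' Measure all segmented nuclei
#'
#' Extracts, for every label in the map: centroid and area; perimeter from a
#' sub-pixel (marching-squares) contour of the binary region boundary and
#' the derived diameter \code{perimeter / pi}; mean DAPI and marker
#' intensities over the region mask; the nucleolus census from DAPI-dark
#' interior blobs; and, when Sycp3/Pcna channels are present, their
#' subnuclear localization metrics (\code{\link{polarityMetrics}}).
#' Relative-intensity columns stay \code{NA} until
#' \code{\link{applyRelativeNormalization}} is applied; cyst columns stay
#' \code{NA} until \code{\link{assignCystsToRecords}}.
#'
#' @param labels a \code{\linkS4class{NucleusLabelMap}}.
#' @param channels numeric array (height x width x channel) with channel
#'   names in the third dimension, or a \code{\linkS4class{SceneBundle}}.
#' @param nucleolusMinDepth,nucleolusMinArea passed to \code{\link{countNucleoli}}.
#' @return data.frame with one row per nucleus (columns listed in the
#'   package vignette); attributes \code{background} and \code{backgroundSd}
#'   hold the per-channel background estimates (median and MAD over
#'   non-nucleus pixels), \code{pixelSize} the pixel size.
#' @export
measureNuclei <- function(labels, channels,
                          nucleolusMinDepth = 0.25, nucleolusMinArea = 0.3) {
  if (is(channels, "SceneBundle")) channels <- sceneChannels(channels)
  chNames <- dimnames(channels)[[3]]
  if (is.null(chNames)) stop("channels must carry channel names")
  if (!"DAPI" %in% chNames)
    stopWithClass("configurationError", "channel 'DAPI' is missing")
  lab <- labelMatrix(labels)
  ps <- pixelSize(labels)
  n <- nucleusCount(labels)

  bg <- vapply(chNames, function(ch) median(channels[, , ch][lab == 0L]), 0)
  bgSd <- vapply(chNames, function(ch) mad(channels[, , ch][lab == 0L]), 0)

  rows <- lapply(seq_len(n), function(id)
    .measureOne(id, lab, channels, ps, bg, bgSd,
                nucleolusMinDepth, nucleolusMinArea))
  rec <- if (n) do.call(rbind, rows) else .emptyRecords()
  attr(rec, "background") <- bg
  attr(rec, "backgroundSd") <- bgSd
  attr(rec, "pixelSize") <- ps
  rec
}

#' @rdname measureNuclei
#' @param labelId one nucleus id present in the label map.
#' @export
measureNucleus <- function(labelId, labels, channels, ...) {
  if (is(channels, "SceneBundle")) channels <- sceneChannels(channels)
  if (!labelId %in% labelMatrix(labels))
    stop("label id ", labelId, " not present in label map")
  rec <- measureNuclei(labels, channels, ...)
  rec[rec$id == labelId, ]
}

## Refine a nucleus mask to the half-maximum boundary. The global threshold
## that separates nuclei from background sits well below the plateau of
## bright classes, which inflates their masks (and so perimeter-based
## diameters) and dilutes their mean intensity. The refined mask keeps the
## pixels above background + half the background-subtracted in-mask median,
## restricted to this nucleus' watershed region plus free background, and
## takes the connected component overlapping the original mask.
.refineMask <- function(maskW, labW, dapiW, bgDapi) {
  med <- median(dapiW[maskW])
  thr <- bgDapi + 0.5 * (med - bgDapi)
  if (!is.finite(thr) || med <= bgDapi) return(maskW)
  cand <- (dapiW > thr) & (labW == 0L | maskW)
  if (!any(cand)) return(maskW)
  comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1)))
  keep <- unique(comp[maskW & cand])
  keep <- keep[keep > 0]
  if (!length(keep)) return(maskW)
  ## largest overlapping component, holes (nucleoli) filled
  ov <- vapply(keep, function(k) sum(comp == k & maskW), 0)
  out <- comp == keep[which.max(ov)]
  EBImage::imageData(EBImage::fillHull(EBImage::Image(out * 1))) > 0.5
}

.emptyRecords <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(.FEATURE_COLS) + 5))
  names(out) <- c(.FEATURE_COLS, "ddx4_mean", "piwil1_mean", "sycp3_mean",
                  "pcna_mean", "sycp3_punctateness")
  out
}

.measureOne <- function(id, lab, channels, ps, bg, bgSd, minDepth, minArea) {
  idx <- which(lab == id, arr.ind = TRUE)
  i0 <- max(1L, min(idx[, 1]) - 4L); i1 <- min(nrow(lab), max(idx[, 1]) + 4L)
  j0 <- max(1L, min(idx[, 2]) - 4L); j1 <- min(ncol(lab), max(idx[, 2]) + 4L)
  labW <- lab[i0:i1, j0:j1]
  maskW <- labW == id
  maskW <- .refineMask(maskW, labW, channels[i0:i1, j0:j1, "DAPI"], bg[["DAPI"]])

  idxW <- which(maskW, arr.ind = TRUE)
  areaPx <- nrow(idxW)
  perim <- maskPerimeter(maskW) * ps
  cx <- (mean(idxW[, 2]) + j0 - 2) * ps
  cy <- (mean(idxW[, 1]) + i0 - 2) * ps
  chNames <- dimnames(channels)[[3]]

  win <- function(ch) channels[i0:i1, j0:j1, ch]
  chMean <- vapply(chNames, function(ch) mean(win(ch)[maskW]), 0)

  nucleoli <- countNucleoli(win("DAPI"), maskW, ps,
                            minDepth = minDepth, minArea = minArea)

  metr <- list(Sycp3 = NULL, Pcna = NULL)
  for (ch in c("Sycp3", "Pcna")) {
    if (ch %in% chNames)
      metr[[ch]] <- polarityMetrics(win(ch), maskW, ps,
                                    backgroundMean = bg[[ch]],
                                    backgroundSd = bgSd[[ch]])
  }
  m <- function(ch, f) if (is.null(metr[[ch]])) NA_real_ else metr[[ch]][[f]]
  sep <- if (!is.null(metr$Sycp3) && !is.null(metr$Pcna) &&
             !is.na(metr$Sycp3$polar_angle) && !is.na(metr$Pcna$polar_angle))
    angleSep(metr$Sycp3$polar_angle, metr$Pcna$polar_angle) else NA_real_

  getRaw <- function(ch) if (ch %in% chNames) chMean[[ch]] else NA_real_

  data.frame(
    id = id, cyst_id = NA_integer_, cyst_size = NA_integer_,
    x_um = cx, y_um = cy, area_um2 = areaPx * ps^2,
    perimeter_um = perim, diameter_um = perim / pi,
    nucleolus_count = nucleoli,
    dapi_mean = chMean[["DAPI"]],
    dapi_rel = NA_real_, ddx4_rel = NA_real_, piwil1_rel = NA_real_,
    sycp3_rel = NA_real_, pcna_rel = NA_real_,
    sycp3_pattern = NA_character_, pcna_pattern = NA_character_,
    sycp3_rho = m("Sycp3", "rho"), sycp3_coverage = m("Sycp3", "coverage"),
    pcna_rho = m("Pcna", "rho"), pcna_coverage = m("Pcna", "coverage"),
    pcna_punctateness = m("Pcna", "punctateness"),
    polar_angle_sep_deg = sep,
    ddx4_mean = getRaw("Ddx4"), piwil1_mean = getRaw("Piwil1"),
    sycp3_mean = getRaw("Sycp3"), pcna_mean = getRaw("Pcna"),
    sycp3_punctateness = m("Sycp3", "punctateness"),
    stringsAsFactors = FALSE)
}

#' Count nucleoli as DAPI-dark interior blobs
#'
#' Nucleoli exclude DAPI and appear as dark discs inside the nucleus. Counted
#' are connected regions where intensity falls below
#' \code{(1 - minDepth) * median(DAPI in mask)}, of area at least
#' \code{minArea}, that do not touch the nuclear boundary.
#'
#' @param dapi numeric matrix (window around one nucleus).
#' @param mask logical matrix, the nucleus mask.
#' @param pixelSize micrometres per pixel.
#' @param minDepth minimal fractional intensity dip (default 0.25).
#' @param minArea minimal blob area in square micrometres (default 0.3).
#' @return integer nucleolus count.
#' @export
countNucleoli <- function(dapi, mask, pixelSize,
                          minDepth = 0.25, minArea = 0.3) {
  stopifnot(any(mask))
  thr <- (1 - minDepth) * median(dapi[mask])
  interior <- EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(3, "box")) > 0.5
  cand <- mask & (dapi < thr)
  if (!any(cand)) return(0L)
  blobs <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cand * 1)))
  minPx <- minArea / pixelSize^2
  count <- 0L
  for (b in seq_len(max(blobs))) {
    pix <- blobs == b
    if (sum(pix) < minPx) next
    if (any(pix & !interior)) next   # touches the nuclear boundary
    count <- count + 1L
  }
  count
}

#' Attach cyst assignment to measured records
#'
#' Fills the \code{cyst_id} and \code{cyst_size} columns. With an explicit
#' \code{linkDistance} this is \code{\link{groupCysts}} (fixed-distance
#' single linkage). The default is size-adaptive single linkage: two nuclei
#' link when their centroid distance is at most \code{adaptiveFactor} times
#' the mean of their two measured diameters, which keeps small-nucleus
#' cysts (spermatozoa, 2 um) and large-nucleus cysts (spermatogonia, 6 um)
#' grouped correctly in the same image, where any single global distance
#' either splits the large cysts or merges the small ones.
#'
#' @param records output of \code{\link{measureNuclei}}.
#' @param linkDistance linkage distance in micrometres, or NULL (default)
#'   for size-adaptive linkage.
#' @param adaptiveFactor multiple of the pair mean diameter used by the
#'   adaptive default.
#' @return records with cyst columns filled.
#' @export
assignCystsToRecords <- function(records, linkDistance = NULL,
                                 adaptiveFactor = 2) {
  if (!nrow(records)) return(records)
  if (!is.null(linkDistance)) {
    grp <- groupCysts(records, linkDistance)
    ids <- grp$cyst_id
  } else {
    n <- nrow(records)
    D <- as.matrix(stats::dist(cbind(records$x_um, records$y_um)))
    thr <- adaptiveFactor * outer(records$diameter_um, records$diameter_um, "+") / 2
    adj <- D <= thr
    ## connected components by BFS
    comp <- integer(n); cur <- 0L
    for (s in seq_len(n)) {
      if (comp[s]) next
      cur <- cur + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        if (comp[v]) next
        comp[v] <- cur
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    ids <- comp
  }
  records$cyst_id <- as.integer(ids)
  records$cyst_size <- as.integer(table(ids)[as.character(ids)])
  records
}

#' Normalize intensities to reference nuclei of the same image
#'
#' Relative intensity divides each nucleus' background-subtracted mean by
#' the mean over the reference nuclei's background-subtracted means, per
#' channel, so the reference class averages exactly 1. The reference class
#' is \code{SPG-A(2,4,8-cell)}; its nuclei may be given explicitly or found
#' with \code{\link{selectReferenceNuclei}}. With a zero background estimate
#' this reduces to the plain ratio of raw means.
#'
#' Pattern labels for Sycp3/Pcna are filled at the same time (via
#' \code{\link{classifyPattern}}) because they require the relative level.
#'
#' @param records output of \code{\link{measureNuclei}}.
#' @param referenceIds nucleus ids of the reference class in this image.
#' @param thresholds localization thresholds (see
#'   \code{\link{defaultThresholds}}); only \code{marker_absent} is used here.
#' @return records with \code{*_rel} and pattern columns filled.
#' @export
applyRelativeNormalization <- function(records, referenceIds,
                                       thresholds = defaultThresholds()) {
  if (!length(referenceIds) || !any(records$id %in% referenceIds))
    stopWithClass("missingReferenceError",
                  "no reference nuclei available for normalization")
  bg <- attr(records, "background")
  if (is.null(bg)) bg <- c(DAPI = 0, Ddx4 = 0, Piwil1 = 0, Sycp3 = 0, Pcna = 0)
  ref <- records[records$id %in% referenceIds, ]

  relCol <- c(DAPI = "dapi_rel", Ddx4 = "ddx4_rel", Piwil1 = "piwil1_rel",
              Sycp3 = "sycp3_rel", Pcna = "pcna_rel")
  rawCol <- c(DAPI = "dapi_mean", Ddx4 = "ddx4_mean", Piwil1 = "piwil1_mean",
              Sycp3 = "sycp3_mean", Pcna = "pcna_mean")
  denomDapi <- mean(ref[[rawCol[["DAPI"]]]]) - bg[["DAPI"]]
  if (!is.finite(denomDapi) || denomDapi <= 0)
    stopWithClass("missingReferenceError", "degenerate reference DAPI mean")

  for (ch in names(relCol)) {
    raw <- records[[rawCol[[ch]]]]
    if (all(is.na(raw))) next
    b <- if (ch %in% names(bg)) bg[[ch]] else 0
    denom <- mean(ref[[rawCol[[ch]]]]) - b
    ## markers near-absent from the reference class (e.g. Sycp3) have no
    ## usable own denominator; express them in reference-DAPI-equivalent
    ## units instead, which keeps zero at zero and is scale invariant.
    if (!is.finite(denom) || denom < 0.02 * denomDapi) denom <- denomDapi
    records[[relCol[[ch]]]] <- (raw - b) / denom
  }

  records <- .labelPatterns(records, thresholds)
  records
}

## Assign sycp3/pcna pattern labels from metrics + relative level.
.labelPatterns <- function(records, thresholds) {
  if (!nrow(records)) return(records)
  for (i in seq_len(nrow(records))) {
    if (!is.na(records$sycp3_rho[i]) && !is.na(records$sycp3_rel[i]))
      records$sycp3_pattern[i] <- classifyPattern(
        list(rho = records$sycp3_rho[i], coverage = records$sycp3_coverage[i],
             punctateness = records$sycp3_punctateness[i],
             level = records$sycp3_rel[i]), thresholds)
    if (!is.na(records$pcna_rho[i]) && !is.na(records$pcna_rel[i]))
      records$pcna_pattern[i] <- classifyPattern(
        list(rho = records$pcna_rho[i], coverage = records$pcna_coverage[i],
             punctateness = records$pcna_punctateness[i],
             level = records$pcna_rel[i]), thresholds)
  }
  records
}

#' Auto-select reference nuclei for normalization
#'
#' When no explicit reference ids are known (unlabeled images), candidate
#' \code{SPG-A(2,4,8-cell)} nuclei are flagged as members of cysts of 2-8
#' cells whose diameter lies within one profile sd of the reference profile
#' mean and whose raw Ddx4 signal is in the top quartile of the image.
#'
#' @param records measured records with cyst columns filled.
#' @param profiles a \code{\linkS4class{ClassProfileSet}}.
#' @return integer vector of candidate reference nucleus ids.
#' @export
selectReferenceNuclei <- function(records, profiles = makeDefaultProfiles()) {
  prof <- getProfile(profiles, referenceLabel(profiles))
  ok <- records$cyst_size >= 2 & records$cyst_size <= 8 &
    abs(records$diameter_um - prof$diameter_mean) <= prof$diameter_sd
  if (!all(is.na(records$ddx4_mean))) {
    q3 <- quantile(records$ddx4_mean, 0.75, na.rm = TRUE, names = FALSE)
    ok <- ok & !is.na(records$ddx4_mean) & records$ddx4_mean >= q3
  }
  ids <- records$id[which(ok)]
  if (!length(ids))
    stopWithClass("missingReferenceError",
                  "auto-reference found no candidate SPG-A(2,4,8-cell) nuclei")
  ids
}

#' Write / read the canonical features CSV
#'
#' Column order: id, cyst_id, cyst_size, x_um, y_um, area_um2, perimeter_um,
#' diameter_um, nucleolus_count, dapi_mean, dapi_rel, ddx4_rel, piwil1_rel,
#' sycp3_rel, pcna_rel, sycp3_pattern, pcna_pattern, sycp3_rho,
#' sycp3_coverage, pcna_rho, pcna_coverage, pcna_punctateness,
#' polar_angle_sep_deg. Missing channels yield empty fields.
#'
#' @param records measured (and usually normalized) records.
#' @param path CSV path.
#' @return \code{writeFeatures}: \code{path} invisibly; \code{readFeatures}:
#'   a records data.frame.
#' @export
writeFeatures <- function(records, path) {
  write.csv(records[, .FEATURE_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
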