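## Subnuclear Sycp3/Pcna localization and meiotic prophase staging.
##
## Across primary spermatocyte (SPC-I) prophase, Sycp3 spreads from one
## nuclear pole (leptotene) across the nucleus as a stripe (zygotene) until
## it occupies the whole nucleus (pachytene), while Pcna moves from co-polar
## with Sycp3, to the complementary side, to punctate foci of decreasing
## level, to undetectable. The metrics below quantify that progression.

#' Subnuclear localization metrics for one nucleus
#'
#' Computed on background-subtracted signal:
#' \itemize{
#'   \item \code{rho}: polarity displacement, distance between the
#'     intensity-weighted centroid and the nuclear centroid divided by the
#'     equivalent nuclear radius (0 = symmetric, ~0.42 for a half-disc);
#'   \item \code{coverage}: fraction of nuclear area with signal above
#'     threshold (default threshold: background mean + 3 background sd);
#'   \item \code{punctateness}: number of distinct above-threshold blobs;
#'   \item \code{polar_angle}: direction (degrees) of the displacement;
#'   \item \code{level}: background-subtracted mean in-nucleus signal (raw
#'     counts; converted to reference units during normalization).
#' }
#'
#' @param channel numeric matrix, the marker window around the nucleus.
#' @param mask logical matrix, the nucleus mask (same size).
#' @param pixelSize micrometres per pixel.
#' @param backgroundMean,backgroundSd per-channel background estimates.
#' @param signalThreshold absolute intensity threshold overriding the
#'   default \code{backgroundMean + 3 backgroundSd}.
#' @return list with rho, coverage, punctateness, polar_angle, level.
#' @export
polarityMetrics <- function(channel, mask, pixelSize,
                            backgroundMean = 0, backgroundSd = 0,
                            signalThreshold = NULL) {
  stopifnot(any(mask))
  if (is.null(signalThreshold))
    signalThreshold <- backgroundMean + 3 * backgroundSd
  sig <- pmax(channel - backgroundMean, 0)
  above <- mask & (channel > signalThreshold)

  idx <- which(mask, arr.ind = TRUE)
  c0 <- colMeans(idx)                      # nuclear centroid (row, col)
  areaPx <- nrow(idx)
  rEq <- sqrt(areaPx / pi)                 # equivalent radius in px

  w <- sig[mask]
  tot <- sum(w)
  if (tot > 0) {
    cw <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / tot
    disp <- cw - c0
    rho <- sqrt(sum(disp^2)) / rEq
    ## angle in image coordinates: x = col, y = row
    polar <- (atan2(disp[1], disp[2]) * 180 / pi) %% 360
  } else {
    rho <- 0; polar <- NA_real_
  }

  punct <- 0L
  if (any(above)) {
    blobs <- EBImage::bwlabel(EBImage::Image(above * 1))
    sizes <- tabulate(EBImage::imageData(blobs)[above])
    punct <- sum(sizes >= 2L)              # ignore single-pixel noise
  }

  list(rho = rho,
       coverage = sum(above) / areaPx,
       punctateness = punct,
       polar_angle = polar,
       level = mean(sig[mask]))
}

#' Classify a subnuclear pattern from its metrics
#'
#' First-match decision list over the closed pattern vocabulary:
#' \enumerate{
#'   \item \code{absent} if level < \code{t_abs};
#'   \item \code{dots} if coverage < 0.1 and 1-6 blobs;
#'   \item \code{polar} if rho >= 0.35 and coverage <= 0.5;
#'   \item \code{whole} if coverage >= 0.9;
#'   \item \code{stripe} if 0.5 < coverage < 0.9;
#'   \item \code{punctate} if >= 7 blobs and coverage < 0.5;
#'   \item \code{diffuse} otherwise.
#' }
#' Deterministic and total over finite metrics.
#'
#' @param m list with \code{rho}, \code{coverage}, \code{punctateness} and
#'   \code{level} (level in relative units).
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @return one of absent, dots, polar, stripe, whole, punctate, diffuse.
#' @export
classifyPattern <- function(m, thresholds = defaultThresholds()) {
  t <- thresholds
  if (is.na(m$level) || m$level < t$t_abs) return("absent")
  if (!is.na(m$coverage) && m$coverage < 0.1 &&
      !is.na(m$punctateness) && m$punctateness >= 1 && m$punctateness <= 6)
    return("dots")
  if (!is.na(m$rho) && m$rho >= t$rho_polar && m$coverage <= t$coverage_polar)
    return("polar")
  if (m$coverage >= t$coverage_whole) return("whole")
  if (m$coverage > t$coverage_polar && m$coverage < t$coverage_whole)
    return("stripe")
  if (!is.na(m$punctateness) && m$punctateness >= 7 &&
      m$coverage < t$coverage_polar)
    return("punctate")
  "diffuse"
}

#' Stage a primary spermatocyte from Sycp3/Pcna patterns
#'
#' Maps the joint Sycp3/Pcna localization to the five SPC-I substages:
#' \itemize{
#'   \item L (leptotene): Sycp3 polar and Pcna polar on the same side
#'     (angular separation < 60 degrees);
#'   \item EZ (early zygotene): Sycp3 polar with Pcna on the complementary
#'     side (separation > 120 degrees, or coverage > 0.5 opposite);
#'   \item MZ (mid zygotene): Sycp3 stripe with coverage < 0.65, Pcna
#'     punctate;
#'   \item LZ (late zygotene): Sycp3 stripe with coverage >= 0.65, Pcna
#'     punctate at lower level (level used as tiebreak near the coverage
#'     boundary);
#'   \item P (pachytene): Sycp3 whole-nucleus, Pcna absent.
#' }
#'
#' @param sycp3 list: metrics of the Sycp3 channel plus \code{pattern}.
#' @param pcna list: metrics of the Pcna channel plus \code{pattern}.
#' @param angleSepDeg angular separation (degrees) between the Sycp3 and
#'   Pcna displacement vectors; may be NA when either is undefined.
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @return list with \code{subtype} (one of L, EZ, MZ, LZ, P) and
#'   \code{rule}, the id of the staging rule that fired.
#' @export
stageSpc1 <- function(sycp3, pcna, angleSepDeg = NA,
                      thresholds = defaultThresholds()) {
  t <- thresholds
  sp <- sycp3$pattern
  if (!sp %in% c("polar", "stripe", "whole"))
    stopWithClass("notSpc1Error",
                  "Sycp3 pattern '%s' is not meiotic: not an SPC-I nucleus", sp)
  pp <- pcna$pattern
  if (sp == "polar") {
    if (pp == "polar" && !is.na(angleSepDeg) && angleSepDeg < t$sep_same)
      return(list(subtype = "L", rule = "stage-L"))
    if ((pp %in% c("polar", "stripe", "diffuse")) && !is.na(angleSepDeg) &&
        angleSepDeg > t$sep_opposite)
      return(list(subtype = "EZ", rule = "stage-EZ"))
    if (!is.na(pcna$coverage) && pcna$coverage > 0.5 &&
        !is.na(angleSepDeg) && angleSepDeg > 90)
      return(list(subtype = "EZ", rule = "stage-EZ-coverage"))
    ## fallback: side of the Pcna signal decides
    if (!is.na(angleSepDeg))
      return(list(subtype = if (angleSepDeg < 90) "L" else "EZ",
                  rule = "stage-polar-fallback"))
    return(list(subtype = "L", rule = "stage-polar-fallback"))
  }
  if (sp == "stripe") {
    cov <- sycp3$coverage
    near <- abs(cov - t$coverage_stripe_split) <= 0.05
    if (near && !is.na(pcna$level)) {
      ## decreasing Pcna level along meiosis breaks boundary ties
      subtype <- if (pcna$level >= t$pcna_mz_level) "MZ" else "LZ"
      return(list(subtype = subtype, rule = "stage-MZ-LZ-level"))
    }
    subtype <- if (cov < t$coverage_stripe_split) "MZ" else "LZ"
    return(list(subtype = subtype, rule = paste0("stage-", subtype)))
  }
  ## whole-nucleus Sycp3
  list(subtype = "P", rule = "stage-P")
}
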