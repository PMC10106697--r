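#' @import methods
#' @importFrom stats median mad quantile rnorm runif sd setNames
#' @importFrom grDevices contourLines
#' @importFrom utils write.csv read.csv
#' @useDynLib SpermatoTyper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## The twelve cell type / subtype labels, in developmental order.
.CELL_LABELS <- c(
  "SPG-A(1-cell)", "SPG-A(2,4,8-cell)",
  "SPG-B(16,32-cell)", "SPG-B(64,128,256-cell)",
  "SPC-I(L)", "SPC-I(EZ)", "SPC-I(MZ)", "SPC-I(LZ)", "SPC-I(P)",
  "SPC-II", "SPD", "SPZ"
)

.SYCP3_PATTERNS <- c("absent", "dots", "polar", "stripe", "whole")
.PCNA_PATTERNS  <- c("absent", "low", "high", "polar", "complementary", "punctate")
.PATTERN_LABELS <- c("absent", "dots", "polar", "stripe", "whole", "punctate", "diffuse")

.PROFILE_COLS <- c("label", "diameter_mean", "diameter_sd",
                   "dapi_rel_mean", "dapi_rel_sd",
                   "ddx4", "piwil1", "sycp3", "pcna",
                   "sycp3_pattern", "pcna_pattern",
                   "nucleolus_min", "nucleolus_max", "nucleolus_rel_diam")

#' ClassProfileSet: per-cell-type generative and diagnostic parameters
#'
#' Holds one row per spermatogenic cell type/subtype with nuclear diameter
#' (mean, sd, micrometres), relative DAPI intensity (dimensionless, normalized
#' to the type B reference spermatogonia \code{SPG-A(2,4,8-cell)}), relative
#' marker levels for Ddx4, Piwil1, Sycp3 and Pcna, the subnuclear Sycp3/Pcna
#' pattern each type displays, its nucleolus census and the admissible clonal
#' cyst sizes. The set also records which label is the normalization
#' reference.
#'
#' @slot profiles data.frame, one row per label (see \code{\link{makeDefaultProfiles}}).
#' @slot cystSizes named list mapping each label to its admissible cyst cell counts.
#' @slot reference character, label of the normalization reference class.
#'
#' @seealso \code{\link{makeDefaultProfiles}}, \code{\link{readProfiles}}
#' @export
setClass("ClassProfileSet",
  representation(profiles = "data.frame", cystSizes = "list",
                 reference = "character"))

setValidity("ClassProfileSet", function(object) {
  p <- object@profiles
  msg <- character()
  if (!all(.PROFILE_COLS %in% names(p)))
    msg <- c(msg, paste("profiles must have columns:",
                        paste(setdiff(.PROFILE_COLS, names(p)), collapse = ", ")))
  else {
    if (anyDuplicated(p$label)) msg <- c(msg, "duplicated profile labels")
    if (!(object@reference %in% p$label))
      msg <- c(msg, sprintf("reference label '%s' not present", object@reference))
    if (any(p$diameter_mean <= 0)) msg <- c(msg, "diameter_mean must be > 0")
    if (any(p$diameter_sd < 0)) msg <- c(msg, "diameter_sd must be >= 0")
    if (any(p[, c("ddx4", "piwil1", "sycp3", "pcna")] < 0))
      msg <- c(msg, "marker levels must be >= 0")
    if (!all(p$sycp3_pattern %in% .SYCP3_PATTERNS))
      msg <- c(msg, "invalid sycp3_pattern")
    if (!all(p$pcna_pattern %in% .PCNA_PATTERNS))
      msg <- c(msg, "invalid pcna_pattern")
    if (!setequal(names(object@cystSizes), p$label) ||
        any(!vapply(object@cystSizes, length, 0L)))
      msg <- c(msg, "cystSizes must map every label to a nonempty count set")
    if (object@reference %in% p$label &&
        abs(p$dapi_rel_mean[p$label == object@reference] - 1) > 1e-12)
      msg <- c(msg, "reference class must have dapi_rel_mean exactly 1")
  }
  if (length(msg)) msg else TRUE
})

#' SceneConfig: parameters of one synthetic testis-section scene
#'
#' @slot imageSize integer length-2, image height and width in pixels.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot channels character, ordered channel names; DAPI first.
#' @slot cystPlan data.frame with columns \code{label} and \code{size}: one
#'   clonal cyst per row.
#' @slot noiseSd numeric, additive Gaussian noise sd (intensity counts).
#' @slot backgroundLevel numeric, flat background (intensity counts).
#' @slot illuminationGradient numeric, fractional slope of a multiplicative
#'   linear illumination ramp applied identically to every channel (0 = flat).
#' @slot seed integer, RNG seed making the scene reproducible.
#' @export
setClass("SceneConfig",
  representation(imageSize = "integer", pixelSize = "numeric",
                 channels = "character", cystPlan = "data.frame",
                 noiseSd = "numeric", backgroundLevel = "numeric",
                 illuminationGradient = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (length(object@imageSize) != 2L || any(object@imageSize < 16L))
    msg <- c(msg, "imageSize must be two pixel counts >= 16")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(object@channels) < 1L || object@channels[1] != "DAPI")
    msg <- c(msg, "channels must start with 'DAPI'")
  if (!all(c("label", "size") %in% names(object@cystPlan)))
    msg <- c(msg, "cystPlan needs columns label, size")
  if (object@noiseSd < 0 || object@backgroundLevel < 0)
    msg <- c(msg, "noiseSd and backgroundLevel must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SceneBundle: a rendered synthetic scene plus its ground truth
#'
#' @slot channels numeric array (height x width x channel) of intensities.
#' @slot truth data.frame, one row per rendered nucleus: \code{id},
#'   \code{label}, \code{subtype}, \code{cyst_id}, \code{x_um}, \code{y_um},
#'   \code{diameter_um}, \code{dapi_rel}, \code{polar_angle} (degrees or NA).
#' @slot config the \code{\link{SceneConfig}} the scene was rendered from.
#' @export
setClass("SceneBundle",
  representation(channels = "array", truth = "data.frame",
                 config = "SceneConfig"))

setValidity("SceneBundle", function(object) {
  msg <- character()
  dm <- dim(object@channels)
  cfg <- object@config
  if (length(dm) != 3L || dm[3] != length(cfg@channels))
    msg <- c(msg, "channel count must equal config channel count")
  tr <- object@truth
  need <- c("id", "label", "subtype", "cyst_id", "x_um", "y_um",
            "diameter_um", "polar_angle")
  if (!all(need %in% names(tr)))
    msg <- c(msg, "truth is missing required columns")
  else if (nrow(tr)) {
    if (anyDuplicated(tr$id)) msg <- c(msg, "truth ids must be unique")
    fw <- (cfg@imageSize[2] - 1) * cfg@pixelSize
    fh <- (cfg@imageSize[1] - 1) * cfg@pixelSize
    r <- tr$diameter_um / 2
    if (any(tr$x_um - r < 0 | tr$x_um + r > fw |
            tr$y_um - r < 0 | tr$y_um + r > fh))
      msg <- c(msg, "every truth nucleus must lie fully inside the image")
  }
  if (length(msg)) msg else TRUE
})

#' NucleusLabelMap: segmented nuclei
#'
#' Integer label image produced by \code{\link{segmentNuclei}}: 0 marks
#' background, k > 0 the k-th nucleus; label ids are contiguous from 1.
#'
#' @slot labels integer matrix.
#' @slot pixelSize numeric, micrometres per pixel.
#' @export
setClass("NucleusLabelMap",
  representation(labels = "matrix", pixelSize = "numeric"))

setValidity("NucleusLabelMap", function(object) {
  msg <- character()
  lab <- object@labels
  if (any(lab < 0)) msg <- c(msg, "labels must be nonnegative")
  u <- sort(unique(as.integer(lab[lab > 0])))
  if (length(u) && !identical(u, seq_along(u)))
    msg <- c(msg, "label ids must be contiguous from 1")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Cyst3D: a packed spherical cyst
#'
#' Geometry produced by \code{\link{packCyst}}: n equal spheres (cells) packed
#' without overlap inside a spherical cyst, the "clay ball" used to infer the
#' clonal generation of spermatogonial cysts from planar section counts.
#'
#' @slot nCells integer, number of cells.
#' @slot cellDiameter numeric, cell diameter (arbitrary length unit).
#' @slot centers numeric matrix (n x 3) of cell centers.
#' @slot ballRadius numeric, radius of the enclosing cyst sphere.
#' @slot packingFraction numeric, target packing fraction.
#' @export
setClass("Cyst3D",
  representation(nCells = "integer", cellDiameter = "numeric",
                 centers = "matrix", ballRadius = "numeric",
                 packingFraction = "numeric"))

setValidity("Cyst3D", function(object) {
  msg <- character()
  X <- object@centers
  d <- object@cellDiameter
  tol <- 1e-6 * d
  if (nrow(X) != object@nCells) msg <- c(msg, "centers must have nCells rows")
  if (object@nCells > 1L) {
    if (min(stats::dist(X)) < d - tol)
      msg <- c(msg, "cells overlap: pairwise center distance < cellDiameter")
  }
  if (any(sqrt(rowSums(X^2)) > object@ballRadius - d / 2 + tol))
    msg <- c(msg, "all cells must lie inside the cyst ball")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ClassProfileSet", function(object) {
  cat(sprintf("ClassProfileSet with %d cell types (reference: %s)\n",
              nrow(object@profiles), object@reference))
  cat("  labels:", paste(object@profiles$label, collapse = ", "), "\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %d x %d px @ %.3g um/px, %d channels, %d cysts planned\n",
              object@imageSize[1], object@imageSize[2], object@pixelSize,
              length(object@channels), nrow(object@cystPlan)))
})

setMethod("show", "SceneBundle", function(object) {
  cat(sprintf("SceneBundle: %d channel(s) [%s], %d ground-truth nuclei\n",
              dim(object@channels)[3],
              paste(object@config@channels, collapse = ", "),
              nrow(object@truth)))
})

setMethod("show", "NucleusLabelMap", function(object) {
  cat(sprintf("NucleusLabelMap: %d x %d px @ %.3g um/px, %d nuclei\n",
              nrow(object@labels), ncol(object@labels), object@pixelSize,
              max(0L, max(object@labels))))
})

setMethod("show", "Cyst3D", function(object) {
  cat(sprintf("Cyst3D: %d cells of diameter %.3g packed at phi=%.2f in ball radius %.3g\n",
              object@nCells, object@cellDiameter, object@packingFraction,
              object@ballRadius))
})
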