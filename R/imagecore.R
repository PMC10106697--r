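#' Segment nuclei from a DAPI channel
#'
#' Standard DAPI pipeline: Gaussian smoothing, global thresholding (Otsu on
#' log-intensities by default, so that dim and bright nucleus populations
#' end up on the same side of the threshold), hole filling (so DAPI-dark
#' nucleoli do not fragment nuclei), distance-transform watershed to split
#' touching nuclei, and a minimum-area filter.
#'
#' @param dapi numeric matrix of DAPI intensities (row = y, column = x).
#' @param pixelSize micrometres per pixel.
#' @param smoothingSigma Gaussian smoothing sigma in micrometres.
#' @param minArea minimum nucleus area in square micrometres; smaller regions
#'   are discarded. The default is tuned to the smallest expected nuclei
#'   (spermatozoa, about 2 um across).
#' @param thresholdMethod \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold fixed intensity threshold, used when
#'   \code{thresholdMethod = "fixed"}.
#' @param watershedTolerance height tolerance of the distance-map watershed.
#' @return a \code{\linkS4class{NucleusLabelMap}}; an all-background image
#'   yields an empty label map.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[20:30, 20:30] <- 100
#' nucleusCount(segmentNuclei(img, pixelSize = 0.2))
#' @export
segmentNuclei <- function(dapi, pixelSize,
                          smoothingSigma = 0.3, minArea = 2,
                          thresholdMethod = c("otsu", "fixed"),
                          threshold = NULL,
                          watershedTolerance = 1) {
  thresholdMethod <- match.arg(thresholdMethod)
  if (any(!is.finite(dapi)))
    stop("dapi contains non-finite values")
  if (any(dapi < 0)) dapi <- pmax(dapi, 0)
  empty <- function() new("NucleusLabelMap",
                          labels = matrix(0L, nrow(dapi), ncol(dapi)),
                          pixelSize = pixelSize)
  rng <- range(dapi)
  if (diff(rng) < 1e-9) return(empty())

  sigmaPx <- smoothingSigma / pixelSize
  img <- EBImage::Image(dapi)
  if (sigmaPx > 0.2) img <- EBImage::gblur(img, sigma = sigmaPx)

  if (thresholdMethod == "fixed") {
    if (is.null(threshold)) stop("thresholdMethod 'fixed' needs a threshold")
    bin <- img > threshold
  } else {
    lg <- log1p(EBImage::imageData(img))
    lg01 <- (lg - min(lg)) / diff(range(lg))
    th <- EBImage::otsu(EBImage::Image(lg01), range = c(0, 1))
    bin <- EBImage::Image(lg01 > th)
  }
  bin <- EBImage::fillHull(bin)
  if (!any(bin)) return(empty())

  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = watershedTolerance, ext = 1)
  lab <- EBImage::imageData(lab)

  minPx <- minArea / pixelSize^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minPx)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  pos <- lab > 0
  out[pos] <- remap[lab[pos]]
  new("NucleusLabelMap", labels = out, pixelSize = pixelSize)
}

#' Group nuclei into cysts by single-linkage proximity
#'
#' Two nuclei belong to the same cyst iff a chain of pairwise centroid
#' distances each at most \code{linkDistance} connects them (single-linkage
#' connected components). Clonal cysts are contiguous groups of same-stage
#' cells, so chained proximity is the section-level surrogate for cyst
#' membership.
#'
#' @param centroids numeric matrix (n x 2) of nucleus centroids in
#'   micrometres, or a data.frame with columns \code{x_um}, \code{y_um}.
#' @param linkDistance linkage distance in micrometres; the conventional
#'   default is 1.5 times the median equivalent nuclear diameter of the
#'   image (see \code{\link{measureNuclei}}).
#' @return list with \code{cyst_id} (integer per nucleus, ids contiguous
#'   from 1 in first-appearance order) and \code{members} (list mapping cyst
#'   id to member indices).
#' @examples
#' pts <- rbind(c(0, 0), c(5, 0), c(10, 0), c(40, 0))
#' groupCysts(pts, linkDistance = 6)$cyst_id
#' @export
groupCysts <- function(centroids, linkDistance) {
  if (is.data.frame(centroids))
    centroids <- cbind(centroids$x_um, centroids$y_um)
  stopifnot(linkDistance > 0)
  n <- nrow(centroids)
  if (n == 0L) return(list(cyst_id = integer(), members = list()))
  if (n == 1L) return(list(cyst_id = 1L, members = list(`1` = 1L)))
  hc <- stats::hclust(stats::dist(centroids), method = "single")
  grp <- stats::cutree(hc, h = linkDistance)
  ## relabel in first-appearance order for determinism
  ids <- match(grp, unique(grp))
  members <- split(seq_len(n), ids)
  names(members) <- seq_along(members)
  list(cyst_id = as.integer(ids), members = members)
}
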