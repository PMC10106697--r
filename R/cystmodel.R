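## The "clay ball" model: a clonal cyst is a sphere densely packed with n
## equal spherical cells; the number of cells seen on its largest planar
## section identifies the clonal generation (n is a power of two). Published
## anchors for zebrafish: largest-section counts of 14.3 +/- 1.5 for
## 32-cell cysts and 54.9 +/- 10.7 for 256-cell cysts.

.GENERATION_SET <- c(1L, 2L, 4L, 8L, 16L, 32L, 64L, 128L, 256L)

.generationLabel <- function(n) {
  if (n <= 1) "SPG-A(1-cell)"
  else if (n <= 8) "SPG-A(2,4,8-cell)"
  else if (n <= 32) "SPG-B(16,32-cell)"
  else "SPG-B(64,128,256-cell)"
}

#' Pack a spherical cyst with n cells
#'
#' Cells (unit spheres of diameter \code{cellDiameter}) are packed inside
#' the minimal cyst ball of radius
#' \code{(n / phi)^(1/3) * cellDiameter / 2 * (1 + slack)} by random
#' insertion followed by centripetal compression: centers start dilute,
#' pairwise overlaps are relaxed with a small decaying jitter while the
#' confining radius shrinks stepwise toward its target. Random packings in a
#' hard spherical boundary jam below ideal densities, so when compression
#' stalls before the nominal radius the achieved jamming radius is reported
#' as \code{ballRadius} (typically 5-10% above nominal); n = 1 and the
#' kissing pair n = 2 are exact special cases. Deterministic given
#' \code{seed}.
#'
#' @param nCells number of cells (>= 1).
#' @param cellDiameter cell diameter (any length unit).
#' @param packingFraction target packing fraction phi in [0.45, 0.70];
#'   default 0.60 (loose random packing).
#' @param seed integer RNG seed (NULL: use the current stream).
#' @param slack fractional radius slack of the confining ball.
#' @return a \code{\linkS4class{Cyst3D}}.
#' @examples
#' cyst <- packCyst(32, seed = 1)
#' ballRadius(cyst)
#' largestSectionCount(cyst)$count
#' @export
packCyst <- function(nCells, cellDiameter = 1, packingFraction = 0.60,
                     seed = NULL, slack = 0.02) {
  stopifnot(nCells >= 1)
  if (packingFraction < 0.45 || packingFraction > 0.70)
    stopWithClass("infeasiblePackingError",
                  "packingFraction %.2f outside [0.45, 0.70]", packingFraction)
  n <- as.integer(nCells); d <- cellDiameter
  R <- (n / packingFraction)^(1/3) * d / 2 * (1 + slack)
  if (n == 1L)
    return(new("Cyst3D", nCells = 1L, cellDiameter = d,
               centers = matrix(0, 1, 3), ballRadius = d / 2,
               packingFraction = packingFraction))
  R <- max(R, d)   # a pair of kissing cells needs at least radius d
  if (n == 2L)
    ## the kissing pair is the exact minimal configuration: centers d apart
    ## on a uniformly random axis through the origin
    return(withSeed(seed, {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      new("Cyst3D", nCells = 2L, cellDiameter = d,
          centers = rbind(u * d / 2, -u * d / 2), ballRadius = d,
          packingFraction = packingFraction)
    }))
  withSeed(seed, {
    rc <- R - d / 2
    res <- NULL
    for (attempt in 1:3) {
      init <- runifBall(n, max(rc, (n / 0.20)^(1/3) * d / 2 - d / 2))
      res <- .pack_relax(init, d, rc)
      if (res$ok) break
    }
    if (is.null(res) || !res$ok)
      stopWithClass("infeasiblePackingError",
        "could not pack %d cells at packing fraction %.2f", n, packingFraction)
    ## when the random packing jams before the nominal density is reached,
    ## the achieved (jamming) radius defines the cyst ball
    new("Cyst3D", nCells = n, cellDiameter = d, centers = res$X,
        ballRadius = max(R, res$rachieved + d / 2),
        packingFraction = packingFraction)
  })
}

#' Count cells on the largest planar section
#'
#' A cell is in a section when its sphere intersects the cutting plane,
#' i.e. \code{|center_z - plane_z| < cellDiameter / 2}. The count is
#' maximized exactly by sweeping the finite set of critical plane positions
#' (every center z offset by half a diameter).
#'
#' @param cyst a \code{\linkS4class{Cyst3D}}.
#' @return list with \code{plane_z} (a maximizing plane) and \code{count}.
#' @export
largestSectionCount <- function(cyst) {
  z <- cystCenters(cyst)[, 3]
  h <- cyst@cellDiameter / 2
  eps <- 1e-9 * cyst@cellDiameter
  cand <- sort(unique(c(z, z - h + eps, z + h - eps)))
  counts <- vapply(cand, function(p) sum(abs(z - p) < h), 0L)
  i <- which.max(counts)
  list(plane_z = cand[i], count = as.integer(counts[i]))
}

#' Simulate largest-section counts over many cysts
#'
#' @param nCells cells per cyst.
#' @param reps number of independent cysts.
#' @param packingFraction target packing fraction.
#' @param seed base seed; cyst r uses seed + r.
#' @param cellDiameter cell diameter.
#' @return integer vector of per-cyst largest-section counts.
#' @export
simulateSectionCounts <- function(nCells, reps, packingFraction = 0.60,
                                  seed = 1L, cellDiameter = 1) {
  vapply(seq_len(reps), function(r) {
    cyst <- packCyst(nCells, cellDiameter, packingFraction, seed = seed + r)
    largestSectionCount(cyst)$count
  }, 0L)
}

#' Analytic expectation of the largest-section count
#'
#' Uniform-density slab expectation: treating the n cells as uniformly
#' distributed in the nominal minimal ball of radius
#' \code{R = (n / phi)^(1/3) * d / 2}, the expected number of cells whose
#' sphere intersects a central plane is
#' \code{n * integral(|z| < d/2) pi (R^2 - z^2) dz / (4/3 pi R^3)},
#' clipped to [1, n]. This closed form serves as an independent oracle for
#' the packing simulation; it ignores the wall layering of real packings,
#' which inflates central-section counts at small n (see vignette).
#'
#' @param nCells cells per cyst.
#' @param packingFraction packing fraction phi.
#' @param cellDiameter cell diameter d.
#' @return expected count (numeric).
#' @examples
#' expectedSectionCount(32, 0.64)   # ~12.7
#' @export
expectedSectionCount <- function(nCells, packingFraction = 0.60,
                                 cellDiameter = 1) {
  n <- nCells; d <- cellDiameter
  if (n < 1) stop("nCells must be >= 1")
  R <- (n / packingFraction)^(1/3) * d / 2
  e <- n * 3 * (R^2 * d - d^3 / 12) / (4 * R^3)
  min(max(e, 1), n)
}

#' Infer the clonal generation from an observed largest-section count
#'
#' Picks the power of two in {1, 2, ..., 256} whose expected largest-section
#' count (\code{\link{expectedSectionCount}}) is nearest the observation,
#' and maps it to the spermatogonial class: 1 cell = SPG-A(1-cell), 2-8 =
#' SPG-A(2,4,8-cell), 16-32 = SPG-B(16,32-cell), 64-256 =
#' SPG-B(64,128,256-cell).
#'
#' @param observedCount observed mean largest-section count (>= 1).
#' @param packingFraction packing fraction used for the expectation.
#' @return list with \code{nearest_n}, \code{label} and \code{candidates}
#'   (the expectation table).
#' @examples
#' inferGeneration(14.3)$nearest_n   # 32
#' inferGeneration(54.9)$nearest_n   # 256
#' @export
inferGeneration <- function(observedCount, packingFraction = 0.60) {
  stopifnot(observedCount >= 1)
  expect <- vapply(.GENERATION_SET, expectedSectionCount,
                   0, packingFraction = packingFraction)
  i <- which.min(abs(expect - observedCount))
  list(nearest_n = .GENERATION_SET[i],
       label = .generationLabel(.GENERATION_SET[i]),
       candidates = data.frame(n = .GENERATION_SET, expected_count = expect))
}

#' Unpaired two-tailed Student's t-test between two groups
#'
#' Classical pooled-variance (equal-variance) t statistic with
#' \code{n_a + n_b - 2} degrees of freedom, as conventionally used for
#' comparing cyst-section counts between classes; Welch's correction is
#' available by flag. Degenerate case: when the pooled variance is zero the
#' p-value is 1 for equal means and 0 otherwise (documented convention).
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param welch use Welch's unequal-variance test instead.
#' @param alpha significance level for the convenience flag.
#' @return list with \code{t}, \code{p}, \code{df}, \code{significant}.
#' @examples
#' compareGroups(c(1, 2, 3), c(1, 2, 3, 4))
#' @export
compareGroups <- function(a, b, welch = FALSE, alpha = 0.05) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else Inf, p = if (equal) 1 else 0,
                df = length(a) + length(b) - 2, significant = !equal))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), significant = ht$p.value < alpha)
}
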