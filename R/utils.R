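## Internal helpers shared across modules.

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG stream. seed = NULL uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Normal draw truncated symmetrically at +/- trunc sd (keeps the mean).
rnormTrunc <- function(n, mean, sd, trunc = 2) {
  if (sd <= 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > trunc * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > trunc * sd
  }
  x
}

## Uniform points in a 3D ball of given radius.
runifBall <- function(n, radius) {
  X <- matrix(0, n, 3)
  m <- 0L
  while (m < n) {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) { m <- m + 1L; X[m, ] <- p }
  }
  X
}

## Closed polygon length.
polygonLength <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

## Sub-pixel boundary perimeter of a binary mask (pixels, row = y, col = x).
## The mask is lightly blurred so the 0.5 iso-contour localizes the boundary
## between pixel centers; a raw marching-squares contour of a binary disc
## overestimates a circle's perimeter by ~5%, the blurred contour by < 1%.
maskPerimeter <- function(mask, smoothSigmaPx = 1) {
  pad <- ceiling(3 * smoothSigmaPx) + 1L
  z <- matrix(0, nrow(mask) + 2L * pad, ncol(mask) + 2L * pad)
  z[pad + seq_len(nrow(mask)), pad + seq_len(ncol(mask))] <- mask * 1.0
  if (smoothSigmaPx > 0)
    z <- gaussBlur(z, smoothSigmaPx)
  cl <- contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                     z = z, levels = 0.5)
  if (!length(cl)) return(0)
  sum(vapply(cl, function(c) polygonLength(c$x, c$y), 0))
}

## Separable Gaussian blur on a plain matrix (replicate-padded).
gaussBlur <- function(m, sigma) {
  k <- ceiling(3 * sigma)
  g <- stats::dnorm(-k:k, sd = sigma)
  g <- g / sum(g)
  conv1 <- function(v) {
    p <- c(rep(v[1], k), v, rep(v[length(v)], k))
    stats::filter(p, g, sides = 2)[(k + 1):(k + length(v))]
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

## Angular separation in degrees between two angles given in degrees.
angleSep <- function(a, b) {
  d <- abs((a - b) %% 360)
  ifelse(d > 180, 360 - d, d)
}

## Signed-area fraction of a disc beyond the chord at normalized distance t
## from the center (t in [-1, 1]); used to convert stripe coverage targets
## into chord offsets and back.
discSegmentArea <- function(t) (acos(t) - t * sqrt(pmax(0, 1 - t^2))) / pi

## Inverse of discSegmentArea: chord offset giving target coverage.
chordForCoverage <- function(coverage) {
  f <- function(t) discSegmentArea(t) - coverage
  stats::uniroot(f, c(-1 + 1e-9, 1 - 1e-9), tol = 1e-9)$root
}

## Stop with a classed error (testable with expect_error(class = ...)).
stopWithClass <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
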