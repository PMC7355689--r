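# Shared helpers: coordinate conventions, seeded evaluation, small numerics.
#
# Pixel convention used throughout the package: 0-based integer pixel centers,
# origin at the top-left corner, x rightward (matrix column - 1), y downward
# (matrix row - 1). Boxes are c(x, y, w, h) and half-open:
# [x, x + w) x [y, y + h). Masks are logical h x w matrices, or equivalently
# integer vectors of column-major matrix indices.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded internals never
#' perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## mask index <-> 0-based pixel coordinates (column-major, h rows)
idxToX <- function(idx, h) (idx - 1L) %/% h
idxToY <- function(idx, h) (idx - 1L) %% h
xyToIdx <- function(x, y, h) as.integer(x) * h + as.integer(y) + 1L

#' Tight bounding box of a pixel-index mask
#' @param idx Integer vector of column-major indices into an h x w matrix.
#' @param h Frame height in pixels.
#' @return Numeric c(x, y, w, h), half-open, 0-based.
#' @keywords internal
boxFromMaskIdx <- function(idx, h) {
  x <- idxToX(idx, h); y <- idxToY(idx, h)
  c(min(x), min(y), max(x) - min(x) + 1, max(y) - min(y) + 1)
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) v else v / n
}

#' Cosine distance between two vectors
#' @keywords internal
cosineDist <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

## maximal runs of TRUE in a logical vector -> data.frame(from, to) (1-based)
trueRuns <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from = starts[keep], to = ends[keep])
}

## vectorized HSV -> RGB on numeric vectors in [0,1] (h in [0,1) wraps)
hsv2rgbMat <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

## deterministic, translation-covariant pseudo-noise in [0,1]
hashNoise <- function(a, b, salt = 0) {
  x <- sin(a * 12.9898 + b * 78.233 + salt * 37.719) * 43758.5453
  x - floor(x)
}
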