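#' @include utils.R
NULL

asMaskIdx <- function(mask, h = NULL, w = NULL) {
  if (is.matrix(mask)) {
    list(idx = which(mask != 0), h = nrow(mask), w = ncol(mask))
  } else {
    stopifnot(!is.null(h), !is.null(w))
    list(idx = as.integer(mask), h = h, w = w)
  }
}

#' Localize the instrument tip in a mask
#'
#' The trajectory of an instrument must follow its tip, not its box center.
#' When the mask touches an image border (the usual case: the shaft enters
#' from outside the view), the tip is the mask pixel with maximal Euclidean
#' distance from the centroid of the border-contact pixels. Otherwise the
#' tip is the extreme pixel along the mask's major principal axis, on the
#' end with the smaller perpendicular width. Ties break deterministically
#' (smallest y, then smallest x).
#'
#' @param mask Logical/0-1 matrix, or an integer index vector with `h`, `w`.
#' @param h,w Frame dimensions when `mask` is an index vector.
#' @return Numeric c(x, y), 0-based pixel coordinates inside the mask.
#' @export
detectTip <- function(mask, h = NULL, w = NULL) {
  m <- asMaskIdx(mask, h, w)
  if (length(m$idx) == 0) stop("empty mask")
  x <- idxToX(m$idx, m$h); y <- idxToY(m$idx, m$h)
  onBorder <- x == 0 | x == m$w - 1 | y == 0 | y == m$h - 1
  if (any(onBorder)) {
    cx <- mean(x[onBorder]); cy <- mean(y[onBorder])
    d2 <- (x - cx)^2 + (y - cy)^2
    ord <- order(-d2, y, x)
    return(c(x = x[ord[1]], y = y[ord[1]]))
  }
  # interior mask: extreme pixel along the major principal axis on the
  # narrower end
  mx <- mean(x); my <- mean(y)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  s <- (x - mx) * axis[1] + (y - my) * axis[2]
  q <- abs(-(x - mx) * axis[2] + (y - my) * axis[1])
  rng <- range(s)
  span <- diff(rng)
  nearHi <- s >= rng[2] - max(1, 0.15 * span)
  nearLo <- s <= rng[1] + max(1, 0.15 * span)
  hiWidth <- if (any(nearHi)) stats::median(q[nearHi]) else Inf
  loWidth <- if (any(nearLo)) stats::median(q[nearLo]) else Inf
  sgn <- if (hiWidth <= loWidth) 1 else -1
  ss <- sgn * s
  ord <- order(-ss, y, x)
  c(x = x[ord[1]], y = y[ord[1]])
}

#' Measure the shaft width of an elongated mask
#'
#' Median extent of the mask perpendicular to its major principal axis,
#' sampled along the shaft (one sample per axial pixel bin). Requires an
#' elongated mask (major/minor extent ratio >= 2); call again on a later
#' frame otherwise.
#'
#' @inheritParams detectTip
#' @return Shaft width in pixels.
#' @export
measureShaftWidth <- function(mask, h = NULL, w = NULL) {
  m <- asMaskIdx(mask, h, w)
  if (length(m$idx) == 0) stop("empty mask")
  x <- idxToX(m$idx, m$h); y <- idxToY(m$idx, m$h)
  mx <- mean(x); my <- mean(y)
  cv <- stats::cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  s <- (x - mx) * axis[1] + (y - my) * axis[2]
  q <- -(x - mx) * axis[2] + (y - my) * axis[1]
  if (diff(range(s)) < 2 * diff(range(q)))
    stop("mask not elongated enough to measure shaft width")
  bin <- round(s)
  ext <- tapply(q, bin, function(v) diff(range(v)) + 1)
  counts <- tapply(q, bin, length)
  ext <- ext[counts >= 3]
  if (length(ext) == 0) stop("mask too small to measure shaft width")
  as.numeric(stats::median(ext))
}

#' Pixel-to-millimetre calibration
#'
#' The instrument shaft has a known physical width of 8 mm; measuring its
#' on-screen width in pixels fixes the metric scale of the whole view by
#' proportionality. The calibration is measured once (on the first
#' qualifying frames) and held constant for the video; zoom changes during
#' a video are a documented error source.
#'
#' @param shaftWidthPx Measured shaft width in pixels (> 0).
#' @param shaftWidthMm Physical shaft width (default 8 mm).
#' @return List(shaftWidthPx, shaftWidthMm, mmPerPx).
#' @export
makeCalibration <- function(shaftWidthPx, shaftWidthMm = 8) {
  stopifnot(shaftWidthPx > 0, shaftWidthMm > 0)
  list(shaftWidthPx = shaftWidthPx, shaftWidthMm = shaftWidthMm,
       mmPerPx = shaftWidthMm / shaftWidthPx)
}

#' Calibrate a trajectory from pixels to millimetres
#'
#' Linear scaling of coordinates (and hence all derived displacements) by
#' the calibration's mm-per-px factor; adds/overwrites `x_mm`, `y_mm`.
#'
#' @param trajectory data.frame with `x_px`, `y_px` columns.
#' @param calibration A calibration from [makeCalibration()].
#' @return The trajectory with millimetre coordinates.
#' @export
calibrateTrajectory <- function(trajectory, calibration) {
  stopifnot(calibration$mmPerPx > 0)
  trajectory$x_mm <- trajectory$x_px * calibration$mmPerPx
  trajectory$y_mm <- trajectory$y_px * calibration$mmPerPx
  trajectory
}

#' Estimate the calibration from detections
#'
#' Measures the shaft width on up to `maxFrames` qualifying (sufficiently
#' elongated) masks, takes the median and rounds to the nearest pixel (the
#' on-screen width is an integer number of pixels).
#'
#' @param detections Flat list of detections.
#' @param shaftWidthMm Physical shaft width.
#' @param maxFrames Number of qualifying masks to aggregate.
#' @return A calibration, or NULL when no mask qualifies.
#' @export
calibrateFromDetections <- function(detections, shaftWidthMm = 8,
                                    maxFrames = 10) {
  widths <- numeric(0)
  for (d in detections) {
    wpx <- tryCatch(measureShaftWidth(d$maskIdx, d$h, d$w),
                    error = function(e) NA_real_)
    if (!is.na(wpx)) widths <- c(widths, wpx)
    if (length(widths) >= maxFrames) break
  }
  if (length(widths) == 0) return(NULL)
  makeCalibration(round(stats::median(widths)), shaftWidthMm)
}
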