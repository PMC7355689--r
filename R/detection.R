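#' @include sceneSim.R
NULL

#' Construct a detection
#'
#' A detection is one instrument candidate in one frame: a tight bounding
#' box, a binary mask and a confidence. Detections carry no class label;
#' instrument identity is assigned exclusively by the tracker and the
#' re-identification cascade.
#'
#' @param frame Frame index (1-based).
#' @param maskIdx Integer vector of column-major mask pixel indices.
#' @param h,w Frame height/width in pixels.
#' @param confidence Numeric in \[0, 1\].
#' @return A `detection` list (frame, box, maskIdx, h, w, confidence).
#' @export
makeDetection <- function(frame, maskIdx, h, w, confidence = 1) {
  stopifnot(length(maskIdx) > 0, confidence >= 0, confidence <= 1)
  box <- boxFromMaskIdx(maskIdx, h)
  structure(list(frame = frame, box = box, maskIdx = as.integer(maskIdx),
                 h = as.integer(h), w = as.integer(w),
                 confidence = confidence), class = "detection")
}

#' Detection noise configuration
#'
#' Controls the corruption applied by [oracleDetect()], emulating the failure
#' modes of real instance segmentation: box/mask jitter, missed detections,
#' spurious components, and merging of overlapping instruments into a single
#' fused detection.
#'
#' @param boxJitterSd Per-axis Gaussian translation jitter s.d. (px); the
#'   mask is shifted by the rounded offset.
#' @param missRate Probability a visible instrument is not detected.
#' @param falsePositiveRate Expected spurious detections per frame (Poisson).
#' @param mergeOnOcclusion If TRUE, overlapping ground-truth instruments are
#'   emitted as one fused detection (union mask, hull box).
#' @param confidenceBase,confidenceJitter Confidence model: base minus a
#'   small penalty per px of applied jitter, plus Gaussian noise, clamped to
#'   \[0.05, 1\].
#' @param seed Integer; detection noise is reproducible per frame.
#' @return A `noiseConfig` list.
#' @export
noiseConfig <- function(boxJitterSd = 0, missRate = 0, falsePositiveRate = 0,
                        mergeOnOcclusion = FALSE, confidenceBase = 1,
                        confidenceJitter = 0, seed = 1L) {
  stopifnot(boxJitterSd >= 0, missRate >= 0, missRate <= 1,
            falsePositiveRate >= 0)
  list(boxJitterSd = boxJitterSd, missRate = missRate,
       falsePositiveRate = falsePositiveRate,
       mergeOnOcclusion = mergeOnOcclusion,
       confidenceBase = confidenceBase, confidenceJitter = confidenceJitter,
       seed = as.integer(seed))
}

shiftMaskIdx <- function(idx, h, w, dx, dy) {
  x <- idxToX(idx, h) + dx
  y <- idxToY(idx, h) + dy
  keep <- x >= 0 & x < w & y >= 0 & y < h
  if (!any(keep)) return(integer(0))
  xyToIdx(x[keep], y[keep], h)
}

#' Ground-truth-backed detector with configurable corruption
#'
#' Emits the scene's ground-truth masks/boxes as detections. At zero noise
#' the detections equal the ground truth with confidence 1; the noise model
#' adds translation jitter, misses, false positives and occlusion merging.
#' Masks are amodal (an occluded instrument still yields its full
#' silhouette), mirroring an ideal instance-segmentation stage.
#'
#' @param scene A [Scene-class].
#' @param frameIndex Frame (1-based).
#' @param noise A [noiseConfig()].
#' @return List of detections (possibly empty).
#' @export
oracleDetect <- function(scene, frameIndex, noise = noiseConfig()) {
  stopifnot(frameIndex >= 1, frameIndex <= nFrames(scene))
  st <- scene@truth
  h <- scene@config@height; w <- scene@config@width
  frameSeed <- (noise$seed + frameIndex * 7919L) %% .Machine$integer.max
  withSeed(frameSeed, {
    vis <- which(st$visible[frameIndex, ])
    masks <- lapply(vis, function(i) st$maskIdx[[i]][[frameIndex]])

    if (noise$mergeOnOcclusion && length(masks) > 1) {
      # union-find over pairwise mask overlaps
      grp <- seq_along(masks)
      for (a in seq_along(masks)) for (b in seq_along(masks)) {
        if (a < b && length(intersect(masks[[a]], masks[[b]])) > 0)
          grp[grp == grp[b]] <- grp[a]
      }
      masks <- lapply(unique(grp), function(g)
        sort(unique(unlist(masks[grp == g]))))
    }

    dets <- list()
    for (m in masks) {
      if (noise$missRate > 0 && stats::runif(1) < noise$missRate) next
      jit <- c(0, 0)
      if (noise$boxJitterSd > 0) {
        jit <- round(stats::rnorm(2, 0, noise$boxJitterSd))
        m <- shiftMaskIdx(m, h, w, jit[1], jit[2])
        if (length(m) == 0) next
      }
      conf <- clamp(noise$confidenceBase - 0.01 * sqrt(sum(jit^2)) +
                      (if (noise$confidenceJitter > 0)
                        stats::rnorm(1, 0, noise$confidenceJitter) else 0),
                    0.05, 1)
      dets[[length(dets) + 1]] <- makeDetection(frameIndex, m, h, w, conf)
    }

    nFp <- if (noise$falsePositiveRate > 0)
      stats::rpois(1, noise$falsePositiveRate) else 0
    for (k in seq_len(nFp)) {
      cx <- stats::runif(1, 10, w - 10); cy <- stats::runif(1, 10, h - 10)
      rx <- stats::runif(1, 5, 14); ry <- stats::runif(1, 5, 14)
      xs <- max(0, floor(cx - rx)):min(w - 1, ceiling(cx + rx))
      ys <- max(0, floor(cy - ry)):min(h - 1, ceiling(cy + ry))
      px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
      keep <- ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1
      if (sum(keep) < 4) next
      dets[[length(dets) + 1]] <- makeDetection(
        frameIndex, xyToIdx(px[keep], py[keep], h), h, w,
        clamp(stats::runif(1, 0.3, 0.8), 0.05, 1))
    }
    dets
  })
}

#' Classical color/shape segmenter
#'
#' Classifies pixels by channel ratio: tissue is strongly red-dominant,
#' instruments are not (blue/green or metallic-gray), so a pixel is
#' foreground when its green or blue channel exceeds `channelRatio` times
#' its red channel -- a brightness-invariant rule that survives shading
#' along the shaft. Each connected component above the minimum area becomes
#' one detection; confidence is the component's fill ratio (area / box
#' area).
#'
#' @param frame RGB array `h x w x 3`.
#' @param params List: `channelRatio` (default 0.6) and `minArea`
#'   (px, default 200 -- comfortably above the fixed indicator overlays).
#' @return List of detections (possibly empty).
#' @export
colorSegment <- function(frame, params = list()) {
  ratio <- params$channelRatio %||% 0.6
  minArea <- params$minArea %||% 200
  h <- dim(frame)[1]; w <- dim(frame)[2]
  fg <- frame[, , 2] > ratio * frame[, , 1] |
    frame[, , 3] > ratio * frame[, , 1]
  if (!any(fg)) return(list())
  lab <- EBImage::bwlabel(fg)
  dets <- list()
  for (g in seq_len(max(lab))) {
    idx <- which(lab == g)
    if (length(idx) < minArea) next
    box <- boxFromMaskIdx(idx, h)
    dets[[length(dets) + 1]] <- makeDetection(
      NA_integer_, idx, h, w,
      clamp(length(idx) / (box[3] * box[4]), 0.05, 1))
  }
  dets
}

#' Non-maximum suppression
#'
#' Greedy suppression in descending confidence (ties broken by smaller list
#' index): a detection is dropped when its box IOU with an already-kept
#' detection reaches the threshold. The final bounding boxes are selected
#' from among the candidates this way before tracking.
#'
#' @param detections List of detections from a single frame.
#' @param iouThreshold Numeric in \[0, 1\].
#' @return Surviving detections, sorted by descending confidence.
#' @export
nmsFilter <- function(detections, iouThreshold = 0.5) {
  if (iouThreshold < 0 || iouThreshold > 1)
    stop("iouThreshold must lie in [0, 1]")
  if (length(detections) <= 1) return(detections)
  conf <- vapply(detections, `[[`, numeric(1), "confidence")
  ord <- order(-conf, seq_along(detections))
  keep <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in keep) {
      if (boxIou(detections[[i]]$box, detections[[j]]$box) >= iouThreshold) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  detections[keep]
}

## --- detection serialization: JSON-lines with run-length-encoded masks ---

#' Run-length encode a mask
#'
#' Column-major RLE: alternating run lengths of background and foreground
#' pixels, starting with the (possibly zero) leading background run.
#'
#' @param idx Mask pixel indices (column-major).
#' @param h,w Frame dimensions.
#' @return Integer vector of run lengths summing to `h * w`.
#' @export
rleEncodeMask <- function(idx, h, w) {
  v <- logical(h * w)
  v[idx] <- TRUE
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1]) counts <- c(0L, counts)
  as.integer(counts)
}

#' @rdname rleEncodeMask
#' @param counts Integer run lengths as produced by `rleEncodeMask`.
#' @return `rleDecodeMask`: integer vector of mask pixel indices.
#' @export
rleDecodeMask <- function(counts, h, w) {
  stopifnot(sum(counts) == h * w)
  vals <- rep(c(FALSE, TRUE), length.out = length(counts))
  which(rep(vals, counts))
}

#' Read or write detections as JSON-lines
#'
#' One JSON record per detection: `frame`, `box` (x, y, w, h), `confidence`,
#' `h`, `w`, `rle` (see [rleEncodeMask()]).
#'
#' @param detections Flat list of detections (all frames).
#' @param path File path.
#' @return `writeDetections`: invisibly `path`; `readDetections`: flat list
#'   of detections.
#' @export
writeDetections <- function(detections, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in detections) {
    writeLines(jsonlite::toJSON(list(
      frame = d$frame, box = d$box, confidence = d$confidence,
      h = d$h, w = d$w, rle = rleEncodeMask(d$maskIdx, d$h, d$w)
    ), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    makeDetection(rec$frame, rleDecodeMask(rec$rle, rec$h, rec$w),
                  rec$h, rec$w, rec$confidence)
  })
}
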