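#' @include AllClasses.R AllGenerics.R
NULL

SHAFT_WIDTH_MM <- 8  # known physical instrument shaft width

#' Construct a synthetic scene configuration
#'
#' @param width,height Frame size in pixels.
#' @param fps Frames per second.
#' @param nFrames Number of frames.
#' @param instruments List of instrument descriptions; each element a list
#'   with `pivot` (xy, the trocar-like pivot outside the view), `armSide`
#'   ("left"/"right"), `hue` in \[0,1), and either `path` (nFrames x 2 matrix
#'   of tip positions, px) or `waypoints` (matrix frame/x/y, spline-interpolated).
#' @param shaftWidthPx Rendered shaft width (px).
#' @param tipLengthPx Length of the tapered tip wedge (px).
#' @param exitEvents,cameraEvents,activeIntervals Event tables; see
#'   [SceneConfig-class].
#' @param seed Integer seed driving all scene randomness.
#' @return A validated [SceneConfig-class].
#' @export
sceneConfig <- function(width = 320, height = 240, fps = 23, nFrames = 100,
                        instruments,
                        shaftWidthPx = 16, tipLengthPx = 14,
                        exitEvents = noEvents(instrument = TRUE),
                        cameraEvents = noEvents(camera = TRUE),
                        activeIntervals = noEvents(instrument = TRUE),
                        seed = 1L) {
  new("SceneConfig", width = as.integer(width), height = as.integer(height),
      fps = fps, nFrames = as.integer(nFrames),
      shaftWidthPx = shaftWidthPx, tipLengthPx = tipLengthPx,
      instruments = instruments, exitEvents = exitEvents,
      cameraEvents = cameraEvents, activeIntervals = activeIntervals,
      seed = as.integer(seed))
}

#' Empty event table
#' @param instrument,camera Select the column layout.
#' @return Zero-row data.frame with the proper columns.
#' @export
noEvents <- function(instrument = FALSE, camera = FALSE) {
  if (camera)
    data.frame(from = integer(0), to = integer(0),
               dx = numeric(0), dy = numeric(0))
  else
    data.frame(instrument = integer(0), from = integer(0), to = integer(0))
}

## natural-spline interpolation of waypoints over 1..nFrames,
## constant beyond the first/last waypoint
interpPath <- function(waypoints, nFrames) {
  t0 <- waypoints[, 1]
  tq <- clamp(seq_len(nFrames), min(t0), max(t0))
  if (nrow(waypoints) == 1)
    return(cbind(rep(waypoints[1, 2], nFrames), rep(waypoints[1, 3], nFrames)))
  x <- stats::spline(t0, waypoints[, 2], xout = tq, method = "natural")$y
  y <- stats::spline(t0, waypoints[, 3], xout = tq, method = "natural")$y
  cbind(x, y)
}

## smoothstep in [0,1]
sstep <- function(x) { x <- clamp(x, 0, 1); x * x * (3 - 2 * x) }

## axis crossing: smallest t >= 0 with (apex - t*dir) outside rect
## [0, w-1] x [0, h-1]; returns t
rayExitT <- function(apex, dirv, w, h) {
  ts <- c()
  if (abs(dirv[1]) > 1e-12)
    ts <- c(ts, (apex[1] - (-1e-9)) / dirv[1], (apex[1] - (w - 1 + 1e-9)) / dirv[1])
  if (abs(dirv[2]) > 1e-12)
    ts <- c(ts, (apex[2] - (-1e-9)) / dirv[2], (apex[2] - (h - 1 + 1e-9)) / dirv[2])
  ts <- ts[ts > 0]
  if (!length(ts)) return(Inf)
  min(ts)
}

## Rasterize one instrument: capsule shaft from the pivot direction with a
## linear taper to zero width over the final tipLen px (the tip wedge).
## Returns NULL when nothing is visible; otherwise list(idx, entry, tip).
rasterInstrument <- function(apex, pivot, r, tipLen, w, h) {
  dirv <- unitize(apex - pivot)
  if (all(dirv == 0)) return(NULL)
  tExit <- rayExitT(apex, dirv, w, h)
  if (!is.finite(tExit)) return(NULL)
  pExit <- apex - tExit * dirv
  xr <- clamp(c(floor(min(apex[1], pExit[1]) - r - 2),
                ceiling(max(apex[1], pExit[1]) + r + 2)), 0, w - 1)
  yr <- clamp(c(floor(min(apex[2], pExit[2]) - r - 2),
                ceiling(max(apex[2], pExit[2]) + r + 2)), 0, h - 1)
  xs <- xr[1]:xr[2]; ys <- yr[1]:yr[2]
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  rx <- apex[1] - px; ry <- apex[2] - py
  s <- rx * dirv[1] + ry * dirv[2]          # axial distance back from apex
  q <- rx * dirv[2] - ry * dirv[1]          # signed perpendicular offset
  # half-open band [-r, r): an axis-aligned shaft rasterizes to exactly
  # shaftWidthPx rows/columns, so the metric calibration is recoverable
  inside <- (s >= tipLen & q >= -r & q < r) |
    (s >= 0 & s < tipLen & q >= -r * s / tipLen & q < r * s / tipLen)
  if (!any(inside)) return(NULL)
  idx <- xyToIdx(px[inside], py[inside], h)
  ax <- round(apex[1]); ay <- round(apex[2])
  if (ax >= 0 && ax < w && ay >= 0 && ay < h)
    idx <- union(idx, xyToIdx(ax, ay, h))
  # ground-truth tip: the mask pixel farthest from the exact shaft-entry
  # point on the border (deterministic tie-break: smallest y, then x)
  tx <- idxToX(idx, h); ty <- idxToY(idx, h)
  d2 <- (tx - pExit[1])^2 + (ty - pExit[2])^2
  ord <- order(-d2, ty, tx)
  tip <- c(tx[ord[1]], ty[ord[1]])
  list(idx = idx, entry = pExit, tip = tip)
}

cameraOffsets <- function(cameraEvents, nFrames) {
  off <- matrix(0L, nFrames, 2)
  moving <- rep(FALSE, nFrames)
  for (k in seq_len(nrow(cameraEvents))) {
    ev <- cameraEvents[k, ]
    t <- ev$from:ev$to
    u <- if (ev$to > ev$from) (t - ev$from) / (ev$to - ev$from) else rep(0.5, length(t))
    off[t, 1] <- off[t, 1] + as.integer(round(ev$dx * sin(pi * u)^2))
    off[t, 2] <- off[t, 2] + as.integer(round(ev$dy * sin(pi * u)^2))
    moving[t] <- TRUE
  }
  list(offset = off, moving = moving)
}

smoothField <- function(h, w, passes = 3, k = 9) {
  m <- matrix(stats::runif(h * w), h, w)
  kern <- rep(1 / k, k)
  for (p in seq_len(passes)) {
    m <- apply(m, 2, function(col) as.numeric(
      stats::filter(col, kern, sides = 2, circular = TRUE)))
    m <- t(apply(m, 1, function(row) as.numeric(
      stats::filter(row, kern, sides = 2, circular = TRUE))))
  }
  (m - min(m)) / max(1e-9, diff(range(m)))
}

#' Generate a synthetic surgical scene with ground truth
#'
#' Realizes a [SceneConfig-class]: instrument tip paths (splined waypoints or
#' explicit paths), scheduled exits (the tip slides out past its entry border
#' and back), out-and-back camera translations, per-frame instrument masks,
#' tight bounding boxes, ground-truth tip pixels, visibility flags and the
#' active-arm schedule. Deterministic for a fixed seed: generating the same
#' configuration twice yields byte-identical frames and ground truth.
#'
#' @param config A [SceneConfig-class].
#' @return A [Scene-class]; frames render on demand via [renderFrame()].
#' @export
generateScene <- function(config) {
  validObject(config)
  w <- config@width; h <- config@height; n <- config@nFrames
  nInstr <- length(config@instruments)
  r <- config@shaftWidthPx / 2
  tipLen <- config@tipLengthPx

  paths <- vector("list", nInstr)
  for (i in seq_len(nInstr)) {
    ins <- config@instruments[[i]]
    paths[[i]] <- if (!is.null(ins$path)) {
      stopifnot(nrow(ins$path) == n)
      as.matrix(ins$path)
    } else interpPath(as.matrix(ins$waypoints), n)
  }

  # exit events: the tip retracts along its shaft toward the entry border
  # (easing out, so the last visible steps are slow), is pulled fully out,
  # dwells off-view, snaps back to a near-border hold point (where it rests
  # long enough for a tracker to re-acquire it), then rejoins its path
  ex <- config@exitEvents
  for (k in seq_len(nrow(ex))) {
    i <- ex$instrument[k]; f1 <- ex$from[k]; f2 <- ex$to[k]
    T <- f2 - f1 + 1
    pivot <- config@instruments[[i]]$pivot
    alongShaft <- function(apex, depth) {
      # point `depth` px inside (depth > 0) or outside (depth < 0) the
      # border, along the shaft axis through `apex`
      dirv <- unitize(apex - pivot)
      tExit <- rayExitT(apex, dirv, w, h)
      if (!is.finite(tExit)) tExit <- max(w, h)
      apex - (tExit - depth) * dirv
    }
    outDepth <- -(3 * r + tipLen + 5)
    if (T < 20) {
      outPoint <- alongShaft(paths[[i]][f1, ], outDepth)
      ramp <- max(2, floor(T / 3))
      for (t in f1:f2) {
        b <- sstep(min(1, (t - f1) / ramp, (f2 - t) / ramp))
        paths[[i]][t, ] <- (1 - b) * paths[[i]][t, ] + b * outPoint
      }
    } else {
      holdN <- max(3, min(6, round(0.1 * T)))
      r1 <- f1 + max(6, round(0.30 * T))
      r3 <- f2 - max(6, round(0.22 * T)) - holdN - 2
      inA <- alongShaft(paths[[i]][f1, ], 8)
      outA <- alongShaft(paths[[i]][f1, ], outDepth)
      inB <- alongShaft(paths[[i]][f2, ], 8)
      outB <- alongShaft(paths[[i]][f2, ], outDepth)
      anchors <- rbind(c(f1, paths[[i]][f1, ]), c(r1, inA),
                       c(r1 + 2, outA), c(r3, outB), c(r3 + 2, inB),
                       c(r3 + 2 + holdN, inB), c(f2, paths[[i]][f2, ]))
      paths[[i]][f1:f2, ] <- holdGlidePath(anchors, n)[f1:f2, ]
    }
  }

  cam <- cameraOffsets(config@cameraEvents, n)

  active <- matrix(FALSE, n, nInstr)
  ai <- config@activeIntervals
  for (k in seq_len(nrow(ai)))
    active[ai$from[k]:ai$to[k], ai$instrument[k]] <- TRUE

  appearance <- withSeed(config@seed, lapply(seq_len(nInstr), function(i) {
    list(phase = stats::runif(1, 0, 2 * pi), salt = stats::runif(1, 1, 100),
         freq = stats::runif(1, 0.03, 0.10))
  }))
  pad <- as.integer(max(10, if (nrow(config@cameraEvents))
    max(abs(config@cameraEvents$dx), abs(config@cameraEvents$dy)) + 10 else 10))
  field <- withSeed(config@seed + 1L, smoothField(h + 2 * pad, w + 2 * pad))
  background <- array(0, c(h + 2 * pad, w + 2 * pad, 3))
  background[, , 1] <- 0.30 + 0.25 * field
  background[, , 2] <- 0.12 + 0.10 * field
  background[, , 3] <- 0.12 + 0.08 * field

  tip <- lapply(seq_len(nInstr), function(i) matrix(NA_real_, n, 2))
  apexView <- lapply(seq_len(nInstr), function(i) matrix(NA_real_, n, 2))
  boxes <- lapply(seq_len(nInstr), function(i) matrix(NA_real_, n, 4))
  maskIdx <- lapply(seq_len(nInstr), function(i) vector("list", n))
  visible <- matrix(FALSE, n, nInstr)

  for (t in seq_len(n)) {
    off <- cam$offset[t, ]
    for (i in seq_len(nInstr)) {
      apex <- paths[[i]][t, ] - off
      pivot <- config@instruments[[i]]$pivot - off
      apexView[[i]][t, ] <- apex
      if (apex[1] < 0 || apex[1] > w - 1 || apex[2] < 0 || apex[2] > h - 1)
        next
      ras <- rasterInstrument(apex, pivot, r, tipLen, w, h)
      if (is.null(ras) || length(ras$idx) < 30) next
      visible[t, i] <- TRUE
      maskIdx[[i]][[t]] <- ras$idx
      boxes[[i]][t, ] <- boxFromMaskIdx(ras$idx, h)
      tip[[i]][t, ] <- ras$tip
    }
  }

  armSide <- vapply(config@instruments, function(ins)
    ins$armSide %||% "left", character(1))

  truth <- list(
    tip = tip, apex = apexView, boxes = boxes, maskIdx = maskIdx,
    visible = visible, cameraMoving = cam$moving, cameraOffset = cam$offset,
    active = active, armSide = armSide,
    mmPerPx = SHAFT_WIDTH_MM / config@shaftWidthPx,
    appearance = appearance, pivots = lapply(config@instruments, `[[`, "pivot"),
    scheduled = list(exitEvents = config@exitEvents,
                     cameraEvents = config@cameraEvents,
                     activeIntervals = config@activeIntervals)
  )
  new("Scene", config = config, truth = truth, background = background,
      templates = makeIndicatorTemplates(w, h), pad = pad)
}

#' @rdname renderFrame
#' @export
setMethod("renderFrame", "Scene", function(x, i) {
  cfg <- x@config
  w <- cfg@width; h <- cfg@height
  stopifnot(i >= 1, i <= cfg@nFrames)
  off <- x@truth$cameraOffset[i, ]
  pad <- x@pad
  rows <- (pad + 1 + off[2]):(pad + h + off[2])
  cols <- (pad + 1 + off[1]):(pad + w + off[1])
  frame <- x@background[rows, cols, , drop = FALSE]
  r <- cfg@shaftWidthPx / 2
  tipLen <- cfg@tipLengthPx
  npx <- h * w
  for (k in seq_along(cfg@instruments)) {
    if (!x@truth$visible[i, k]) next
    idx <- x@truth$maskIdx[[k]][[i]]
    apex <- x@truth$apex[[k]][i, ]
    pivot <- x@truth$pivots[[k]] - off
    dirv <- unitize(apex - pivot)
    pxx <- idxToX(idx, h); pyy <- idxToY(idx, h)
    rx <- apex[1] - pxx; ry <- apex[2] - pyy
    s <- rx * dirv[1] + ry * dirv[2]
    q <- abs(rx * dirv[2] - ry * dirv[1])
    ap <- x@truth$appearance[[k]]
    hue <- cfg@instruments[[k]]$hue %||% ((k - 1) / 3)
    val <- 0.45 + 0.22 * sin(2 * pi * s * (ap$freq %||% 0.05) + ap$phase) +
      0.18 * (hashNoise(round(s), round(q * sign(rx * dirv[2] - ry * dirv[1])),
                        ap$salt) - 0.5)
    sat <- rep(0.65, length(s))
    isTip <- s < tipLen
    val[isTip] <- clamp(val[isTip] + 0.25, 0, 1)
    sat[isTip] <- 0.15
    rgb <- hsv2rgbMat(rep(hue, length(s)), sat, clamp(val, 0.05, 1))
    frame[idx] <- rgb[, 1]
    frame[idx + npx] <- rgb[, 2]
    frame[idx + 2 * npx] <- rgb[, 3]
  }
  st <- x@truth
  anyLeft <- any(st$active[i, ] & st$armSide == "left")
  anyRight <- any(st$active[i, ] & st$armSide == "right")
  for (tpl in x@templates) {
    drawIt <- switch(tpl$kind,
                     instrument_arm_left = anyLeft,
                     instrument_arm_right = anyRight,
                     camera_arm = st$cameraMoving[i])
    if (drawIt) frame <- drawTemplate(frame, tpl)
  }
  frame
})

drawTemplate <- function(frame, tpl) {
  th <- dim(tpl$image)[1]; tw <- dim(tpl$image)[2]
  x0 <- tpl$pos[1]; y0 <- tpl$pos[2]
  frame[(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw), ] <- tpl$image
  frame
}

#' Export scene frames as PNG files
#' @param scene A [Scene-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths (frame_000001.png ...).
#' @export
exportFrames <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nFrames(scene))
  for (i in seq_len(nFrames(scene))) {
    paths[i] <- file.path(dir, sprintf("frame_%06d.png", i))
    png::writePNG(renderFrame(scene, i), paths[i])
  }
  invisible(paths)
}

#' Write scene ground truth to JSON
#'
#' Schema version 1: per-instrument tip positions, visibility, boxes and
#' run-length-encoded masks, plus the camera/active schedules and the
#' mm-per-px scale.
#'
#' @param scene A [Scene-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeGroundTruth <- function(scene, path) {
  st <- scene@truth
  h <- scene@config@height
  gt <- list(
    schema = "sitrack-gt/1",
    width = scene@config@width, height = h, fps = scene@config@fps,
    nFrames = scene@config@nFrames, mmPerPx = st$mmPerPx,
    seed = scene@config@seed,
    cameraMoving = st$cameraMoving,
    active = st$active, armSide = st$armSide,
    instruments = lapply(seq_along(st$tip), function(i) list(
      tip = st$tip[[i]], visible = st$visible[, i], box = st$boxes[[i]],
      maskRle = lapply(st$maskIdx[[i]], function(ix)
        if (is.null(ix)) NULL else rleEncodeMask(ix, h, scene@config@width))
    ))
  )
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
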