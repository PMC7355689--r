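#' @include utils.R
NULL

#' Built-in arm-indicator templates
#'
#' The robotic console overlays fixed-position indicators on the surgery
#' view: one arm-status glyph per instrument arm (left / right, shown while
#' that arm is active) and a camera-arm glyph (shown while the laparoscope
#' is being moved). Positions vary by robot model but are fixed within a
#' view, so each template is stored in advance together with its anchor
#' search region and a normalized-cross-correlation threshold.
#'
#' @param width,height View size in pixels.
#' @param size Template side in pixels.
#' @param threshold Match threshold (default 0.8).
#' @param regionPad Search-region padding around the nominal position.
#' @return List of three template lists (kind, image, pos, region,
#'   threshold).
#' @export
makeIndicatorTemplates <- function(width, height, size = 12, threshold = 0.8,
                                   regionPad = 4) {
  ii <- matrix(rep(0:(size - 1), times = size), size)   # row index (y)
  jj <- matrix(rep(0:(size - 1), each = size), size)    # col index (x)
  c0 <- (size - 1) / 2
  blank <- function() array(0.10, c(size, size, 3))
  paint <- function(img, maskM, col) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[maskM] <- col[ch]
      img[, , ch] <- plane
    }
    img
  }
  left <- blank()
  ring <- pmax(abs(ii - c0), abs(jj - c0))
  left <- paint(left, ring >= 2.5 & ring <= 4.6, c(0.10, 0.85, 0.20))
  left <- paint(left, ring <= 1.1, c(0.95, 0.95, 0.95))
  right <- blank()
  cross <- abs(ii - jj) <= 1 | abs(ii + jj - (size - 1)) <= 1
  right <- paint(right, cross, c(0.85, 0.15, 0.80))
  camera <- blank()
  rad <- sqrt((ii - c0)^2 + (jj - c0)^2)
  camera <- paint(camera, rad <= 4.6, c(0.10, 0.80, 0.85))
  camera <- paint(camera, rad <= 1.6, c(0.05, 0.10, 0.40))

  mk <- function(kind, img, pos) {
    region <- c(pos[1] - regionPad, pos[2] - regionPad,
                size + 2 * regionPad, size + 2 * regionPad)
    region[1:2] <- pmax(region[1:2], 0)
    list(kind = kind, image = img, pos = pos, region = region,
         threshold = threshold)
  }
  list(
    mk("instrument_arm_left", left, c(8L, height - size - 8L)),
    mk("instrument_arm_right", right, c(width - size - 8L, height - size - 8L)),
    mk("camera_arm", camera, c(as.integer(round((width - size) / 2)), 6L))
  )
}

#' Match an indicator template within its anchor region
#'
#' Maximum normalized cross-correlation (on grayscale) of the template over
#' every placement inside its anchor region; the indicator is present when
#' the score reaches the template's threshold. Constant windows score 0.
#'
#' @param frame RGB array.
#' @param template A template list (see [makeIndicatorTemplates()]).
#' @return List: `score` in \[0, 1\] (negative correlations clamp to 0),
#'   `present` logical.
#' @export
matchTemplate <- function(frame, template) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  reg <- template$region
  x0 <- max(0, reg[1]); y0 <- max(0, reg[2])
  x1 <- min(w, reg[1] + reg[3]); y1 <- min(h, reg[2] + reg[4])
  th <- dim(template$image)[1]; tw <- dim(template$image)[2]
  if (x1 - x0 < tw || y1 - y0 < th)
    stop("anchor region smaller than template")
  toGray <- function(a) 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  tg <- as.vector(toGray(template$image))
  if (stats::sd(tg) == 0) stop("template has zero variance")
  region <- toGray(frame[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE])
  best <- 0
  for (dy in 0:(nrow(region) - th)) {
    for (dx in 0:(ncol(region) - tw)) {
      win <- as.vector(region[(dy + 1):(dy + th), (dx + 1):(dx + tw)])
      if (stats::sd(win) == 0) next
      cc <- stats::cor(tg, win)
      if (cc > best) best <- cc
    }
  }
  list(score = max(0, best), present = max(0, best) >= template$threshold)
}

#' Indicator state of one frame
#' @param frame RGB array.
#' @param templates Template list covering the three indicator kinds.
#' @param frameIndex Frame number recorded in the output.
#' @return One-row data.frame(frame, cameraMoving, leftActive, rightActive).
#' @export
indicatorStateFrame <- function(frame, templates, frameIndex = NA_integer_) {
  res <- list(camera_arm = FALSE, instrument_arm_left = FALSE,
              instrument_arm_right = FALSE)
  for (tpl in templates) res[[tpl$kind]] <- matchTemplate(frame, tpl)$present
  data.frame(frame = frameIndex, cameraMoving = res$camera_arm,
             leftActive = res$instrument_arm_left,
             rightActive = res$instrument_arm_right)
}

#' Per-frame indicator states of a scene or frame sequence
#'
#' The camera flag is true exactly on frames where the camera-arm template
#' is present; the active arms are those whose arm-status template is
#' present (at most two arms exist).
#'
#' @param x A [Scene-class], a list of RGB frames, or a function(i)
#'   returning frame i (then `n` is required).
#' @param templates Indicator templates; defaults to the scene's own.
#' @param n Number of frames when `x` is a function.
#' @return data.frame(frame, cameraMoving, leftActive, rightActive).
#' @export
indicatorStates <- function(x, templates = NULL, n = NULL) {
  if (methods::is(x, "Scene")) {
    templates <- templates %||% x@templates
    n <- nFrames(x)
    getFrame <- function(i) renderFrame(x, i)
  } else if (is.function(x)) {
    stopifnot(!is.null(n), !is.null(templates))
    getFrame <- x
  } else {
    n <- length(x)
    stopifnot(!is.null(templates))
    getFrame <- function(i) x[[i]]
  }
  do.call(rbind, lapply(seq_len(n), function(i)
    indicatorStateFrame(getFrame(i), templates, i)))
}

#' Infer the arm side of each tracked identity
#'
#' Arm indicators sit on the side of the view their instrument works from;
#' each identity is assigned "left" or "right" by the median x position of
#' its trajectory relative to the view center.
#'
#' @param trajectory data.frame with `identity` and `x_px` (or `x_mm`)
#'   columns.
#' @param center x coordinate separating the sides (half the view width in
#'   px, or 0 for centred mm coordinates).
#' @return Named character vector, identity -> "left"/"right".
#' @export
inferArmAssignment <- function(trajectory, center) {
  xcol <- if ("x_px" %in% names(trajectory)) "x_px" else "x_mm"
  med <- tapply(trajectory[[xcol]], trajectory$identity, stats::median,
                na.rm = TRUE)
  out <- ifelse(med < center, "left", "right")
  names(out) <- names(med)
  out
}

#' Gate a trajectory with indicator states
#'
#' Adds validity flags without altering any position (lossless): samples on
#' camera-moving frames are marked invalid for motion (screen motion must
#' not be read as instrument motion), and identities whose arm is not
#' active are marked inactive (an immobile but visible instrument must not
#' contribute displacement). Metric functions exclude displacement across
#' flagged samples but keep positions and in-view information.
#'
#' @param trajectory data.frame with columns frame, identity, positions.
#' @param states data.frame from [indicatorStates()] covering every
#'   trajectory frame.
#' @param armOf Named vector identity -> "left"/"right"; inferred via
#'   [inferArmAssignment()] when NULL.
#' @param center Passed to [inferArmAssignment()] when `armOf` is NULL.
#' @return The trajectory with `camera_moving`, `active` and `valid_motion`
#'   columns.
#' @export
gateTrajectory <- function(trajectory, states, armOf = NULL, center = NULL) {
  if (nrow(trajectory) == 0) {
    trajectory$camera_moving <- logical(0)
    trajectory$active <- logical(0)
    trajectory$valid_motion <- logical(0)
    return(trajectory)
  }
  if (!all(trajectory$frame %in% states$frame))
    stop("trajectory frames not covered by indicator states")
  if (is.null(armOf)) {
    if (is.null(center)) stop("supply armOf or center")
    armOf <- inferArmAssignment(trajectory, center)
  }
  m <- match(trajectory$frame, states$frame)
  trajectory$camera_moving <- states$cameraMoving[m]
  side <- armOf[as.character(trajectory$identity)]
  trajectory$active <- ifelse(side == "left", states$leftActive[m],
                              states$rightActive[m])
  vis <- if ("visible" %in% names(trajectory)) trajectory$visible else TRUE
  trajectory$valid_motion <- !trajectory$camera_moving & vis
  trajectory
}

#' Write / read indicator templates (PNG + JSON manifest)
#' @param templates Template list.
#' @param dir Directory for the PNG files and `manifest.json`.
#' @return `writeTemplates`: invisibly `dir`; `readTemplates`: template list.
#' @export
writeTemplates <- function(templates, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(templates, function(tpl) {
    fn <- paste0(tpl$kind, ".png")
    png::writePNG(tpl$image, file.path(dir, fn))
    list(kind = tpl$kind, file = fn, pos = tpl$pos, region = tpl$region,
         threshold = tpl$threshold)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeTemplates
#' @export
readTemplates <- function(dir) {
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                           simplifyVector = FALSE)
  lapply(mf, function(rec) {
    img <- png::readPNG(file.path(dir, rec$file))
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    list(kind = rec$kind, image = img[, , 1:3, drop = FALSE],
         pos = unlist(rec$pos), region = unlist(rec$region),
         threshold = rec$threshold)
  })
}
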