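#' @include kalman.R hungarian.R
NULL

#' Intersection over union of two boxes
#'
#' Boxes are c(x, y, w, h), half-open. Symmetric; returns 0 when both boxes
#' are degenerate.
#'
#' @param a,b Numeric boxes.
#' @return IOU in \[0, 1\].
#' @export
boxIou <- function(a, b) {
  stopifnot(a[3] >= 0, a[4] >= 0, b[3] >= 0, b[4] >= 0)
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  uni <- a[3] * a[4] + b[3] * b[4] - inter
  if (uni <= 0) return(0)
  inter / uni
}

GATE_SENTINEL <- 1e6

#' Associate rows with columns at minimum total cost
#'
#' Hungarian assignment over a cost matrix with optional admissibility
#' gating: inadmissible pairs are set to a large sentinel before solving and
#' any match that lands on a gated pair is removed afterwards.
#'
#' @param cost Numeric matrix (rows = tracks, columns = detections).
#' @param admissible Optional logical matrix of the same shape.
#' @return List: `matches` (2-column matrix row/col), `unmatchedRows`,
#'   `unmatchedCols`, `cost` (the gated matrix used).
#' @export
associate <- function(cost, admissible = NULL) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (is.null(nr) || nr == 0 || nc == 0) {
    return(list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatchedRows = seq_len(nr %||% 0),
                unmatchedCols = seq_len(nc %||% 0), cost = cost))
  }
  gated <- cost
  if (!is.null(admissible)) gated[!admissible] <- GATE_SENTINEL
  sol <- solveAssignment(gated)
  ok <- gated[sol] < GATE_SENTINEL / 2
  matches <- sol[ok, , drop = FALSE]
  list(matches = matches,
       unmatchedRows = setdiff(seq_len(nr), matches[, 1]),
       unmatchedCols = setdiff(seq_len(nc), matches[, 2]),
       cost = gated)
}

#' Tracker configuration
#'
#' @param maxAge Frames a confirmed track survives unmatched before deletion.
#' @param nInit Consecutive hits required to confirm a tentative track.
#' @param maxConfirmed Hard cap on simultaneously confirmed instrument
#'   tracks (three: the robotic-surgery view shows at most three
#'   instruments). A confirmation that would exceed the cap is denied; the
#'   blocked track keeps accumulating hits and confirms when a slot frees.
#' @param lambda Weight of the motion term in the combined association cost
#'   `lambda * mahalanobis + (1 - lambda) * appearance cosine distance`
#'   (appearance-dominant by default).
#' @param mahalanobisGate Chi-square 0.95 quantile, 4 df.
#' @param iouGate Minimum IOU for the fallback IOU association pass.
#' @param appearanceBufferSize Descriptors retained per track.
#' @return A `trackerConfig` list.
#' @export
trackerConfig <- function(maxAge = 30, nInit = 3, maxConfirmed = 3,
                          lambda = 0.02, mahalanobisGate = 9.4877,
                          iouGate = 0.3, appearanceBufferSize = 30) {
  list(maxAge = maxAge, nInit = nInit, maxConfirmed = maxConfirmed,
       lambda = lambda, mahalanobisGate = mahalanobisGate,
       iouGate = iouGate, appearanceBufferSize = appearanceBufferSize)
}

#' Create an empty tracker state
#' @param config A [trackerConfig()].
#' @return Tracker state list; advance it with [trackerStep()].
#' @export
newTracker <- function(config = trackerConfig()) {
  list(tracks = list(), nextId = 1L, frame = 0L, config = config)
}

newTrack <- function(id, det, descriptor) {
  list(id = id, status = "tentative", hits = 1L, tsu = 0L,
       state = kalmanInit(det$box), box = det$box, identity = NA_integer_,
       appBuffer = if (is.null(descriptor)) list() else list(descriptor),
       patchWindow = list(), lastDet = NA_integer_)
}

appearanceCost <- function(track, descriptor) {
  if (is.null(descriptor) || length(track$appBuffer) == 0) return(NA_real_)
  min(vapply(track$appBuffer, cosineDist, numeric(1), b = descriptor))
}

#' Advance the tracker by one frame
#'
#' SORT-style tracking-by-detection with a matching cascade: confirmed
#' tracks are matched in order of recency (smallest time-since-update first)
#' using the combined appearance/motion cost under Mahalanobis gating, then
#' remaining age-1 and tentative tracks get an IOU-only pass. Unmatched
#' detections spawn tentative tracks; tracks confirm after `nInit`
#' consecutive hits subject to the three-track cap; confirmed tracks
#' unmatched for more than `maxAge` frames are deleted.
#'
#' @param ts Tracker state from [newTracker()] / a previous step.
#' @param detections NMS-filtered detections of the current frame.
#' @param descriptors Optional list of appearance descriptors parallel to
#'   `detections` (NULL disables the appearance term).
#' @return Updated tracker state; `$assignments` maps track ids to detection
#'   indices for this frame, `$newlyConfirmed` lists track ids confirmed
#'   this frame.
#' @export
trackerStep <- function(ts, detections, descriptors = NULL) {
  cfg <- ts$config
  ts$frame <- ts$frame + 1L
  nDet <- length(detections)
  for (i in seq_along(ts$tracks)) {
    ts$tracks[[i]]$state <- kalmanPredict(ts$tracks[[i]]$state)
    ts$tracks[[i]]$tsu <- ts$tracks[[i]]$tsu + 1L
  }
  zs <- if (nDet) t(vapply(detections, function(d) boxToZ(d$box),
                           numeric(4))) else matrix(0, 0, 4)

  remaining <- seq_len(nDet)
  matchedPairs <- list()

  status <- vapply(ts$tracks, `[[`, character(1), "status")
  tsu <- vapply(ts$tracks, `[[`, integer(1), "tsu")

  # matching cascade over confirmed (incl. lost) tracks by recency
  for (age in seq_len(cfg$maxAge)) {
    cand <- which(status %in% c("confirmed", "lost") & tsu == age)
    if (!length(cand) || !length(remaining)) next
    cost <- matrix(0, length(cand), length(remaining))
    adm <- matrix(TRUE, length(cand), length(remaining))
    for (a in seq_along(cand)) {
      tr <- ts$tracks[[cand[a]]]
      d2 <- kalmanGatingDistance(tr$state, zs[remaining, , drop = FALSE])
      app <- vapply(seq_along(remaining), function(b)
        appearanceCost(tr, if (is.null(descriptors)) NULL
                       else descriptors[[remaining[b]]]), numeric(1))
      comb <- ifelse(is.na(app), cfg$lambda * d2,
                     cfg$lambda * d2 + (1 - cfg$lambda) * app)
      cost[a, ] <- comb
      adm[a, ] <- d2 <= cfg$mahalanobisGate
    }
    res <- associate(cost, adm)
    for (k in seq_len(nrow(res$matches))) {
      ti <- cand[res$matches[k, 1]]
      di <- remaining[res$matches[k, 2]]
      matchedPairs[[length(matchedPairs) + 1]] <- c(ti, di)
    }
    if (nrow(res$matches))
      remaining <- remaining[-res$matches[, 2, drop = TRUE]]
  }

  # IOU pass for tentative tracks and confirmed tracks the cascade missed
  # (abrupt accelerations fail the Mahalanobis gate, but the elongated
  # instrument boxes still overlap heavily frame to frame)
  matchedT <- vapply(matchedPairs, `[[`, numeric(1), 1)
  cand <- setdiff(seq_along(ts$tracks), matchedT)
  if (length(cand) && length(remaining)) {
    cost <- matrix(0, length(cand), length(remaining))
    adm <- matrix(TRUE, length(cand), length(remaining))
    for (a in seq_along(cand)) {
      predBox <- zToBox(ts$tracks[[cand[a]]]$state$mean[1:4])
      lastBox <- ts$tracks[[cand[a]]]$box
      # this pass exists for motion-model failures (abrupt accelerations,
      # shrinking masks at the border), so it considers the last observed
      # box as well as the possibly-degenerate prediction
      predOk <- all(is.finite(predBox)) && predBox[3] > 0 && predBox[4] > 0
      ious <- vapply(remaining, function(b) {
        max(if (predOk) boxIou(predBox, detections[[b]]$box) else 0,
            boxIou(lastBox, detections[[b]]$box))
      }, numeric(1))
      cost[a, ] <- 1 - ious
      adm[a, ] <- ious >= cfg$iouGate
    }
    res <- associate(cost, adm)
    for (k in seq_len(nrow(res$matches))) {
      ti <- cand[res$matches[k, 1]]
      di <- remaining[res$matches[k, 2]]
      matchedPairs[[length(matchedPairs) + 1]] <- c(ti, di)
    }
    if (nrow(res$matches))
      remaining <- remaining[-res$matches[, 2, drop = TRUE]]
  }

  # updates for matched tracks
  newlyConfirmed <- integer(0)
  matchedT <- if (length(matchedPairs))
    vapply(matchedPairs, `[[`, numeric(1), 1) else numeric(0)
  confirmedCount <- sum(vapply(ts$tracks, function(tr)
    tr$status %in% c("confirmed", "lost"), logical(1)))
  for (p in matchedPairs) {
    ti <- p[1]; di <- p[2]
    tr <- ts$tracks[[ti]]
    tr$state <- kalmanUpdate(tr$state, boxToZ(detections[[di]]$box))
    tr$box <- detections[[di]]$box
    tr$hits <- tr$hits + 1L
    tr$tsu <- 0L
    tr$lastDet <- di
    if (!is.null(descriptors) && !is.null(descriptors[[di]])) {
      tr$appBuffer <- c(tr$appBuffer, list(descriptors[[di]]))
      if (length(tr$appBuffer) > cfg$appearanceBufferSize)
        tr$appBuffer <- tr$appBuffer[-1]
    }
    if (tr$status == "tentative") {
      if (tr$hits >= cfg$nInit && confirmedCount < cfg$maxConfirmed) {
        tr$status <- "confirmed"
        confirmedCount <- confirmedCount + 1L
        newlyConfirmed <- c(newlyConfirmed, tr$id)
      }
    } else {
      tr$status <- "confirmed"  # lost -> confirmed on re-association
    }
    ts$tracks[[ti]] <- tr
  }

  # unmatched tracks: lifecycle
  drop <- logical(length(ts$tracks))
  for (i in seq_along(ts$tracks)) {
    tr <- ts$tracks[[i]]
    if (tr$tsu == 0L) next
    if (tr$status == "tentative") {
      drop[i] <- TRUE  # a missed tentative track is removed
    } else if (tr$tsu > cfg$maxAge) {
      drop[i] <- TRUE  # lost beyond max age -> deleted
    } else {
      tr$status <- "lost"
      tr$lastDet <- NA_integer_
      ts$tracks[[i]] <- tr
    }
  }

  # unmatched detections spawn tentative tracks
  for (di in remaining) {
    ts$tracks[[length(ts$tracks) + 1]] <-
      newTrack(ts$nextId, detections[[di]],
               if (is.null(descriptors)) NULL else descriptors[[di]])
    ts$tracks[[length(ts$tracks)]]$lastDet <- di
    ts$nextId <- ts$nextId + 1L
  }
  ts$tracks <- ts$tracks[!c(drop, logical(length(ts$tracks) - length(drop)))]

  ids <- vapply(ts$tracks, `[[`, integer(1), "id")
  lastDet <- vapply(ts$tracks, `[[`, integer(1), "lastDet")
  st <- vapply(ts$tracks, `[[`, character(1), "status")
  ts$assignments <- data.frame(trackId = ids, detIdx = lastDet, status = st)[
    !is.na(lastDet) & vapply(ts$tracks, function(tr) tr$tsu == 0L,
                             logical(1)), , drop = FALSE]
  ts$newlyConfirmed <- newlyConfirmed
  ts
}

#' Count tracks by status
#' @param ts Tracker state.
#' @param statuses Character vector of statuses to count.
#' @return Integer.
#' @export
countTracks <- function(ts, statuses = c("confirmed", "lost")) {
  sum(vapply(ts$tracks, function(tr) tr$status %in% statuses, logical(1)))
}

getTrack <- function(ts, id) {
  for (tr in ts$tracks) if (tr$id == id) return(tr)
  NULL
}

setTrackField <- function(ts, id, field, value) {
  for (i in seq_along(ts$tracks)) {
    if (ts$tracks[[i]]$id == id) {
      ts$tracks[[i]][[field]] <- value
      return(ts)
    }
  }
  ts
}
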