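#' @include reid.R randomScene.R
NULL

## paste the central section of instrument `src`'s rendering (at frame f)
## over `targetBox`, simulating the band of shaft that occludes a crossed
## instrument (a crossing shaft covers a section, not the whole instrument)
overlayInstrument <- function(frame, scene, f, src, targetBox) {
  st <- scene@truth
  h <- dim(frame)[1]; w <- dim(frame)[2]
  idx <- st$maskIdx[[src]][[f]]
  if (is.null(idx)) return(frame)
  x <- idxToX(idx, h); y <- idxToY(idx, h)
  d2c <- (x - mean(x))^2 + (y - mean(y))^2
  keepC <- d2c <= (0.4 * sqrt(max(d2c)))^2
  if (sum(keepC) > 30) {
    idx <- idx[keepC]; x <- x[keepC]; y <- y[keepC]
  }
  dx <- round(targetBox[1] + targetBox[3] * 0.35 - mean(x))
  dy <- round(targetBox[2] + targetBox[4] / 2 - mean(y))
  nx <- x + dx; ny <- y + dy
  keep <- nx >= 0 & nx < w & ny >= 0 & ny < h
  if (!any(keep)) return(frame)
  toIdx <- xyToIdx(nx[keep], ny[keep], h)
  fromIdx <- idx[keep]
  npx <- h * w
  for (ch in 0:2)
    frame[toIdx + ch * npx] <- frame[fromIdx + ch * npx]
  frame
}

corruptFrame <- function(frame, noiseSd, brightShift) {
  clamp(frame * (1 + brightShift) +
          array(stats::rnorm(length(frame), 0, noiseSd), dim(frame)), 0, 1)
}

#' Synthetic re-identification benchmark
#'
#' Builds a seeded gallery/query benchmark from rendered scenes and scores
#' three re-identification routes by rank-1 cumulative matching accuracy:
#' the offline appearance gallery alone, the online bag-of-visual-words
#' model alone (trained on the ten frames preceding each query), and the
#' sequential cascade of both.
#'
#' Two query types reproduce the failure modes re-identification exists
#' for: re-entry queries (the instrument is seen again after an absence,
#' only partially inserted, under pixel noise and a global brightness
#' shift) and crossing queries (the instruments have just separated after
#' crossing in close proximity; the tracker's motion-continuity incumbent
#' carried through the crossing is wrong with probability `swapProb`,
#' the identity swap the cascade exists to correct).
#'
#' @param nExit,nCross Number of re-entry / crossing queries (total split
#'   over several scenes).
#' @param noiseSd Additive pixel noise s.d. for query frames.
#' @param swapProb Probability the crossing incumbent is wrong.
#' @param k BOVW vocabulary size.
#' @param seed Integer seed.
#' @return List: `rank1` (named: combined, offline, online), `queries`
#'   (per-query detail data.frame).
#' @export
reidBenchmark <- function(nExit = 20, nCross = 20, noiseSd = 0.06,
                          swapProb = 0, k = 32, seed = 1L) {
  queriesPerScene <- 4L
  nScenes <- ceiling((nExit + nCross) / queriesPerScene)
  detail <- list()
  withSeed(seed, {
    exitLeft <- nExit; crossLeft <- nCross
    for (sc in seq_len(nScenes)) {
      scene <- randomScene(nInstruments = 3, nFrames = 80, width = 240,
                           height = 180, withCrossings = FALSE,
                           withExits = FALSE, withCamera = FALSE,
                           thirdWandersFullScene = TRUE,
                           seed = seed + 131L * sc)
      # real instruments look alike: closely spaced hues, so identity
      # hinges on subtle color mixtures, shaft orientation and texture
      # real instruments share the same metallic color: identity hinges
      # on shaft orientation and banding texture, not hue
      cfg <- scene@config
      for (i in 1:3) cfg@instruments[[i]]$hue <- 0.58
      scene@config <- cfg
      st <- scene@truth
      # offline gallery from early frames
      gallery <- newGallery(50)
      for (f in seq(4, 30, by = 2)) {
        fr <- renderFrame(scene, f)
        for (i in 1:3) {
          if (!st$visible[f, i]) next
          gallery <- galleryAdd(gallery, i,
                                extractDescriptor(fr, st$boxes[[i]][f, ],
                                                  st$maskIdx[[i]][[f]]))
        }
      }
      qf <- sample(45:75, 1)
      # online training window: the 10 previous frames (clean renders)
      winD <- list(); winI <- list()      # box crops: standalone baseline
      winDm <- list(); winIm <- list()    # mask-filtered: cascade stage 2
      for (f in (qf - 10):(qf - 1)) {
        # the online window is past frames of the same noisy video
        fr <- corruptFrame(renderFrame(scene, f), noiseSd,
                           stats::runif(1, -0.1, 0.1))
        for (i in 1:3) {
          if (!st$visible[f, i]) next
          p <- localPatchDescriptors(fr, st$boxes[[i]][f, ])
          if (nrow(p) > 0) {
            winD[[length(winD) + 1]] <- p
            winI[[length(winI) + 1]] <- rep(i, nrow(p))
          }
          pm <- localPatchDescriptors(fr, st$boxes[[i]][f, ],
                                      st$maskIdx[[i]][[f]])
          if (nrow(pm) > 0) {
            winDm[[length(winDm) + 1]] <- pm
            winIm[[length(winIm) + 1]] <- rep(i, nrow(pm))
          }
        }
      }
      windowDesc <- do.call(rbind, winD)
      windowId <- unlist(winI)
      model <- bovwFit(windowDesc, windowId,
                       k = min(k, nrow(windowDesc) - 1), seed = seed + sc)
      windowDescM <- do.call(rbind, winDm)
      windowIdM <- unlist(winIm)
      qframe <- renderFrame(scene, qf)

      for (q in seq_len(queriesPerScene)) {
        isCross <- if (crossLeft > 0 && exitLeft > 0) q > 2 else crossLeft > 0
        if (isCross) crossLeft <- crossLeft - 1 else {
          if (exitLeft == 0) next
          exitLeft <- exitLeft - 1
        }
        target <- sample(1:3, 1)
        if (!st$visible[qf, target]) target <- which(st$visible[qf, ])[1]
        box <- st$boxes[[target]][qf, ]
        qmask <- st$maskIdx[[target]][[qf]]
        fr <- qframe
        incumbent <- NA_integer_
        if (isCross) {
          other <- sample(setdiff(1:3, target), 1)
          fr <- overlayInstrument(fr, scene, qf, other, box)
          incumbent <- if (stats::runif(1) < swapProb) other else target
        } else {
          # a re-entering instrument is only partially inserted: keep the
          # tip-side portion of the mask and its tight box
          h <- dim(fr)[1]
          tip <- st$tip[[target]][qf, ]
          dx <- idxToX(qmask, h) - tip[1]; dy <- idxToY(qmask, h) - tip[2]
          d2 <- dx^2 + dy^2
          qmask <- qmask[d2 <= (0.55 * sqrt(max(d2)))^2]
          box <- boxFromMaskIdx(qmask, h)
        }
        fr <- corruptFrame(fr, noiseSd, stats::runif(1, -0.25, 0.25))
        qdesc <- extractDescriptor(fr, box, qmask)
        qpatchBox <- localPatchDescriptors(fr, box)
        qpatchMask <- localPatchDescriptors(fr, box, qmask)

        offRank <- galleryRank(qdesc, gallery)$identity
        onRank <- if (nrow(qpatchBox) > 0)
          bovwRank(model, bovwHistogram(model, qpatchBox))$identity else
            offRank
        dec <- cascadeReid(incumbent, qdesc, gallery,
                           windowDescriptors = windowDescM,
                           windowIdentity = windowIdM,
                           queryPatches = qpatchMask, k = k,
                           seed = seed + sc)
        combRank <- c(dec$identity, setdiff(offRank, dec$identity))
        detail[[length(detail) + 1]] <- data.frame(
          scene = sc, type = if (isCross) "crossing" else "reentry",
          truth = target, incumbent = incumbent,
          offline = offRank[1], online = onRank[1], combined = combRank[1])
      }
    }
  })
  d <- do.call(rbind, detail)
  rank1 <- c(combined = mean(d$combined == d$truth),
             offline = mean(d$offline == d$truth),
             online = mean(d$online == d$truth))
  list(rank1 = rank1, queries = d)
}
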