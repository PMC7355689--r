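#' @include utils.R
NULL

#' Extract an appearance descriptor for a box patch
#'
#' Classical fixed-length appearance feature standing behind the offline
#' re-identification interface: the box is divided into a 3 x 3 grid and each
#' cell contributes a joint 8-hue x 4-saturation color histogram plus a 9-bin
#' gradient-orientation histogram; the concatenation is L2-normalized.
#' Deterministic. Any embedding with the same contract can be swapped in.
#'
#' @param frame RGB array `h x w x 3`.
#' @param box Numeric c(x, y, w, h), half-open, inside the frame; at least
#'   3 x 3 px.
#' @param maskIdx Optional column-major frame indices of the instrument
#'   mask: histograms are then restricted to instrument pixels, so the
#'   descriptor is not diluted by background inside the box (an elongated
#'   diagonal shaft fills only a sliver of its axis-aligned box).
#' @return Unit-norm numeric vector of length 369.
#' @export
extractDescriptor <- function(frame, box, maskIdx = NULL) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- max(0, floor(box[1])); y0 <- max(0, floor(box[2]))
  x1 <- min(w, ceiling(box[1] + box[3])); y1 <- min(h, ceiling(box[2] + box[4]))
  if (x1 - x0 < 3 || y1 - y0 < 3) stop("degenerate box for descriptor")
  patch <- frame[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  ph <- dim(patch)[1]; pw <- dim(patch)[2]
  hsv <- grDevices::rgb2hsv(as.vector(patch[, , 1]), as.vector(patch[, , 2]),
                            as.vector(patch[, , 3]), maxColorValue = 1)
  hueBin <- pmin(7L, floor(hsv[1, ] * 8))
  satBin <- pmin(3L, floor(hsv[2, ] * 4))
  colorBin <- hueBin * 4L + satBin + 1L  # 1..32
  gray <- 0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3]
  gx <- matrix(0, ph, pw); gy <- matrix(0, ph, pw)
  if (pw > 2) gx[, 2:(pw - 1)] <- (gray[, 3:pw] - gray[, 1:(pw - 2)]) / 2
  if (ph > 2) gy[2:(ph - 1), ] <- (gray[3:ph, ] - gray[1:(ph - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx)  # (-pi, pi]
  oriBin <- pmin(8L, floor((ori + pi) / (2 * pi) * 9)) + 1L  # 1..9
  rowIdx <- rep(seq_len(ph), times = pw)
  colIdx <- rep(seq_len(pw), each = ph)
  cellR <- pmin(2L, (rowIdx - 1L) * 3L %/% ph)
  cellC <- pmin(2L, (colIdx - 1L) * 3L %/% pw)
  cell <- cellR * 3L + cellC  # 0..8
  inMask <- rep(TRUE, ph * pw)
  if (!is.null(maskIdx)) {
    fy <- idxToY(maskIdx, h); fx <- idxToX(maskIdx, h)
    keep <- fx >= x0 & fx < x1 & fy >= y0 & fy < y1
    if (any(keep)) {
      inMask <- rep(FALSE, ph * pw)
      inMask[(fx[keep] - x0) * ph + (fy[keep] - y0) + 1L] <- TRUE
    }
  }
  vec <- numeric(9 * 41)
  for (cl in 0:8) {
    sel <- cell == cl & inMask
    colorHist <- tabulate(colorBin[sel], nbins = 32)
    magSel <- mag[sel]; oriSel <- oriBin[sel]
    gradHist <- vapply(1:9, function(b) sum(magSel[oriSel == b]), numeric(1))
    seg <- cl * 41
    vec[(seg + 1):(seg + 32)] <- colorHist / max(1, sum(colorHist))
    vec[(seg + 33):(seg + 41)] <- gradHist / max(1e-9, sum(gradHist))
  }
  unitize(vec)
}

#' Create an empty re-identification gallery
#'
#' The offline stage's exemplar store: up to `capacity` descriptors per
#' instrument identity, at most three identities (the view never shows more
#' than three instruments), FIFO eviction.
#'
#' @param capacity Exemplars kept per identity.
#' @return A `gallery` list.
#' @export
newGallery <- function(capacity = 50) {
  list(identities = list(), capacity = capacity, maxIdentities = 3L)
}

#' Add an exemplar descriptor to a gallery
#' @param gallery A gallery from [newGallery()].
#' @param identity Integer identity label (1-3).
#' @param descriptor Appearance descriptor vector.
#' @return Updated gallery.
#' @export
galleryAdd <- function(gallery, identity, descriptor) {
  key <- as.character(identity)
  if (is.null(gallery$identities[[key]]) &&
      length(gallery$identities) >= gallery$maxIdentities)
    stop("gallery is limited to three identities")
  exs <- gallery$identities[[key]] %||% list()
  exs <- c(exs, list(descriptor))
  if (length(exs) > gallery$capacity) exs <- exs[-1]
  gallery$identities[[key]] <- exs
  gallery
}

#' Rank gallery identities by distance to a query
#'
#' Identities are sorted by the minimum cosine distance between the query
#' descriptor and their exemplars; at most three identities are returned,
#' rank 1 first.
#'
#' @param query Descriptor vector.
#' @param gallery A gallery with at least one exemplar.
#' @return data.frame(identity, distance), ascending distance.
#' @export
galleryRank <- function(query, gallery) {
  if (length(gallery$identities) == 0) stop("gallery is empty")
  ids <- as.integer(names(gallery$identities))
  d <- vapply(gallery$identities, function(exs)
    min(vapply(exs, cosineDist, numeric(1), a = query)), numeric(1))
  ord <- order(d, ids)
  data.frame(identity = ids[ord], distance = as.numeric(d[ord]))[
    seq_len(min(3, length(ids))), , drop = FALSE]
}

#' Serialize / restore a gallery as JSON
#' @param gallery A gallery.
#' @param path File path.
#' @return `writeGallery`: invisibly `path`; `readGallery`: a gallery.
#' @export
writeGallery <- function(gallery, path) {
  jsonlite::write_json(list(
    capacity = gallery$capacity,
    identities = lapply(gallery$identities, function(exs)
      do.call(rbind, exs))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGallery
#' @export
readGallery <- function(path) {
  obj <- jsonlite::fromJSON(path)
  g <- newGallery(obj$capacity)
  for (key in names(obj$identities)) {
    m <- obj$identities[[key]]
    g$identities[[key]] <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  g
}

#' Local patch descriptors for the bag-of-visual-words model
#'
#' Samples non-overlapping 8 x 8 patches on a grid inside the box; each
#' patch yields its mean RGB and grayscale s.d. (4 dimensions) -- the
#' deliberately simple visual word of a classical online model.
#'
#' @param frame RGB array.
#' @param box Numeric c(x, y, w, h).
#' @param maskIdx Optional mask indices; only patches with at least
#'   `minMaskFrac` of their pixels on the mask are kept, so the words
#'   describe the instrument rather than background or an overlapping
#'   neighbour.
#' @param patchSize Patch side in px.
#' @param minMaskFrac Minimum on-mask pixel fraction per kept patch.
#' @return Numeric matrix, one row per patch (possibly 0 rows).
#' @export
localPatchDescriptors <- function(frame, box, maskIdx = NULL, patchSize = 8,
                                  minMaskFrac = 0.3) {
  if (any(is.na(box))) return(matrix(0, 0, 4))
  h <- dim(frame)[1]; w <- dim(frame)[2]
  x0 <- max(0, floor(box[1])); y0 <- max(0, floor(box[2]))
  x1 <- min(w, ceiling(box[1] + box[3])); y1 <- min(h, ceiling(box[2] + box[4]))
  if (x1 - x0 < patchSize || y1 - y0 < patchSize) return(matrix(0, 0, 4))
  maskM <- NULL
  if (!is.null(maskIdx)) {
    maskM <- matrix(FALSE, h, w)
    maskM[maskIdx] <- TRUE
  }
  xs <- seq(x0, x1 - patchSize, by = patchSize)
  ys <- seq(y0, y1 - patchSize, by = patchSize)
  out <- matrix(0, length(xs) * length(ys), 4)
  k <- 0
  for (px in xs) for (py in ys) {
    if (!is.null(maskM) &&
        mean(maskM[(py + 1):(py + patchSize),
                   (px + 1):(px + patchSize)]) < minMaskFrac) next
    k <- k + 1
    p <- frame[(py + 1):(py + patchSize), (px + 1):(px + patchSize), ,
               drop = FALSE]
    gray <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
    out[k, ] <- c(mean(p[, , 1]), mean(p[, , 2]), mean(p[, , 3]),
                  stats::sd(as.vector(gray)))
  }
  out[seq_len(k), , drop = FALSE]
}

#' Fit an online bag-of-visual-words model
#'
#' Quantizes local patch descriptors collected over the previous ten frames
#' against a k-means vocabulary (fixed seed, capped iterations) and stores
#' one normalized word histogram per identity.
#'
#' @param descriptors Numeric matrix of patch descriptors (rows).
#' @param identity Integer vector of identity labels, one per row.
#' @param k Vocabulary size (>= 2).
#' @param seed Integer seed for k-means.
#' @return A `bovwModel` list (vocabulary, per-identity histograms).
#' @export
bovwFit <- function(descriptors, identity, k = 32, seed = 1L) {
  stopifnot(k >= 2)
  descriptors <- as.matrix(descriptors)
  if (nrow(descriptors) < k)
    stop("fewer patch descriptors (", nrow(descriptors),
         ") than vocabulary size k = ", k, "; reduce k")
  km <- withSeed(seed, stats::kmeans(descriptors, centers = k,
                                     iter.max = 25, nstart = 1))
  hists <- lapply(split(km$cluster, identity), function(cl) {
    hh <- tabulate(cl, nbins = k)
    hh / sum(hh)
  })
  list(vocabulary = km$centers, histograms = hists, k = k)
}

nearestWord <- function(vocabulary, x) {
  d <- colSums((t(vocabulary) - x)^2)
  which.min(d)
}

#' Histogram of a query under a bag-of-visual-words vocabulary
#' @param model A model from [bovwFit()].
#' @param descriptors Patch descriptor matrix of the query box.
#' @return Normalized word histogram (length k).
#' @export
bovwHistogram <- function(model, descriptors) {
  descriptors <- as.matrix(descriptors)
  stopifnot(nrow(descriptors) > 0)
  words <- apply(descriptors, 1, nearestWord, vocabulary = model$vocabulary)
  hh <- tabulate(words, nbins = model$k)
  hh / sum(hh)
}

#' Rank identities by word-histogram similarity
#' @param model A model from [bovwFit()].
#' @param queryHist Histogram from [bovwHistogram()].
#' @return data.frame(identity, similarity), descending cosine similarity.
#' @export
bovwRank <- function(model, queryHist) {
  ids <- as.integer(names(model$histograms))
  sim <- vapply(model$histograms, function(hh)
    1 - cosineDist(hh, queryHist), numeric(1))
  ord <- order(-sim, ids)
  data.frame(identity = ids[ord], similarity = as.numeric(sim[ord]))
}

#' Cascaded re-identification decision
#'
#' Stage 1 proposes the gallery rank-1 identity. If the proposal differs
#' from the incumbent identity (an identity-change prediction) and the
#' distance margin exceeds `tieEps` (otherwise appearance is uninformative
#' and motion continuity keeps the incumbent), stage 2 fits a
#' bag-of-visual-words model on the previous ten frames and votes: the final
#' identity is the vote when it agrees with either candidate, else the
#' incumbent is retained. Degenerate windows fall back to the stage-1
#' proposal.
#'
#' @param incumbent Current identity label or NA for a newly confirmed track.
#' @param query Appearance descriptor of the current detection.
#' @param gallery Offline gallery.
#' @param windowDescriptors,windowIdentity Patch descriptors and labels from
#'   the previous ten frames (stage-2 training material), or NULL.
#' @param queryPatches Patch descriptor matrix of the current box, or NULL.
#' @param k BOVW vocabulary size.
#' @param tieEps Cosine-distance margin under which appearance ranks are
#'   considered tied.
#' @param seed Integer seed for stage 2.
#' @return List: `identity` (decision), `ranked` (stage-1 table),
#'   `stage2` (logical, whether BOVW ran).
#' @export
cascadeReid <- function(incumbent, query, gallery,
                        windowDescriptors = NULL, windowIdentity = NULL,
                        queryPatches = NULL, k = 32, tieEps = 0.02,
                        seed = 1L) {
  ranked <- galleryRank(query, gallery)
  proposal <- ranked$identity[1]
  if (is.na(incumbent) || proposal == incumbent)
    return(list(identity = proposal, ranked = ranked, stage2 = FALSE))
  dInc <- ranked$distance[match(incumbent, ranked$identity)]
  if (!is.na(dInc) && abs(dInc - ranked$distance[1]) < tieEps)
    return(list(identity = incumbent, ranked = ranked, stage2 = FALSE))
  effK <- min(k, if (is.null(windowDescriptors)) 0 else
    max(0, nrow(windowDescriptors) - 1))
  if (is.null(windowDescriptors) || is.null(queryPatches) ||
      nrow(queryPatches) == 0 || effK < 2)
    return(list(identity = proposal, ranked = ranked, stage2 = FALSE))
  model <- bovwFit(windowDescriptors, windowIdentity, k = effK, seed = seed)
  vote <- bovwRank(model, bovwHistogram(model, queryPatches))$identity[1]
  decision <- if (vote %in% c(proposal, incumbent)) vote else incumbent
  list(identity = decision, ranked = ranked, stage2 = TRUE)
}

#' Cumulative matching characteristic accuracy
#'
#' Fraction of queries whose true identity appears within the top `k`
#' entries of its ranked identity list; rank-1 is the headline
#' re-identification metric.
#'
#' @param rankedLists List of integer vectors (ranked identities per query).
#' @param trueIdentities Integer vector, one per query.
#' @param k Rank cutoff.
#' @return Accuracy in \[0, 1\].
#' @export
cmcAccuracy <- function(rankedLists, trueIdentities, k = 1) {
  if (length(rankedLists) == 0) stop("no queries supplied")
  stopifnot(length(rankedLists) == length(trueIdentities))
  hits <- mapply(function(rl, tr) tr %in% rl[seq_len(min(k, length(rl)))],
                 rankedLists, trueIdentities)
  mean(hits)
}
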