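uniformPatch <- function(r, g, b, n = 24) {
  a <- array(0, c(n, n, 3))
  a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b
  a
}

test_that("descriptor is deterministic, unit-norm, and color-sensitive", {
  red <- uniformPatch(0.9, 0.1, 0.1)
  blue <- uniformPatch(0.1, 0.1, 0.9)
  box <- c(0, 0, 24, 24)
  d1 <- extractDescriptor(red, box)
  d2 <- extractDescriptor(red, box)
  expect_identical(d1, d2)
  expect_equal(sqrt(sum(d1^2)), 1, tolerance = 1e-9)
  db <- extractDescriptor(blue, box)
  expect_gt(sitrack:::cosineDist(d1, db), 0.5)
  expect_error(extractDescriptor(red, c(0, 0, 2, 2)), "degenerate")
})

test_that("gallery ranking puts exact exemplars first at distance 0", {
  g <- newGallery(10)
  dA <- extractDescriptor(uniformPatch(0.9, 0.2, 0.1), c(0, 0, 24, 24))
  dB <- extractDescriptor(uniformPatch(0.1, 0.8, 0.3), c(0, 0, 24, 24))
  g <- galleryAdd(g, 1, dA)
  g <- galleryAdd(g, 2, dB)
  rk <- galleryRank(dA, g)
  expect_equal(rk$identity[1], 1)
  expect_equal(rk$distance[1], 0, tolerance = 1e-12)
  g1 <- galleryAdd(newGallery(5), 3, dB)
  expect_equal(galleryRank(dA, g1)$identity, 3)
  expect_error(galleryRank(dA, newGallery(5)), "empty")
})

test_that("gallery enforces capacity (FIFO) and the three-identity limit", {
  g <- newGallery(2)
  d <- lapply(1:4, function(i)
    extractDescriptor(uniformPatch(i / 5, 0.5, 0.2), c(0, 0, 24, 24)))
  g <- galleryAdd(g, 1, d[[1]])
  g <- galleryAdd(g, 1, d[[2]])
  g <- galleryAdd(g, 1, d[[3]])
  expect_length(g$identities[["1"]], 2)
  expect_identical(g$identities[["1"]][[1]], d[[2]])
  g <- galleryAdd(g, 2, d[[1]])
  g <- galleryAdd(g, 3, d[[4]])
  expect_error(galleryAdd(g, 4, d[[4]]), "three")
  path <- withr::local_tempfile(fileext = ".json")
  writeGallery(g, path)
  g2 <- readGallery(path)
  expect_equal(galleryRank(d[[4]], g2)$identity[1], 3)
})

test_that("k-means vocabulary recovers separated clusters; histograms sum to 1", {
  withr::with_seed(3, {
    pts <- rbind(matrix(rnorm(60, 0, 0.05), ncol = 4),
                 matrix(rnorm(60, 3, 0.05), ncol = 4))
    ids <- rep(c(1, 2), each = 15)
    m <- bovwFit(pts, ids, k = 2, seed = 7)
    cent <- m$vocabulary
    expect_equal(unname(sort(round(rowMeans(cent)))), c(0, 3))
    for (hh in m$histograms) expect_equal(sum(hh), 1, tolerance = 1e-12)
    m2 <- bovwFit(pts, ids, k = 2, seed = 7)
    expect_identical(m$vocabulary, m2$vocabulary)
    expect_error(bovwFit(pts[1:3, ], ids[1:3], k = 10), "reduce k")
  })
})

test_that("cascade restores identity at re-entry and respects ties", {
  sc <- fixtureScene()
  st <- sceneTruth(sc)
  g <- newGallery(20)
  for (f in seq(3, 13, by = 2)) {
    fr <- renderFrame(sc, f)
    for (i in 1:2) {
      if (!st$visible[f, i]) next
      g <- galleryAdd(g, i, extractDescriptor(fr, st$boxes[[i]][f, ],
                                              st$maskIdx[[i]][[f]]))
    }
  }
  # instrument 2 re-enters near frame 30 after its first exit
  f <- 32
  expect_true(st$visible[f, 2])
  q <- extractDescriptor(renderFrame(sc, f), st$boxes[[2]][f, ],
                         st$maskIdx[[2]][[f]])
  dec <- cascadeReid(NA, q, g)
  expect_equal(dec$identity, 2)

  # identical appearances tie -> incumbent retained by motion continuity
  gTie <- newGallery(5)
  dSame <- extractDescriptor(uniformPatch(0.5, 0.5, 0.5), c(0, 0, 24, 24))
  gTie <- galleryAdd(gTie, 1, dSame)
  gTie <- galleryAdd(gTie, 2, dSame)
  decTie <- cascadeReid(2, dSame, gTie, tieEps = 0.02)
  expect_equal(decTie$identity, 2)
})

test_that("cascade stage 2 arbitrates via the ten-frame window", {
  sc <- fixtureScene()
  st <- sceneTruth(sc)
  g <- newGallery(20)
  f0 <- 45
  for (f in seq(3, 13, by = 2)) {
    fr <- renderFrame(sc, f)
    for (i in 1:2) {
      if (!st$visible[f, i]) next
      g <- galleryAdd(g, i, extractDescriptor(fr, st$boxes[[i]][f, ],
                                              st$maskIdx[[i]][[f]]))
    }
  }
  winD <- list(); winI <- list()
  for (f in (f0 - 10):(f0 - 1)) {
    fr <- renderFrame(sc, f)
    for (i in 1:2) {
      if (!st$visible[f, i]) next
      p <- localPatchDescriptors(fr, st$boxes[[i]][f, ], st$maskIdx[[i]][[f]])
      if (nrow(p)) { winD <- c(winD, list(p)); winI <- c(winI, list(rep(i, nrow(p)))) }
    }
  }
  fr <- renderFrame(sc, f0)
  q <- extractDescriptor(fr, st$boxes[[1]][f0, ], st$maskIdx[[1]][[f0]])
  qp <- localPatchDescriptors(fr, st$boxes[[1]][f0, ], st$maskIdx[[1]][[f0]])
  # incumbent says 2, gallery says 1 -> BOVW arbitration runs and the
  # decision is one of the two candidates
  dec <- cascadeReid(2L, q, g, windowDescriptors = do.call(rbind, winD),
                     windowIdentity = unlist(winI), queryPatches = qp,
                     k = 16, seed = 2)
  expect_true(dec$stage2)
  expect_true(dec$identity %in% c(1L, 2L))
  expect_equal(dec$identity, 1L)  # appearance is unambiguous here
  # degenerate window falls back to the stage-1 proposal
  dec2 <- cascadeReid(2L, q, g, windowDescriptors = NULL,
                      queryPatches = qp)
  expect_false(dec2$stage2)
  expect_equal(dec2$identity, 1L)
})

test_that("CMC accuracy matches the worked rank example and is monotone", {
  ranked <- list(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3))
  truth <- c(1, 2, 3)
  expect_equal(cmcAccuracy(ranked, truth, 1), 1 / 3)
  expect_equal(cmcAccuracy(ranked, truth, 2), 2 / 3)
  expect_equal(cmcAccuracy(ranked, truth, 3), 1)
  expect_equal(cmcAccuracy(list(c(2, 1), c(3, 1)), c(1, 1), 1), 0)
  expect_equal(cmcAccuracy(list(c(1, 2), c(2, 3)), c(1, 2), 1), 1)
  expect_error(cmcAccuracy(list(), integer(0)), "queries")
  withr::with_seed(5, {
    for (rep in 1:10) {
      rl <- lapply(1:8, function(i) sample(1:3))
      tr <- sample(1:3, 8, replace = TRUE)
      accs <- vapply(1:3, function(k) cmcAccuracy(rl, tr, k), numeric(1))
      expect_false(is.unsorted(accs))
      expect_equal(accs[3], 1)
    }
  })
})
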