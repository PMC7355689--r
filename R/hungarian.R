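#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem by the Jonker-style
#' shortest-augmenting-path formulation of the Hungarian method (O(n^3)).
#' Every row (or column, whichever is fewer) is assigned; the total cost of
#' the returned assignment is the global minimum.
#'
#' This is the optimizer behind detection-to-track association: admissible
#' pairs carry a combined motion/appearance cost, inadmissible (gated) pairs a
#' large sentinel, and the final selection is the minimum-total-cost matching.
#'
#' @param cost Numeric cost matrix (finite entries).
#' @return Integer matrix with columns `row`, `col`: one row per assigned
#'   pair, ordered by `row`. `nrow` equals `min(dim(cost))`.
#' @examples
#' solveAssignment(matrix(c(0.1, 0.9, 0.9, 0.1), 2, byrow = TRUE))
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  if (length(cost) == 0) return(matrix(integer(0), 0, 2,
                                       dimnames = list(NULL, c("row", "col"))))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost); m <- ncol(cost)
  # potentials u (rows), v (cols); p[j] = row matched to column j (0 = none)
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)
  way <- integer(m + 1)
  INF <- .Machine$double.xmax / 4
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  rows <- integer(n); cols <- integer(n)
  k <- 0L
  for (j in seq_len(m)) {
    if (p[j + 1] > 0L) {
      k <- k + 1L
      rows[k] <- p[j + 1]; cols[k] <- j
    }
  }
  res <- cbind(row = rows[seq_len(k)], col = cols[seq_len(k)])
  if (transposed) res <- cbind(row = res[, "col"], col = res[, "row"])
  res[order(res[, "row"]), , drop = FALSE]
}
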