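# Constant-velocity Kalman filter in measurement space (cx, cy, aspect, h),
# following the SORT / deep-SORT convention: process and measurement noise
# are scaled to the box height, giving scale-invariant behavior.

KF_WP <- 1 / 20   # position noise weight (per unit box height)
KF_WV <- 1 / 160  # velocity noise weight

#' Box <-> Kalman measurement conversions
#'
#' Measurements are `(cx, cy, aspect, h)`: box center, width/height aspect
#' ratio, and height.
#'
#' @param box Numeric c(x, y, w, h).
#' @param z Numeric c(cx, cy, aspect, h).
#' @return The converted representation.
#' @export
boxToZ <- function(box) {
  c(box[1] + box[3] / 2, box[2] + box[4] / 2, box[3] / box[4], box[4])
}

#' @rdname boxToZ
#' @export
zToBox <- function(z) {
  w <- z[3] * z[4]
  c(z[1] - w / 2, z[2] - z[4] / 2, w, z[4])
}

#' Initialize a Kalman track state from a first measurement
#'
#' @param box Numeric c(x, y, w, h) with h > 0.
#' @return List with `mean` (length 8: measurement then velocities) and
#'   `cov` (8 x 8).
#' @export
kalmanInit <- function(box) {
  z <- boxToZ(box)
  if (z[4] <= 0) stop("box height must be positive")
  mean <- c(z, 0, 0, 0, 0)
  std <- c(2 * KF_WP * z[4], 2 * KF_WP * z[4], 1e-2, 2 * KF_WP * z[4],
           10 * KF_WV * z[4], 10 * KF_WV * z[4], 1e-5, 10 * KF_WV * z[4])
  list(mean = mean, cov = diag(std^2))
}

#' Kalman prediction under the constant-velocity model
#'
#' Advances the mean by `dt` frames of constant velocity and grows the
#' covariance by height-scaled process noise. Deterministic.
#'
#' @param state List(mean, cov) as from [kalmanInit()].
#' @param dt Prediction horizon in frames (>= 1).
#' @return Updated state.
#' @export
kalmanPredict <- function(state, dt = 1) {
  stopifnot(dt >= 1)
  FF <- diag(8)
  FF[1, 5] <- FF[2, 6] <- FF[3, 7] <- FF[4, 8] <- dt
  h <- state$mean[4]
  qstd <- c(KF_WP * h, KF_WP * h, 1e-2, KF_WP * h,
            KF_WV * h, KF_WV * h, 1e-5, KF_WV * h)
  Q <- diag(qstd^2) * dt
  mean <- as.numeric(FF %*% state$mean)
  cov <- FF %*% state$cov %*% t(FF) + Q
  list(mean = mean, cov = (cov + t(cov)) / 2)
}

measurementCov <- function(h, measurementVar = NULL) {
  if (!is.null(measurementVar)) {
    stopifnot(length(measurementVar) %in% c(1, 4))
    return(diag(rep(measurementVar, length.out = 4)))
  }
  rstd <- c(KF_WP * h, KF_WP * h, 1e-1, KF_WP * h)
  diag(rstd^2)
}

#' Kalman measurement update
#'
#' Standard linear correction with height-scaled measurement noise; the
#' posterior covariance trace over the measured components never exceeds the
#' prior's.
#'
#' @param state List(mean, cov).
#' @param z Measurement c(cx, cy, aspect, h), h > 0; a box can be converted
#'   with [boxToZ()].
#' @param measurementVar Optional explicit measurement variance (scalar or
#'   length 4) overriding the height-scaled default.
#' @return Updated state.
#' @export
kalmanUpdate <- function(state, z, measurementVar = NULL) {
  if (z[4] <= 0) stop("measurement height must be positive")
  H <- cbind(diag(4), matrix(0, 4, 4))
  R <- measurementCov(state$mean[4], measurementVar)
  y <- z - as.numeric(H %*% state$mean)
  S <- H %*% state$cov %*% t(H) + R
  K <- state$cov %*% t(H) %*% solve(S)
  mean <- state$mean + as.numeric(K %*% y)
  P <- (diag(8) - K %*% H) %*% state$cov
  list(mean = mean, cov = (P + t(P)) / 2)
}

#' Squared Mahalanobis distance of measurements from a predicted state
#'
#' Used for gating candidate associations at the chi-square 0.95 quantile
#' with 4 degrees of freedom (9.4877).
#'
#' @param state Predicted list(mean, cov).
#' @param zs Matrix of measurements (rows = candidates, 4 columns).
#' @return Numeric vector of squared distances.
#' @export
kalmanGatingDistance <- function(state, zs) {
  zs <- matrix(zs, ncol = 4)
  H <- cbind(diag(4), matrix(0, 4, 4))
  S <- H %*% state$cov %*% t(H) + measurementCov(state$mean[4])
  mu <- as.numeric(H %*% state$mean)
  d <- sweep(zs, 2, mu)
  Sinv <- solve(S)
  rowSums((d %*% Sinv) * d)
}
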