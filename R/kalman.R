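# Constant-velocity Kalman filter on the 8-D state
# (cx, cy, a, h, vcx, vcy, va, vh), where a = width/height. Process and
# measurement noise scale with the object height, the convention of the
# SORT-with-appearance tracker family.

KF_STD_POS <- 1 / 20
KF_STD_VEL <- 1 / 160
# Aspect-ratio noise. The pedestrian-tracking convention treats aspect as
# near-constant (process std 1e-2, init std 1e-2); fruit boxes here are
# clipped while entering/leaving through the frame edges, so the measured
# aspect changes quickly: the filter starts with an uncertain aspect (a
# newborn box may be mostly outside the frame) and keeps enough process
# noise to follow the clipping dynamics.
KF_STD_ASPECT <- 5e-2
KF_STD_ASPECT_INIT <- 1

box_to_measurement <- function(x, y, w, h) {
  c(x + w / 2, y + h / 2, w / h, h)
}

measurement_to_box <- function(z) {
  w <- z[3L] * z[4L]
  c(x = z[1L] - w / 2, y = z[2L] - z[4L] / 2, w = w, h = z[4L])
}

kf_initiate <- function(z) {
  h <- z[4L]
  mean <- c(z, rep(0, 4))
  std <- c(2 * KF_STD_POS * h, 2 * KF_STD_POS * h, KF_STD_ASPECT_INIT,
           2 * KF_STD_POS * h,
           10 * KF_STD_VEL * h, 10 * KF_STD_VEL * h, 1e-5, 10 * KF_STD_VEL * h)
  list(mean = mean, cov = diag(std^2))
}

kf_transition <- function() {
  F <- diag(8)
  F[cbind(1:4, 5:8)] <- 1
  F
}

kf_predict <- function(mean, cov) {
  # a long-coasting track with negative height velocity can drive the
  # height/aspect estimate nonpositive; floor them so the height-scaled
  # noise model stays valid
  mean[4L] <- max(mean[4L], 1)
  mean[3L] <- max(mean[3L], 1e-3)
  h <- mean[4L]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, KF_STD_ASPECT, KF_STD_POS * h,
           KF_STD_VEL * h, KF_STD_VEL * h, 1e-5, KF_STD_VEL * h)
  F <- kf_transition()
  mean <- as.numeric(F %*% mean)
  cov <- F %*% cov %*% t(F) + diag(std^2)
  if (any(!is.finite(cov)) || any(diag(cov) <= 0))
    stop("Kalman covariance lost positive-definiteness", call. = FALSE)
  list(mean = mean, cov = cov)
}

# Project state into measurement space: innovation covariance S and
# predicted measurement.
kf_project <- function(mean, cov) {
  h <- mean[4L]
  std <- c(KF_STD_POS * h, KF_STD_POS * h, 1e-1, KF_STD_POS * h)
  R <- diag(std^2)
  S <- cov[1:4, 1:4] + R
  list(z = mean[1:4], S = S, R = R)
}

kf_update <- function(mean, cov, z) {
  pr <- kf_project(mean, cov)
  K <- cov[, 1:4] %*% solve(pr$S)
  innov <- z - pr$z
  mean_new <- as.numeric(mean + K %*% innov)
  # Joseph-form update: keeps the covariance symmetric positive-definite
  # under long coast/update cycles
  IKH <- diag(8)
  IKH[, 1:4] <- IKH[, 1:4] - K
  cov_new <- IKH %*% cov %*% t(IKH) + K %*% pr$R %*% t(K)
  cov_new <- (cov_new + t(cov_new)) / 2
  list(mean = mean_new, cov = cov_new)
}

# Squared Mahalanobis distance of measurements (rows of Z, 4 cols) from the
# projected state.
kf_gating_distance <- function(mean, cov, Z) {
  pr <- kf_project(mean, cov)
  diff <- sweep(Z, 2L, pr$z)
  Sinv <- solve(pr$S)
  rowSums((diff %*% Sinv) * diff)
}
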