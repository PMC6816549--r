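#' Linear-Gaussian motion model for particle tracks
#'
#' The unobserved particle state is `X = (x, vx, y, vy)`: position plus
#' velocity. Per frame the position performs a random walk driven by its
#' velocity and the velocity performs its own random walk: the transition
#' matrix `F` moves each position by its velocity, and the process noise is
#' diagonal with variance `q_pos` (px^2/frame) on the positions and `q_vel`
#' ((px/frame)^2/frame) on the velocities, independently in x and y. The
#' observation matrix `B` projects the state onto position, with observation
#' noise covariance `R` (px^2). The initial-state prior is centred on the
#' first observed position with zero velocity and near-diffuse covariance
#' `diag(sigma0^2, sigmav^2, sigma0^2, sigmav^2)`.
#'
#' @param q_pos position process-noise variance per frame (px^2/frame).
#' @param q_vel velocity process-noise variance per frame
#'   ((px/frame)^2/frame).
#' @param R 2x2 symmetric positive-definite observation-noise covariance
#'   (px^2); a scalar is expanded to `diag(R, 2)`.
#' @param prior_sigma0 prior position standard deviation (px).
#' @param prior_sigmav prior velocity standard deviation (px/frame).
#' @return An object of class `spt_motion_model` with components `F_mat`,
#'   `Q_proc`, `B`, `R`, `prior_cov`.
#' @export
state_space_model <- function(q_pos = 1.0, q_vel = 0.1, R = 0.01,
                              prior_sigma0 = 10, prior_sigmav = 2) {
  if (length(R) == 1L) R <- diag(as.numeric(R), 2L)
  R <- as.matrix(R)
  stopifnot(nrow(R) == 2L, ncol(R) == 2L, isTRUE(all.equal(R, t(R))))
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("R must be positive definite")
  F1 <- matrix(c(1, 0, 1, 1), 2L, 2L)   # per-axis [[1,1],[0,1]]
  F_mat <- matrix(0, 4L, 4L)
  F_mat[1:2, 1:2] <- F1
  F_mat[3:4, 3:4] <- F1
  Q_proc <- diag(c(q_pos, q_vel, q_pos, q_vel))
  B <- matrix(0, 2L, 4L)
  B[1L, 1L] <- 1
  B[2L, 3L] <- 1
  structure(list(F_mat = F_mat, Q_proc = Q_proc, B = B, R = R,
                 q_pos = q_pos, q_vel = q_vel,
                 prior_sigma0 = prior_sigma0, prior_sigmav = prior_sigmav,
                 prior_cov = diag(c(prior_sigma0^2, prior_sigmav^2,
                                    prior_sigma0^2, prior_sigmav^2))),
            class = "spt_motion_model")
}

.track_frames_xy <- function(track_ids, obs) {
  idx <- match(track_ids, obs$id)
  if (anyNA(idx)) stop("track references unknown observation ids")
  list(t = obs$t[idx], y = rbind(obs$x[idx], obs$y[idx]))
}

#' Kalman filter over a track
#'
#' Runs the predict/update recursion frame by frame from the track's birth
#' to its death. Frames without an observation (blinking gaps) perform a
#' predict step only. At an observed frame the innovation covariance is
#' `S = B P_pred B' + R` and the observation contributes the bivariate
#' normal log-density of its position under mean `B X_pred`, covariance `S`.
#' The first observation is scored against the initial prior, which is
#' centred on its position, so every assigned observation contributes a
#' likelihood term. The update uses the Joseph form so covariances stay
#' symmetric positive semi-definite.
#'
#' @param track_ids integer vector of observation ids in time order.
#' @param obs an `spt_observations` object.
#' @param model an `spt_motion_model`.
#' @return An object of class `spt_track_inference`: a list with `times`
#'   (frames covered), `pred_mean`, `pred_cov`, `filt_mean`, `filt_cov`
#'   (lists indexed per covered frame), `observed` (logical per frame),
#'   `innovations` (data frame with per-observation residuals, innovation
#'   covariance entries and log-likelihood contributions) and
#'   `log_likelihood`.
#' @export
kalman_filter <- function(track_ids, obs, model) {
  if (length(track_ids) < 2L) stop("a track must have at least 2 observations")
  tr <- .track_frames_xy(track_ids, obs)
  times <- tr$t[1L]:tr$t[length(tr$t)]
  nt <- length(times)
  Fm <- model$F_mat; Q <- model$Q_proc; B <- model$B; R <- model$R
  I4 <- diag(4L)
  pred_mean <- filt_mean <- vector("list", nt)
  pred_cov <- filt_cov <- vector("list", nt)
  observed <- times %in% tr$t
  inn <- list()
  x <- c(tr$y[1L, 1L], 0, tr$y[2L, 1L], 0)
  P <- model$prior_cov
  ll <- 0
  k_obs <- 0L
  for (i in seq_len(nt)) {
    if (i > 1L) {
      x <- Fm %*% x
      P <- Fm %*% P %*% t(Fm) + Q
    }
    pred_mean[[i]] <- as.numeric(x)
    pred_cov[[i]] <- P
    if (observed[i]) {
      k_obs <- k_obs + 1L
      yk <- tr$y[, k_obs]
      S <- B %*% P %*% t(B) + R
      S <- (S + t(S)) / 2
      detS <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
      if (!is.finite(detS) || detS <= 0)
        stop(sprintf("innovation covariance not positive definite (det = %g)",
                     detS))
      r <- yk - as.numeric(B %*% x)
      Sinv <- matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2L) / detS
      llk <- -log(2 * pi) - 0.5 * log(detS) -
        0.5 * as.numeric(t(r) %*% Sinv %*% r)
      ll <- ll + llk
      K <- P %*% t(B) %*% Sinv
      x <- x + K %*% r
      IKB <- I4 - K %*% B
      P <- IKB %*% P %*% t(IKB) + K %*% R %*% t(K)
      P <- (P + t(P)) / 2
      inn[[k_obs]] <- c(id = track_ids[k_obs], t = times[i],
                        rx = r[1], ry = r[2],
                        s_xx = S[1, 1], s_xy = S[1, 2], s_yy = S[2, 2],
                        loglik = llk)
    }
    filt_mean[[i]] <- as.numeric(x)
    filt_cov[[i]] <- P
  }
  structure(list(times = times, observed = observed,
                 pred_mean = pred_mean, pred_cov = pred_cov,
                 filt_mean = filt_mean, filt_cov = filt_cov,
                 smooth_mean = NULL, smooth_cov = NULL,
                 innovations = as.data.frame(do.call(rbind, inn)),
                 log_likelihood = ll, model = model),
            class = "spt_track_inference")
}

#' Rauch-Tung-Striebel smoother
#'
#' Backwards pass over a filtered track: smoothed means and covariances for
#' every covered frame, including unobserved gap frames. At the last frame
#' the smoothed estimate equals the filtered one; elsewhere the smoothed
#' covariance never exceeds the filtered covariance in the Loewner order.
#'
#' @param inference an `spt_track_inference` from [kalman_filter()].
#' @param model the `spt_motion_model` used for filtering (defaults to the
#'   one recorded in `inference`).
#' @return The inference object with `smooth_mean` and `smooth_cov` filled.
#' @export
rts_smooth <- function(inference, model = inference$model) {
  nt <- length(inference$times)
  Fm <- model$F_mat
  sm <- vector("list", nt)
  sc <- vector("list", nt)
  sm[[nt]] <- inference$filt_mean[[nt]]
  sc[[nt]] <- inference$filt_cov[[nt]]
  for (i in seq.int(nt - 1L, length.out = nt - 1L, by = -1L)) {
    Pf <- inference$filt_cov[[i]]
    Pp <- inference$pred_cov[[i + 1L]]
    G <- Pf %*% t(Fm) %*% solve(Pp)
    sm[[i]] <- inference$filt_mean[[i]] +
      as.numeric(G %*% (sm[[i + 1L]] - inference$pred_mean[[i + 1L]]))
    P <- Pf + G %*% (sc[[i + 1L]] - Pp) %*% t(G)
    sc[[i]] <- (P + t(P)) / 2
  }
  inference$smooth_mean <- sm
  inference$smooth_cov <- sc
  inference
}

#' Log-likelihood of a track's observations
#'
#' The sum of the per-observation innovation log-densities from the Kalman
#' filter: the track likelihood `P(Y^i | k_i, theta)` in the posterior
#' factorisation. Reassigning any single observation changes the state
#' estimates and hence the likelihood terms of *all* observations of the
#' track, not only the reassigned one.
#'
#' @inheritParams kalman_filter
#' @return A finite scalar log-likelihood.
#' @export
track_log_likelihood <- function(track_ids, obs, model) {
  kalman_filter(track_ids, obs, model)$log_likelihood
}

#' Smoothed observation residuals of a track
#'
#' Residuals `y - B x_smoothed` for every observation of the track, used as
#' the evidence term of the observation-noise covariance update.
#'
#' @inheritParams kalman_filter
#' @return A matrix with one row per observation and columns `rx`, `ry`.
#' @export
track_residuals <- function(track_ids, obs, model) {
  inf <- rts_smooth(kalman_filter(track_ids, obs, model))
  tr <- .track_frames_xy(track_ids, obs)
  idx <- match(tr$t, inf$times)
  res <- t(vapply(seq_along(idx), function(k) {
    xs <- inf$smooth_mean[[idx[k]]]
    c(tr$y[1L, k] - xs[1L], tr$y[2L, k] - xs[3L])
  }, numeric(2)))
  colnames(res) <- c("rx", "ry")
  res
}
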