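#' Draw the tracking parameters from their conjugate conditionals
#'
#' Given the current partition's counting statistics and the smoothed
#' observation residuals of its tracks, all seven parameter dimensions are
#' sampled directly and independently:
#' \itemize{
#' \item `lambda_b ~ Gamma(sum(n_births) + 1, T * fov/A)` and
#'   `lambda_c ~ Gamma(sum(n_clutter) + 1, T * fov/A)` (shape + 1 comes
#'   from the flat improper prior on the positive rates; the rate is the
#'   exposure in frame-area units),
#' \item `p_o ~ Beta(n_observed + 1, n_dark + 1)`,
#' \item `p_s ~ Beta(n_survive + 1, n_die + 1)` (uniform priors), and
#' \item `R ~ InvWishart(Phi + sum(r r'), s + n_observed)` where `r` are
#'   the residuals of the observations about a state trajectory drawn from
#'   the smoothing distribution of the track model (conditioning on sampled
#'   states keeps this update exactly conjugate).
#' }
#' With an empty partition every draw falls back to its prior.
#'
#' @param stats an `spt_partition_stats` object.
#' @param residuals numeric matrix of per-observation state-conditional
#'   residuals (columns `rx`, `ry`), or the 2x2 sum `crossprod(residuals)`
#'   via `resid_sum` below.
#' @param obs an `spt_observations` object.
#' @param prior an `spt_prior_config`.
#' @param resid_sum optional precomputed 2x2 residual scatter matrix; if
#'   given, `residuals` is ignored and `resid_n` must be the residual
#'   count.
#' @param resid_n residual count accompanying `resid_sum`.
#' @return An `spt_parameters` draw.
#' @export
sample_parameters <- function(stats, residuals = NULL, obs,
                              prior = prior_config(),
                              resid_sum = NULL, resid_n = NULL) {
  exposure <- n_frames(obs) * area_ratio(obs)
  if (exposure <= 0) exposure <- 1
  lambda_b <- stats::rgamma(1L, shape = sum(stats$n_births) + 1, rate = exposure)
  lambda_c <- stats::rgamma(1L, shape = sum(stats$n_clutter) + 1, rate = exposure)
  p_o <- stats::rbeta(1L, stats$n_observed + 1, stats$n_dark + 1)
  p_s <- stats::rbeta(1L, stats$n_survive + 1, stats$n_die + 1)
  if (is.null(resid_sum)) {
    if (is.null(residuals) || NROW(residuals) == 0L) {
      resid_sum <- matrix(0, 2L, 2L)
      resid_n <- 0L
    } else {
      resid_sum <- crossprod(as.matrix(residuals))
      resid_n <- NROW(residuals)
    }
  }
  R <- rinvwishart(prior$s + resid_n, prior$Phi + resid_sum)
  parameters(lambda_b = lambda_b, lambda_c = lambda_c,
             p_o = min(max(p_o, 1e-12), 1 - 1e-12),
             p_s = min(max(p_s, 1e-12), 1 - 1e-12), R = R)
}

#' Inverse-Wishart draw
#'
#' Samples `X ~ IW(Psi, nu)` through the Wishart dual: if
#' `W ~ Wishart(nu, Psi^-1)` then `W^-1 ~ IW(Psi, nu)`. Uses
#' [stats::rWishart()].
#'
#' @param nu degrees of freedom (> dimension - 1).
#' @param Psi positive-definite scale matrix.
#' @export
rinvwishart <- function(nu, Psi) {
  W <- stats::rWishart(1L, df = nu, Sigma = solve(Psi))[, , 1L]
  X <- solve(W)
  (X + t(X)) / 2
}

#' Gibbs draw of the parameters given a partition
#'
#' Convenience wrapper: computes the partition statistics, draws a state
#' trajectory for every track by forward-filtering backward-sampling, and
#' calls [sample_parameters()] with the residuals about the sampled states.
#' This is the conditional `P(theta | omega, Y)`; iterating it with a fixed
#' ground-truth partition gives the reference parameter posterior used in
#' recovery checks.
#'
#' @param part an `spt_partition`.
#' @param obs an `spt_observations` object.
#' @param model an `spt_motion_model` (its `R` is the current noise guess
#'   used for state estimation).
#' @param prior an `spt_prior_config`.
#' @export
sample_parameters_given_partition <- function(part, obs,
                                              model = state_space_model(),
                                              prior = prior_config()) {
  # a wide-open gate: this partition is given, not proposed
  cfg <- sampler_config(q_pos = model$q_pos, q_vel = model$q_vel,
                        prior_sigma0 = model$prior_sigma0,
                        prior_sigmav = model$prior_sigmav,
                        max_speed = 1e6,
                        gate_frames = max(4L, n_frames(obs)))
  theta0 <- parameters(R = model$R)
  res <- .run_core(part, obs, theta0, cfg, 0L)
  st <- structure(res$stats, class = "spt_partition_stats")
  sample_parameters(st, obs = obs, prior = prior,
                    resid_sum = res$resid_sum, resid_n = res$resid_n)
}
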