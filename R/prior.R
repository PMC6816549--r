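#' Tracking parameters
#'
#' The seven scalar degrees of freedom that govern the track partition and
#' the observation noise: the birth rate `lambda_b` and clutter rate
#' `lambda_c` (events per frame per normalised area), the observation
#' probability `p_o`, the survival probability `p_s` and the 2x2 symmetric
#' observation-noise covariance `R` (3 free entries).
#'
#' @param lambda_b,lambda_c non-negative rates in E (events per frame per
#'   100 px x 100 px).
#' @param p_o,p_s probabilities in (0, 1).
#' @param R 2x2 symmetric positive-definite matrix (px^2); a scalar is
#'   expanded to `diag(R, 2)`.
#' @return An object of class `spt_parameters`.
#' @export
parameters <- function(lambda_b = 0.5, lambda_c = 0.5, p_o = 0.8,
                       p_s = 0.9, R = 0.01) {
  if (length(R) == 1L) R <- diag(as.numeric(R), 2L)
  stopifnot(lambda_b >= 0, lambda_c >= 0,
            p_o > 0, p_o < 1, p_s > 0, p_s < 1,
            nrow(R) == 2L, ncol(R) == 2L)
  structure(list(lambda_b = lambda_b, lambda_c = lambda_c,
                 p_o = p_o, p_s = p_s, R = as.matrix(R)),
            class = "spt_parameters")
}

#' @export
print.spt_parameters <- function(x, ...) {
  cat(sprintf(
    "<spt_parameters> lambda_b=%.4g lambda_c=%.4g p_o=%.4g p_s=%.4g R=[%.4g %.4g; %.4g %.4g]\n",
    x$lambda_b, x$lambda_c, x$p_o, x$p_s,
    x$R[1, 1], x$R[1, 2], x$R[2, 1], x$R[2, 2]))
  invisible(x)
}

#' Number of scalar degrees of freedom of a parameter object
#' @param theta an `spt_parameters` object.
#' @export
n_parameters <- function(theta) {
  4L + 3L  # lambda_b, lambda_c, p_o, p_s + symmetric 2x2 R
}

#' Prior configuration for the parameter conditionals
#'
#' The rates carry improper flat priors on (0, Inf), the probabilities
#' uniform priors on (0, 1), and the observation-noise covariance `R` an
#' inverse-Wishart prior IW(Phi, s) with `Phi = phi_scale * I` and
#' `s = wishart_dof` degrees of freedom (s > 3 so the prior mean exists).
#'
#' @param phi_scale scale of the inverse-Wishart scale matrix (px^2).
#' @param wishart_dof inverse-Wishart degrees of freedom.
#' @export
prior_config <- function(phi_scale = 0.01, wishart_dof = 4) {
  stopifnot(phi_scale > 0, wishart_dof > 3)
  structure(list(Phi = diag(phi_scale, 2L), s = wishart_dof),
            class = "spt_prior_config")
}

#' Sufficient counts of a partition
#'
#' The counting statistics that drive both the partition prior and the
#' conjugate parameter conditionals: births per frame, clutter per frame,
#' observed and dark (unobserved, within-lifetime) track-frames, and
#' frame-to-frame survivals and deaths. Tracks still alive at the final
#' frame contribute no death event (right-censoring by the end of the
#' movie).
#'
#' @param part an `spt_partition`.
#' @param obs an `spt_observations` object.
#' @return An object of class `spt_partition_stats`: list with `n_births`
#'   and `n_clutter` (integer vectors of length `T`), and scalars
#'   `n_observed`, `n_dark`, `n_survive`, `n_die`.
#' @export
partition_stats <- function(part, obs) {
  Tn <- n_frames(obs)
  n_births <- integer(Tn)
  n_clutter <- integer(Tn)
  n_observed <- 0L
  n_dark <- 0L
  n_survive <- 0L
  n_die <- 0L
  for (tr in part$tracks) {
    tt <- obs$t[match(tr, obs$id)]
    tb <- tt[1L]
    td <- tt[length(tt)]
    n_births[tb + 1L] <- n_births[tb + 1L] + 1L
    span <- td - tb + 1L
    n_observed <- n_observed + length(tr)
    n_dark <- n_dark + (span - length(tr))
    n_survive <- n_survive + (span - 1L)
    if (td < Tn - 1L) n_die <- n_die + 1L
  }
  if (length(part$clutter)) {
    tc <- obs$t[match(part$clutter, obs$id)]
    tab <- tabulate(tc + 1L, nbins = Tn)
    n_clutter <- as.integer(tab)
  }
  structure(list(n_births = n_births, n_clutter = n_clutter,
                 n_observed = n_observed, n_dark = n_dark,
                 n_survive = n_survive, n_die = n_die),
            class = "spt_partition_stats")
}

#' Log prior probability of a track partition
#'
#' `log P(omega | theta)`: the assignment part of the posterior, ignoring
#' the physical positions. Births and clutter counts are per-frame Poisson
#' with area-scaled means `lambda_b * (fov area / A)` and
#' `lambda_c * (fov area / A)`; survival is per-frame Bernoulli with
#' probability `p_s` (so track lifetimes are geometric with mean
#' `1 / (1 - p_s)`, right-censored at the end of the movie); each
#' within-lifetime frame is observed with probability `p_o`. Exactly these
#' forms make the Gamma/Beta parameter conditionals conjugate.
#'
#' @param stats an `spt_partition_stats` object.
#' @param theta an `spt_parameters` object.
#' @param obs an `spt_observations` object.
#' @return Scalar log-probability.
#' @export
log_partition_prior <- function(stats, theta, obs) {
  if (theta$p_o <= 0 || theta$p_o >= 1 || theta$p_s <= 0 || theta$p_s >= 1)
    stop("p_o and p_s must lie strictly inside (0, 1)")
  mu_b <- theta$lambda_b * area_ratio(obs)
  mu_c <- theta$lambda_c * area_ratio(obs)
  sum(stats::dpois(stats$n_births, mu_b, log = TRUE)) +
    sum(stats::dpois(stats$n_clutter, mu_c, log = TRUE)) +
    stats$n_survive * log(theta$p_s) + stats$n_die * log1p(-theta$p_s) +
    stats$n_observed * log(theta$p_o) + stats$n_dark * log1p(-theta$p_o)
}

#' Log-likelihood of the clutter observations
#'
#' Clutter positions are uniform over the field of view, so each clutter
#' observation contributes `log(1 / fov area)`.
#'
#' @param part an `spt_partition`.
#' @param obs an `spt_observations` object.
#' @export
log_clutter_likelihood <- function(part, obs) {
  -length(part$clutter) * log(prod(fov(obs)))
}

#' Log density of the parameter priors
#'
#' Flat (improper) on the rates, uniform on the probabilities, and
#' inverse-Wishart IW(Phi, s) on `R`. Constant across partitions; it only
#' matters when comparing parameter values.
#'
#' @param theta an `spt_parameters` object.
#' @param prior an `spt_prior_config` object.
#' @export
log_parameter_prior <- function(theta, prior = prior_config()) {
  R <- theta$R
  s <- prior$s
  Phi <- prior$Phi
  p <- 2
  detR <- R[1, 1] * R[2, 2] - R[1, 2] * R[2, 1]
  if (detR <= 0) return(-Inf)
  Rinv <- matrix(c(R[2, 2], -R[2, 1], -R[1, 2], R[1, 1]), 2L) / detR
  lmgamma <- 0.5 * p * (p - 1) / 2 * log(pi) +
    sum(lgamma(s / 2 + (1 - seq_len(p)) / 2))
  0.5 * s * determinant(Phi)$modulus[1] - 0.5 * s * p * log(2) - lmgamma -
    0.5 * (s + p + 1) * log(detR) - 0.5 * sum(diag(Phi %*% Rinv))
}

#' Unnormalised log posterior of a partition
#'
#' `log P(omega | theta, Y)` up to a constant: the clutter likelihood plus
#' the product of per-track Kalman likelihoods plus the partition prior,
#' optionally plus the parameter prior. Only ratios across partitions (or
#' parameter values) are meaningful.
#'
#' @param part an `spt_partition`.
#' @param theta an `spt_parameters` object.
#' @param obs an `spt_observations` object.
#' @param model an `spt_motion_model`; its `R` slot is overridden by
#'   `theta$R`.
#' @param prior an `spt_prior_config`, or `NULL` to omit the parameter
#'   prior term (it is constant across partitions).
#' @export
log_posterior <- function(part, theta, obs, model = state_space_model(),
                          prior = prior_config()) {
  model$R <- theta$R
  ll_tracks <- sum(vapply(part$tracks, track_log_likelihood, numeric(1),
                          obs = obs, model = model))
  out <- log_clutter_likelihood(part, obs) + ll_tracks +
    log_partition_prior(partition_stats(part, obs), theta, obs)
  if (!is.null(prior)) out <- out + log_parameter_prior(theta, prior)
  out
}
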