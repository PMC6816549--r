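#' Mean squared displacement of a partition's tracks
#'
#' For each time lag `tau` up to `max_lag`, the average squared
#' displacement over all pairs of observations within a track separated by
#' exactly `tau` frames, pooled over all tracks (per-pair pooling, so long
#' tracks contribute more pairs). Dark frames contribute no pairs at their
#' nominal lag.
#'
#' @param part an `spt_partition`.
#' @param obs an `spt_observations` object.
#' @param max_lag largest lag (frames).
#' @return An object of class `spt_msd`: data frame with columns `tau`,
#'   `msd` (px^2) and `n_pairs`; lags without pairs are dropped.
#' @export
msd <- function(part, obs, max_lag = 8L) {
  acc <- numeric(max_lag)
  cnt <- integer(max_lag)
  for (tr in part$tracks) {
    idx <- match(tr, obs$id)
    tt <- obs$t[idx]
    xx <- obs$x[idx]
    yy <- obs$y[idx]
    m <- length(tr)
    for (i in seq_len(m - 1L)) {
      js <- (i + 1L):m
      lag <- tt[js] - tt[i]
      keep <- lag <= max_lag
      if (!any(keep)) next
      lag <- lag[keep]
      d2 <- (xx[js][keep] - xx[i])^2 + (yy[js][keep] - yy[i])^2
      for (k in seq_along(lag)) {
        acc[lag[k]] <- acc[lag[k]] + d2[k]
        cnt[lag[k]] <- cnt[lag[k]] + 1L
      }
    }
  }
  keep <- cnt > 0L
  out <- data.frame(tau = seq_len(max_lag)[keep], msd = acc[keep] / cnt[keep],
                    n_pairs = cnt[keep])
  class(out) <- c("spt_msd", "data.frame")
  out
}

#' Diffusion coefficient from an MSD curve
#'
#' Weighted least-squares fit of `msd = intercept + slope * tau` over the
#' fitted lags, with pair counts as weights; `D = slope / 4` for 2-D
#' diffusion. Localisation noise inflates the intercept, not the slope.
#'
#' @param curve an `spt_msd` data frame.
#' @param fit_lags lags (frames) used in the fit.
#' @return `D` in px^2/frame.
#' @export
diffusion_coefficient <- function(curve, fit_lags = 1:4) {
  cc <- curve[curve$tau %in% fit_lags, , drop = FALSE]
  if (nrow(cc) < 2L)
    stop("need MSD values at >= 2 of the fitted lags")
  fit <- stats::lm(msd ~ tau, data = cc, weights = cc$n_pairs)
  unname(stats::coef(fit)["tau"]) / 4
}

#' Smallest interval containing a given fraction of samples
#'
#' The credible interval at level `X` is the narrowest contiguous window of
#' sorted sample values that contains at least a fraction `X` of them;
#' ties are broken towards the lower start.
#'
#' @param values numeric sample vector (>= 2 values).
#' @param level fraction in (0, 1].
#' @return Numeric `c(lo, hi)`.
#' @export
smallest_interval_ci <- function(values, level = 0.95) {
  stopifnot(level > 0, level <= 1, length(values) >= 2L)
  v <- sort(values)
  n <- length(v)
  m <- ceiling(level * n)
  if (m < 1L) m <- 1L
  if (m >= n) return(c(v[1L], v[n]))
  starts <- seq_len(n - m + 1L)
  widths <- v[starts + m - 1L] - v[starts]
  s <- starts[which.min(widths)]  # which.min takes the first (lowest) start
  c(v[s], v[s + m - 1L])
}

#' Coverage of smallest-interval credible intervals
#'
#' For a collection of experiments, each providing a posterior sample of
#' the diffusion coefficient and the ground-truth-realisation value, the
#' fraction of experiments whose smallest-interval CI contains the
#' reference value.
#'
#' @param experiments list of `list(D_samples, D_gtr)`.
#' @param level credible level.
#' @return Fraction in `[0, 1]`.
#' @export
ci_coverage <- function(experiments, level = 0.95) {
  stopifnot(length(experiments) >= 1L)
  hits <- vapply(experiments, function(e) {
    ci <- smallest_interval_ci(e$D_samples, level)
    e$D_gtr >= ci[1L] && e$D_gtr <= ci[2L]
  }, logical(1))
  mean(hits)
}

#' Posterior sample of the diffusion coefficient
#'
#' Computes one diffusion coefficient per recorded partition sample: the
#' tracking uncertainty propagated into the derived quantity.
#'
#' @param samples list of `spt_partition` samples.
#' @param obs an `spt_observations` object.
#' @param fit_lags lags used by the MSD fit.
#' @return Numeric vector, one `D` per sample (NA where a sample has too
#'   few displacement pairs).
#' @export
diffusion_posterior <- function(samples, obs, fit_lags = 1:4) {
  vapply(samples, function(p) {
    tryCatch(diffusion_coefficient(msd(p, obs, max_lag = max(fit_lags)),
                                   fit_lags),
             error = function(e) NA_real_)
  }, numeric(1))
}
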