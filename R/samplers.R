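#' Sampler configuration
#'
#' All tunable knobs of the tracker in one place.
#'
#' @param max_speed maximum particle speed (px/frame) used to gate candidate
#'   links; generous by design, well above anything physiological.
#' @param gate_frames maximum frame gap of a candidate link; gaps up to
#'   `gate_frames - 1` dark frames can be bridged.
#' @param birth_stop per-step stop probability of the birth/extend chain
#'   assembly.
#' @param greedy_gate frame gap used by the greedy initial partition.
#' @param q_pos,q_vel process-noise variances of the motion model
#'   (px^2/frame and (px/frame)^2/frame).
#' @param prior_sigma0,prior_sigmav initial-state prior standard deviations
#'   (px and px/frame).
#' @param phi_scale,wishart_dof inverse-Wishart prior on the observation
#'   noise.
#' @param steps_per_sweep Metropolis-Hastings partition steps between
#'   parameter draws; default `max(N, 100)`.
#' @param check_every convergence test cadence, in sweeps.
#' @param check_window trailing window of per-sweep snapshots used by the
#'   convergence test.
#' @param min_sweeps minimum burn-in sweeps before testing convergence.
#' @param max_sweeps burn-in budget, in sweeps.
#' @param n_record recorded (thinned) partition samples per chain.
#' @param ged_pairs sample-pair budget of the graph-edit-distance estimates.
#' @param psrf_threshold Gelman-Rubin threshold for the four scalar
#'   tracking parameters.
#' @param thin_coef numerator of the thinning rule: 1 in
#'   `round(thin_coef / acceptance_rate)` samples is recorded (1 in 8 at a
#'   25% acceptance rate).
#' @return A list of class `spt_config`.
#' @export
sampler_config <- function(max_speed = 16, gate_frames = 4, birth_stop = 0.5,
                           greedy_gate = 2,
                           q_pos = 1.0, q_vel = 0.1,
                           prior_sigma0 = 10, prior_sigmav = 2,
                           phi_scale = 0.01, wishart_dof = 4,
                           steps_per_sweep = NULL,
                           check_every = 200, check_window = 40,
                           min_sweeps = 400, max_sweeps = 20000,
                           n_record = 4000, ged_pairs = 200,
                           psrf_threshold = 1.1, thin_coef = 2) {
  structure(as.list(environment()), class = "spt_config")
}

.model_from_cfg <- function(cfg) {
  state_space_model(q_pos = cfg$q_pos, q_vel = cfg$q_vel,
                    prior_sigma0 = cfg$prior_sigma0,
                    prior_sigmav = cfg$prior_sigmav)
}

.prior_from_cfg <- function(cfg) {
  prior_config(phi_scale = cfg$phi_scale, wishart_dof = cfg$wishart_dof)
}

#' One Metropolis-Hastings partition step
#'
#' Proposes a partition and accepts it with probability
#' `min(1, P(w*|th,Y)/P(w|th,Y) * Q(w|w*)/Q(w*|w))`, evaluated in log
#' space. Identity proposals are trivially accepted (the state does not
#' change) but bookkept as `"identity"`, which counts as a rejection in
#' acceptance-rate statistics.
#'
#' @param current an `spt_partition`.
#' @param theta an `spt_parameters` object.
#' @param obs an `spt_observations` object.
#' @param cfg a [sampler_config()].
#' @return A list with `partition` and `outcome` (one of `"accepted"`,
#'   `"rejected"`, `"identity"`) plus the proposal bookkeeping.
#' @export
mh_step <- function(current, theta, obs, cfg = sampler_config()) {
  pr <- propose(current, obs, cfg)
  if (pr$is_identity)
    return(list(partition = current, outcome = "identity", proposal = pr))
  model <- .model_from_cfg(cfg)
  lp_cur <- log_posterior(current, theta, obs, model, prior = NULL)
  lp_new <- log_posterior(pr$proposal, theta, obs, model, prior = NULL)
  logr <- lp_new - lp_cur + pr$log_q_rev - pr$log_q_fwd
  if (!is.finite(logr)) {
    warning("non-finite posterior ratio; proposal rejected")
    return(list(partition = current, outcome = "rejected", proposal = pr))
  }
  if (log(stats::runif(1L)) < logr)
    list(partition = pr$proposal, outcome = "accepted", proposal = pr)
  else
    list(partition = current, outcome = "rejected", proposal = pr)
}

#' Thinning interval from the acceptance rate
#'
#' One in `n` partition samples is recorded, with `n = round(2 /
#' acceptance_rate)` (capped): an acceptance rate of 25% gives `n = 8`,
#' and the lower the acceptance rate the sparser the recording, since
#' consecutive samples of a slowly moving chain are nearly identical. A
#' degenerate chain that never accepts records every sample.
#'
#' @param acceptance_rate fraction in `[0, 1]`.
#' @param thin_coef numerator of the rule (default 2, fixed by the
#'   25% -> 8 anchor).
#' @param max_interval cap on the interval.
#' @return Integer interval `n >= 1`.
#' @export
thinning_interval <- function(acceptance_rate, thin_coef = 2,
                              max_interval = 1000L) {
  stopifnot(acceptance_rate >= 0, acceptance_rate <= 1)
  if (acceptance_rate == 0) return(1L)
  max(1L, min(as.integer(max_interval),
              as.integer(round(thin_coef / acceptance_rate))))
}

# mean GED between two sets of link-key vectors, over at most max_pairs
# random (or all) pairs
.mean_ged_keys <- function(keys_a, keys_b = NULL, max_pairs = 200) {
  inner <- is.null(keys_b)
  if (inner) keys_b <- keys_a
  na <- length(keys_a)
  nb <- length(keys_b)
  if (na == 0L || nb == 0L || (inner && na < 2L)) return(NA_real_)
  pairs <- if (inner) {
    cbind(sample.int(na, max_pairs, replace = TRUE),
          sample.int(na, max_pairs, replace = TRUE))
  } else {
    cbind(sample.int(na, max_pairs, replace = TRUE),
          sample.int(nb, max_pairs, replace = TRUE))
  }
  if (inner) {
    same <- pairs[, 1L] == pairs[, 2L]
    pairs[same, 2L] <- (pairs[same, 1L] %% na) + 1L
  }
  mean(vapply(seq_len(nrow(pairs)), function(k) {
    a <- keys_a[[pairs[k, 1L]]]
    b <- keys_b[[pairs[k, 2L]]]
    length(setdiff(a, b)) + length(setdiff(b, a))
  }, numeric(1)))
}

.part_link_keys <- function(tracks, n_ids) {
  unlist(lapply(tracks, function(tr) {
    m <- length(tr)
    if (m < 2L) return(numeric())
    as.numeric(tr[-m]) * (n_ids + 1) + as.numeric(tr[-1L])
  }), use.names = FALSE)
}

.convergence_from <- function(keys_a, keys_b, theta_a, theta_b,
                              psrf_threshold, max_pairs) {
  cross <- .mean_ged_keys(keys_a, keys_b, max_pairs)
  inner_a <- .mean_ged_keys(keys_a, NULL, max_pairs)
  inner_b <- .mean_ged_keys(keys_b, NULL, max_pairs)
  psrf <- vapply(c("lambda_b", "lambda_c", "p_o", "p_s"), function(p) {
    if (NROW(theta_a) < 10L || NROW(theta_b) < 10L) return(Inf)
    gelman_rubin(cbind(theta_a[, p], theta_b[, p]))
  }, numeric(1))
  ged_ok <- is.finite(cross) && is.finite(inner_a) && is.finite(inner_b) &&
    cross <= inner_a + inner_b
  structure(list(cross_ged_mean = cross,
                 inner_ged_means = c(inner_a, inner_b),
                 psrf = psrf,
                 converged = ged_ok && all(psrf < psrf_threshold)),
            class = "spt_convergence")
}

#' Convergence diagnostics for a pair of chains
#'
#' Two tests must pass: the average cross-chain graph edit distance between
#' recorded partitions must not exceed the sum of the two average
#' inner-chain distances, and the Gelman-Rubin statistic of each of
#' `lambda_b`, `lambda_c`, `p_o`, `p_s` must fall below the threshold.
#' Distances are estimated on a random subsample of pairs.
#'
#' @param chain_a,chain_b chain records as returned in
#'   `run_sampler()$chains`: lists with `partitions` and `theta_trace`.
#' @param obs an `spt_observations` object.
#' @param psrf_threshold Gelman-Rubin acceptance threshold.
#' @param max_pairs pair budget of each distance estimate.
#' @return An `spt_convergence` report with `cross_ged_mean`,
#'   `inner_ged_means`, `psrf` and `converged`.
#' @export
check_convergence <- function(chain_a, chain_b, obs, psrf_threshold = 1.1,
                              max_pairs = 200) {
  n <- nrow(obs)
  ka <- lapply(chain_a$partitions, function(p) .part_link_keys(p$tracks, n))
  kb <- lapply(chain_b$partitions, function(p) .part_link_keys(p$tracks, n))
  .convergence_from(ka, kb, chain_a$theta_trace, chain_b$theta_trace,
                    psrf_threshold, max_pairs)
}

#' @export
print.spt_convergence <- function(x, ...) {
  cat(sprintf(
    "<spt_convergence> cross GED %.2f vs inner %.2f + %.2f; PSRF max %.3f; %s\n",
    x$cross_ged_mean, x$inner_ged_means[1], x$inner_ged_means[2],
    max(x$psrf), if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

.theta_row <- function(theta) {
  c(lambda_b = theta$lambda_b, lambda_c = theta$lambda_c,
    p_o = theta$p_o, p_s = theta$p_s,
    R_xx = theta$R[1, 1], R_xy = theta$R[1, 2], R_yy = theta$R[2, 2])
}

#' Run the dual-chain Gibbs sampler
#'
#' The full tracker: two chains are initialised far apart (the minimum
#' partition with every observation in the clutter, and a randomised
#' greedy maximum partition), and each alternates sweeps of
#' Metropolis-Hastings partition steps with one conjugate draw of the
#' parameters per sweep. Burn-in continues until the cross/inner
#' graph-edit-distance criterion and the Gelman-Rubin statistics both pass
#' (or the sweep budget is exhausted, in which case the report is flagged);
#' afterwards each chain records `n_record` thinned partition samples plus
#' its parameter trace.
#'
#' @param obs an `spt_observations` object.
#' @param cfg a [sampler_config()].
#' @param seed integer seed; every source of randomness in the run flows
#'   from it.
#' @param verbose print sweep-level progress.
#' @return An object of class `spt_chains`: list with `chains` (two chain
#'   records, each with `partitions`, `theta_trace`, `move_stats`,
#'   `thin_n`, `acceptance_rate`), `convergence`, `burnin_sweeps`, `cfg`
#'   and `seed`.
#' @export
run_sampler <- function(obs, cfg = sampler_config(), seed = NULL,
                        verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(obs)
  steps <- if (is.null(cfg$steps_per_sweep)) max(N, 100L)
           else cfg$steps_per_sweep

  new_chain <- function(part) {
    list(part = part, theta = parameters(),
         move_stats = matrix(0, 9L, 3L,
                             dimnames = list(.move_names,
                                             c("rejected", "identity",
                                               "accepted"))),
         keys = list(), thetas = NULL)
  }
  chains <- list(
    new_chain(minimum_partition(obs)),
    new_chain(greedy_maximum_partition(obs, cfg$max_speed, cfg$greedy_gate)))

  theta_cols <- c("lambda_b", "lambda_c", "p_o", "p_s",
                  "R_xx", "R_xy", "R_yy")
  gibbs <- function(ch, n_sweeps, record_every = 0L, record_offset = 0L,
                    record_max = 0L) {
    res <- .bgl_gibbs(obs$t, obs$x, obs$y, n_frames(obs), fov(obs),
                      area_unit(obs), lapply(ch$part$tracks, as.integer),
                      as.integer(ch$part$clutter), .theta_list(ch$theta),
                      .model_list(cfg), .cfg_list(cfg),
                      as.integer(n_sweeps), as.integer(steps),
                      cfg$phi_scale, cfg$wishart_dof,
                      as.integer(record_every), as.integer(record_offset),
                      as.integer(record_max), as.integer(cfg$check_window))
    ch$part <- partition(res$tracks, res$clutter)
    th <- res$theta
    ch$theta <- parameters(th$lambda_b, th$lambda_c, th$p_o, th$p_s, th$R)
    ch$move_stats <- ch$move_stats + res$move_stats
    tt <- res$theta_trace[seq_len(res$sweeps_done), , drop = FALSE]
    colnames(tt) <- theta_cols
    ch$keys <- res$snapshots
    ch$thetas <- utils::tail(rbind(ch$thetas, tt), cfg$check_window)
    ch$chunk_trace <- tt
    ch$chunk_records <- res$records
    ch$chunk_offset <- res$record_offset
    ch
  }

  # ---- burn-in ----
  report <- NULL
  sweep_count <- 0L
  repeat {
    chunk <- min(cfg$check_every, cfg$max_sweeps - sweep_count)
    chains[[1L]] <- gibbs(chains[[1L]], chunk)
    chains[[2L]] <- gibbs(chains[[2L]], chunk)
    sweep_count <- sweep_count + chunk
    if (sweep_count >= cfg$min_sweeps) {
      report <- .convergence_from(chains[[1L]]$keys, chains[[2L]]$keys,
                                  chains[[1L]]$thetas, chains[[2L]]$thetas,
                                  cfg$psrf_threshold, cfg$ged_pairs)
      if (verbose)
        cat(sprintf("sweep %d: cross GED %.2f, inner %.2f/%.2f, PSRF %.3f\n",
                    sweep_count, report$cross_ged_mean,
                    report$inner_ged_means[1], report$inner_ged_means[2],
                    max(report$psrf)))
      if (isTRUE(report$converged)) break
    }
    if (sweep_count >= cfg$max_sweeps) break
  }
  converged <- !is.null(report) && isTRUE(report$converged)

  # ---- recording ----
  records <- list(list(), list())
  thetas_rec <- list(NULL, NULL)
  thin_n <- integer(2L)
  offsets <- c(0L, 0L)
  for (c_i in 1:2) {
    ms <- chains[[c_i]]$move_stats
    rate <- sum(ms[, "accepted"]) / max(1, sum(ms))
    thin_n[c_i] <- thinning_interval(rate, cfg$thin_coef)
  }
  while (length(records[[1L]]) < cfg$n_record ||
         length(records[[2L]]) < cfg$n_record) {
    for (c_i in 1:2) {
      want <- cfg$n_record - length(records[[c_i]])
      if (want <= 0L) next
      n_sw <- max(2L, ceiling((want * thin_n[c_i]) / steps) + 1L)
      chains[[c_i]] <- gibbs(chains[[c_i]], n_sw,
                             record_every = thin_n[c_i],
                             record_offset = offsets[c_i],
                             record_max = want)
      offsets[c_i] <- chains[[c_i]]$chunk_offset
      thetas_rec[[c_i]] <- rbind(thetas_rec[[c_i]],
                                 chains[[c_i]]$chunk_trace)
      records[[c_i]] <- c(records[[c_i]],
                          lapply(chains[[c_i]]$chunk_records, function(tr) {
        partition(tr, setdiff(obs$id, unlist(tr, use.names = FALSE)))
      }))
    }
  }

  out_chain <- function(c_i) {
    ms <- chains[[c_i]]$move_stats
    list(partitions = records[[c_i]],
         theta_trace = as.data.frame(thetas_rec[[c_i]]),
         move_stats = ms,
         thin_n = thin_n[c_i],
         acceptance_rate = sum(ms[, "accepted"]) / max(1, sum(ms)))
  }
  out <- list(chains = list(out_chain(1L), out_chain(2L)),
              convergence = report, converged = converged,
              burnin_sweeps = sweep_count, steps_per_sweep = steps,
              cfg = cfg, seed = seed)
  class(out) <- "spt_chains"
  out
}

#' @export
print.spt_chains <- function(x, ...) {
  cat(sprintf(
    "<spt_chains> 2 chains, %d recorded samples each; burn-in %d sweeps x %d steps; %s\n",
    length(x$chains[[1]]$partitions), x$burnin_sweeps, x$steps_per_sweep,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Pooled recorded partitions of both chains
#' @param run an `spt_chains` object.
#' @export
pooled_samples <- function(run) {
  c(run$chains[[1L]]$partitions, run$chains[[2L]]$partitions)
}
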