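# Shared fixtures: toy observation sets, an exhaustive partition enumerator
# and a joint-Gaussian oracle for the track likelihood.

# Two parallel diffusive tracks over 4 frames plus two clutter points.
toy_two_tracks <- function() {
  obs <- observation_set(
    t = c(0, 0, 1, 1, 2, 2, 3, 3, 1, 2),
    x = c(1, 6, 1.2, 6.2, 1.4, 6.4, 1.6, 6.6, 3.5, 3.8),
    y = c(1, 1, 1.1, 1.2, 1.3, 1.1, 1.2, 1.0, 2.0, 2.2),
    fov = c(10, 10))
  list(obs = obs,
       part = partition(list(c(1, 3, 5, 7), c(2, 4, 6, 8)), c(9, 10)))
}

# Small bipartite toy: 2 observations at t=0, 3 at t=1; 13 valid partitions.
toy_bipartite <- function() {
  observation_set(t = c(0, 0, 1, 1, 1),
                  x = c(0, 4, 0.3, 4.3, 2),
                  y = c(0, 0, 0.6, 0.5, 0.3), fov = c(8, 8))
}

toy_theta <- function() {
  parameters(lambda_b = 1, lambda_c = 1, p_o = 0.8, p_s = 0.8, R = 0.3)
}

# All gate-valid links in the same order as the compiled kernel's candidate
# index (ascending source id, then ascending frame gap, then id).
candidate_links <- function(obs, cfg) {
  out <- list()
  for (a in obs$id) {
    for (dt in seq_len(cfg$gate_frames)) {
      bs <- obs$id[obs$t == obs$t[a] + dt]
      for (b in bs) {
        if ((obs$x[a] - obs$x[b])^2 + (obs$y[a] - obs$y[b])^2 <=
            (cfg$max_speed * dt)^2)
          out[[length(out) + 1L]] <- c(a, b)
      }
    }
  }
  out
}

# Exhaustively enumerate every valid partition of a toy observation set as
# subsets of candidate links with in/out degree <= 1. Returns partitions and
# the link-set bitmask matching the kernel's mask recording.
enumerate_all_partitions <- function(obs, cfg) {
  links <- candidate_links(obs, cfg)
  L <- length(links)
  stopifnot(L <= 20)
  out <- list()
  for (m in 0:(2^L - 1)) {
    sel <- which(bitwAnd(m, 2^(seq_len(L) - 1L)) > 0)
    ls <- links[sel]
    va <- vapply(ls, `[`, 0, 1L)
    vb <- vapply(ls, `[`, 0, 2L)
    if (anyDuplicated(va) || anyDuplicated(vb)) next
    tracks <- list()
    for (s in setdiff(va, vb)) {
      tr <- s
      while (tr[length(tr)] %in% va)
        tr <- c(tr, vb[match(tr[length(tr)], va)])
      tracks[[length(tracks) + 1L]] <- as.integer(tr)
    }
    out[[length(out) + 1L]] <- list(
      mask = m,
      part = partition(tracks, setdiff(obs$id, unlist(tracks))))
  }
  out
}

# Joint-Gaussian oracle: evaluate the track likelihood by composing the full
# joint normal distribution of the observed positions (no filtering).
joint_gaussian_loglik <- function(track_ids, obs, model) {
  idx <- match(track_ids, obs$id)
  tt <- obs$t[idx]
  m <- length(idx)
  Fm <- model$F_mat
  Q <- model$Q_proc
  B <- model$B
  R <- model$R
  # state marginal covariances and means at observation times
  d <- diff(c(tt[1], tt))
  P <- vector("list", m)
  mu <- vector("list", m)
  P[[1]] <- model$prior_cov
  mu[[1]] <- c(obs$x[idx[1]], 0, obs$y[idx[1]], 0)
  for (k in 2:m) {
    Pk <- P[[k - 1]]
    mk <- mu[[k - 1]]
    for (s in seq_len(d[k])) {
      mk <- Fm %*% mk
      Pk <- Fm %*% Pk %*% t(Fm) + Q
    }
    P[[k]] <- Pk
    mu[[k]] <- mk
  }
  # cross covariances Cov(X_j, X_k) = P_j (F^{t_k - t_j})'
  Fpow <- function(n) {
    M <- diag(4)
    for (s in seq_len(n)) M <- Fm %*% M
    M
  }
  S <- matrix(0, 2 * m, 2 * m)
  mvec <- numeric(2 * m)
  yvec <- numeric(2 * m)
  for (j in seq_len(m)) {
    mvec[(2 * j - 1):(2 * j)] <- as.numeric(B %*% mu[[j]])
    yvec[(2 * j - 1):(2 * j)] <- c(obs$x[idx[j]], obs$y[idx[j]])
    for (k in j:m) {
      Cjk <- P[[j]] %*% t(Fpow(tt[k] - tt[j]))
      blk <- B %*% Cjk %*% t(B)
      if (j == k) blk <- blk + R
      S[(2 * j - 1):(2 * j), (2 * k - 1):(2 * k)] <- blk
      S[(2 * k - 1):(2 * k), (2 * j - 1):(2 * j)] <- t(blk)
    }
  }
  r <- yvec - mvec
  -m * log(2 * pi) - 0.5 * determinant(S)$modulus[1] -
    0.5 * as.numeric(t(r) %*% solve(S) %*% r)
}

# A realistic mid-density realisation for move-footprint and sampler tests.
sim_realisation <- function(seed, lambda_b = 0.8, fov = c(40, 40),
                            n_frames = 40, p_o = 0.9, loc_error = 0.1,
                            lambda_c = 0.4, D = 0.08) {
  set.seed(seed)
  gt <- simulate_ground_truth(lambda_b, 0.95,
                              list(mode = "random_walk", D = D),
                              fov, n_frames)
  realise(gt, p_o, loc_error, lambda_c)
}

# Evolve a partition with some sampler steps to get a "random valid
# partition" that is neither minimal nor maximal.
warmed_partition <- function(obs, n_steps = 2000,
                             theta = parameters(0.5, 0.5, 0.9, 0.95, 0.02),
                             cfg = sampler_config()) {
  res <- sptmcmc:::.run_core(minimum_partition(obs), obs, theta, cfg,
                             n_steps)
  partition(res$tracks, res$clutter)
}
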