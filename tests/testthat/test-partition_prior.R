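test_that("partition statistics count births, darkness and survival", {
  obs <- observation_set(t = c(0, 1, 3, 4, 2), x = c(1, 1.2, 1.6, 1.8, 7),
                         y = rep(1, 5), n_frames = 5, fov = c(10, 10))
  st <- partition_stats(partition(list(c(1L, 2L, 3L, 4L)), 5L), obs)
  expect_identical(st$n_observed, 4L)
  expect_identical(st$n_dark, 1L)        # frame 2 inside the lifetime
  expect_identical(st$n_survive, 4L)
  expect_identical(st$n_die, 0L)         # alive at the final frame
  expect_identical(st$n_births, c(1L, 0L, 0L, 0L, 0L))
  expect_identical(sum(st$n_clutter), 1L)

  st0 <- partition_stats(minimum_partition(obs), obs)
  expect_identical(sum(st0$n_births), 0L)
  expect_identical(sum(st0$n_clutter), 5L)
  expect_identical(st0$n_observed, 0L)
})

test_that("statistics agree with an independent per-frame tally", {
  real <- sim_realisation(51, lambda_b = 0.8, fov = c(30, 30), n_frames = 20)
  obs <- real$obs
  for (p in list(true_partition(real), warmed_partition(obs, 500L))) {
    st <- partition_stats(p, obs)
    # independent tally: walk frames, track live intervals explicitly
    births <- integer(n_frames(obs))
    n_obs <- 0L; n_dark <- 0L; n_surv <- 0L; n_die <- 0L
    for (tr in p$tracks) {
      tt <- sort(obs$t[match(tr, obs$id)])
      births[tt[1] + 1L] <- births[tt[1] + 1L] + 1L
      for (f in tt[1]:tt[length(tt)]) {
        if (f %in% tt) n_obs <- n_obs + 1L else n_dark <- n_dark + 1L
        if (f > tt[1]) n_surv <- n_surv + 1L
      }
      if (tt[length(tt)] < n_frames(obs) - 1L) n_die <- n_die + 1L
    }
    expect_identical(st$n_births, births)
    expect_identical(as.integer(st$n_observed), n_obs)
    expect_identical(as.integer(st$n_dark), n_dark)
    expect_identical(as.integer(st$n_survive), n_surv)
    expect_identical(as.integer(st$n_die), n_die)
    expect_identical(st$n_observed + sum(st$n_clutter), nrow(obs))
  }
})

test_that("partition prior closed forms and monotonicity", {
  obs <- observation_set(integer(), numeric(), numeric(), n_frames = 1L,
                         fov = c(100, 100))
  th <- parameters(lambda_b = 1, lambda_c = 1, p_o = 0.9, p_s = 0.9)
  st <- partition_stats(minimum_partition(obs), obs)
  # two Poisson(0 | 1) terms: log prior = -2
  expect_equal(log_partition_prior(st, th, obs), -2)
  # extra dark frames are penalised when p_o > 1/2
  st_dark <- st
  st_dark$n_observed <- 10L
  st_darker <- st_dark
  st_darker$n_dark <- 3L
  expect_lt(log_partition_prior(st_darker, th, obs),
            log_partition_prior(st_dark, th, obs))
  bad <- parameters(1, 1, 0.9, 0.9)
  bad$p_o <- 1.2
  expect_error(log_partition_prior(st, bad, obs), "inside")
})

test_that("clutter likelihood is uniform over the field of view", {
  obs <- observation_set(t = rep(0L, 10), x = runif(10, 0, 99),
                         y = runif(10, 0, 99), fov = c(100, 100))
  p <- minimum_partition(obs)
  expect_equal(log_clutter_likelihood(p, obs), 10 * log(1e-4))
  expect_equal(log_clutter_likelihood(partition(list(), integer()), obs), 0)
  obs2 <- observation_set(obs$t, obs$x, obs$y, fov = c(200, 100))
  expect_equal(log_clutter_likelihood(p, obs) -
                 log_clutter_likelihood(p, obs2), 10 * log(2))
})

test_that("posterior ratios factorise over tracks", {
  toy <- toy_two_tracks()
  th <- toy_theta()
  model <- state_space_model()
  # two partitions that differ only in the second track
  pa <- toy$part
  pb <- partition(list(c(1L, 3L, 5L, 7L), c(2L, 4L, 6L)), c(8L, 9L, 10L))
  d_full <- log_posterior(pa, th, toy$obs, model, prior = NULL) -
    log_posterior(pb, th, toy$obs, model, prior = NULL)
  model_r <- model
  model_r$R <- th$R
  d_track <- (track_log_likelihood(c(2L, 4L, 6L, 8L), toy$obs, model_r) -
              track_log_likelihood(c(2L, 4L, 6L), toy$obs, model_r))
  sa <- partition_stats(pa, toy$obs)
  sb <- partition_stats(pb, toy$obs)
  d_prior <- log_partition_prior(sa, th, toy$obs) -
    log_partition_prior(sb, th, toy$obs) +
    log_clutter_likelihood(pa, toy$obs) -
    log_clutter_likelihood(pb, toy$obs)
  expect_equal(d_full, d_track + d_prior, tolerance = 1e-10)
})

test_that("compiled and R posterior agree over random partitions", {
  real <- sim_realisation(61, lambda_b = 0.6, fov = c(30, 30), n_frames = 20)
  obs <- real$obs
  cfg <- sampler_config()
  th <- parameters(0.4, 0.4, 0.85, 0.9, 0.02)
  model <- sptmcmc:::.model_from_cfg(cfg)
  for (p in list(minimum_partition(obs), true_partition(real),
                 warmed_partition(obs, 800L))) {
    res <- sptmcmc:::.run_core(p, obs, th, cfg, 0L)
    expect_equal(res$log_posterior_omega,
                 log_posterior(p, th, obs, model, prior = NULL),
                 tolerance = 1e-9)
  }
})

test_that("exhaustive posterior over a toy is a proper positive measure", {
  obs <- toy_bipartite()
  cfg <- sampler_config(gate_frames = 2)
  all_p <- enumerate_all_partitions(obs, cfg)
  expect_identical(length(all_p), 13L)
  lp <- vapply(all_p, function(e)
    log_posterior(e$part, toy_theta(), obs, state_space_model(),
                  prior = NULL), numeric(1))
  expect_true(all(is.finite(lp)))
  expect_gt(sum(exp(lp - max(lp))), 1)
})
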