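test_that("filter handles gaps and scores every observation", {
  obs <- observation_set(t = c(0, 1, 3), x = c(1, 1.2, 1.5),
                         y = c(2, 2.1, 2.4), fov = c(10, 10))
  inf <- kalman_filter(c(1L, 2L, 3L), obs, state_space_model())
  expect_identical(length(inf$times), 4L)   # frame 2 is a dark frame
  expect_identical(nrow(inf$innovations), 3L)
  expect_true(is.finite(inf$log_likelihood))
  expect_error(kalman_filter(1L, obs, state_space_model()), "at least 2")
})

test_that("likelihood is symmetric in x and y and translation invariant", {
  model <- state_space_model()
  obs <- observation_set(t = c(0, 1, 2), x = c(3, 3.4, 3.1),
                         y = c(5, 5.2, 4.9), fov = c(20, 20))
  obs_swap <- observation_set(t = obs$t, x = obs$y, y = obs$x,
                              fov = c(20, 20))
  obs_shift <- observation_set(t = obs$t, x = obs$x + 7, y = obs$y + 3,
                               fov = c(20, 20))
  ll <- track_log_likelihood(1:3, obs, model)
  expect_equal(track_log_likelihood(1:3, obs_swap, model), ll)
  expect_equal(track_log_likelihood(1:3, obs_shift, model), ll)
})

test_that("filter likelihood equals the joint-Gaussian oracle", {
  model <- state_space_model(q_pos = 0.7, q_vel = 0.15, R = 0.04)
  set.seed(31)
  for (rep in 1:8) {
    m <- sample(3:5, 1L)
    tt <- cumsum(c(0, sample(1:3, m - 1L, replace = TRUE)))
    obs <- observation_set(t = tt, x = 5 + cumsum(rnorm(m, sd = 0.6)),
                           y = 5 + cumsum(rnorm(m, sd = 0.6)),
                           fov = c(30, 30))
    ll <- track_log_likelihood(obs$id, obs, model)
    oracle <- joint_gaussian_loglik(obs$id, obs, model)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("compiled kernel and R filter agree on the track likelihood", {
  real <- sim_realisation(41, lambda_b = 0.6, fov = c(30, 30), n_frames = 25)
  obs <- real$obs
  tp <- true_partition(real)
  skip_if(n_tracks(tp) == 0)
  cfg <- sampler_config()
  theta <- parameters(0.5, 0.5, 0.9, 0.95, R = 0.01)
  res <- sptmcmc:::.run_core(tp, obs, theta, cfg, 0L)
  model <- sptmcmc:::.model_from_cfg(cfg)
  model$R <- theta$R
  ll_r <- sum(vapply(tp$tracks, track_log_likelihood, numeric(1),
                     obs = obs, model = model))
  expect_equal(sum(res$track_logliks), ll_r, tolerance = 1e-10)
})

test_that("RTS boundary, Loewner ordering and Brownian-bridge gap", {
  model <- state_space_model()
  obs <- observation_set(t = c(0, 1, 3, 4), x = c(1, 1.4, 2.3, 2.6),
                         y = c(1, 1.1, 1.6, 1.9), fov = c(10, 10))
  inf <- rts_smooth(kalman_filter(obs$id, obs, model))
  n <- length(inf$times)
  expect_equal(inf$smooth_mean[[n]], inf$filt_mean[[n]])
  expect_equal(inf$smooth_cov[[n]], inf$filt_cov[[n]])
  for (i in seq_len(n)) {
    ev <- eigen(inf$filt_cov[[i]] - inf$smooth_cov[[i]],
                symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  # pure random walk (no velocity): smoothed gap position lies between
  # its neighbours' smoothed positions
  rw <- state_space_model(q_pos = 0.5, q_vel = 0, prior_sigmav = 1e-6)
  infr <- rts_smooth(kalman_filter(obs$id, obs, rw))
  gap <- which(!infr$observed)
  for (g in gap) {
    xs <- vapply(infr$smooth_mean, `[`, 0, 1L)
    expect_true(xs[g] >= min(xs[g - 1], xs[g + 1]) - 1e-9)
    expect_true(xs[g] <= max(xs[g - 1], xs[g + 1]) + 1e-9)
  }
})

test_that("zero process noise recovers the least-squares line", {
  set.seed(5)
  tt <- 0:19
  xx <- 2 + 0.5 * tt + rnorm(20, sd = 0.2)
  yy <- 3 + 0.2 * tt + rnorm(20, sd = 0.2)
  obs <- observation_set(tt, xx, yy, fov = c(40, 40))
  model <- state_space_model(q_pos = 1e-10, q_vel = 1e-10, R = 0.04,
                             prior_sigma0 = 100, prior_sigmav = 10)
  inf <- rts_smooth(kalman_filter(obs$id, obs, model))
  sx <- vapply(inf$smooth_mean, `[`, 0, 1L)
  fit <- unname(predict(lm(xx ~ tt)))
  expect_equal(sx, fit, tolerance = 1e-2)
})

test_that("reassigning one observation changes all innovations", {
  model <- state_space_model(R = 0.04)
  obs <- observation_set(t = 0:3, x = c(1, 1.3, 1.6, 1.9),
                         y = c(1, 1.1, 1.2, 1.3), fov = c(20, 20))
  obs_far <- observation_set(t = 0:3, x = c(1, 1.3, 9.0, 1.9),
                             y = c(1, 1.1, 9.0, 1.3), fov = c(20, 20))
  inn_near <- kalman_filter(obs$id, obs, model)$innovations
  inn_far <- kalman_filter(obs_far$id, obs_far, model)$innovations
  # likelihood drops overall
  expect_lt(sum(inn_far$loglik), sum(inn_near$loglik))
  # the term of the *last* (unchanged) observation changes too
  expect_false(isTRUE(all.equal(inn_near$loglik[4], inn_far$loglik[4])))
})

test_that("covariances stay symmetric PSD over long recursions", {
  set.seed(6)
  n <- 400L
  obs <- observation_set(0:(n - 1), 50 + cumsum(rnorm(n, sd = 0.5)),
                         50 + cumsum(rnorm(n, sd = 0.5)), fov = c(200, 200))
  inf <- kalman_filter(obs$id, obs, state_space_model())
  for (i in seq(1L, n, by = 40L)) {
    P <- inf$filt_cov[[i]]
    expect_equal(P, t(P))
    expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})
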