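test_that("thinning interval is anchored at 25% -> 8", {
  expect_identical(thinning_interval(0.25), 8L)
  expect_identical(thinning_interval(0), 1L)
  expect_identical(thinning_interval(0.5), 4L)
  expect_identical(thinning_interval(0.01), 200L)
})

test_that("mh_step bookkeeps identity and preserves the partition", {
  obs <- observation_set(t = c(0, 5), x = c(1, 1), y = c(1, 1),
                         n_frames = 6, fov = c(5, 5))
  cfg <- sampler_config(gate_frames = 2)
  set.seed(1)
  st <- mh_step(minimum_partition(obs), toy_theta(), obs, cfg)
  expect_identical(st$outcome, "identity")
  expect_identical(ged(st$partition, minimum_partition(obs), obs), 0L)
})

test_that("short chains match the enumerated posterior on a toy", {
  obs <- toy_bipartite()
  cfg <- sampler_config(gate_frames = 2)
  theta <- toy_theta()
  all_p <- enumerate_all_partitions(obs, cfg)
  lp <- vapply(all_p, function(e)
    log_posterior(e$part, theta, obs, state_space_model(), prior = NULL),
    numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  set.seed(11)
  res <- sptmcmc:::.run_core(minimum_partition(obs), obs, theta, cfg,
                             2e5, record_mode = 2L)
  thin <- res$masks[seq(53, length(res$masks), by = 53)]
  cnt <- table(factor(thin, levels = vapply(all_p, function(e) e$mask,
                                            numeric(1))))
  ct <- suppressWarnings(chisq.test(as.integer(cnt), p = pr))
  expect_gt(ct$p.value, 0.001)
})

test_that("runs are bit-reproducible from the seed", {
  real <- sim_realisation(101, lambda_b = 0.6, fov = c(25, 25),
                          n_frames = 20)
  cfg <- sampler_config(n_record = 40, min_sweeps = 20, check_every = 20,
                        max_sweeps = 60)
  r1 <- run_sampler(real$obs, cfg, seed = 5)
  r2 <- run_sampler(real$obs, cfg, seed = 5)
  expect_identical(r1$chains[[1]]$theta_trace, r2$chains[[1]]$theta_trace)
  l1 <- link_probabilities(pooled_samples(r1), real$obs)
  l2 <- link_probabilities(pooled_samples(r2), real$obs)
  expect_identical(l1$p_hat, l2$p_hat)
  expect_identical(r1$chains[[2]]$move_stats, r2$chains[[2]]$move_stats)
})

test_that("move bookkeeping is consistent and identities count as rejected", {
  real <- sim_realisation(111, lambda_b = 0.6, fov = c(25, 25),
                          n_frames = 20)
  cfg <- sampler_config(n_record = 20, min_sweeps = 10, check_every = 10,
                        max_sweeps = 30)
  run <- run_sampler(real$obs, cfg, seed = 6)
  for (ch in run$chains) {
    ms <- ch$move_stats
    expect_true(all(rowSums(ms) >= 0))
    expect_equal(ch$acceptance_rate, sum(ms[, "accepted"]) / sum(ms))
    expect_identical(ch$thin_n,
                     thinning_interval(ch$acceptance_rate))
    expect_identical(length(ch$partitions), 20L)
  }
})

test_that("an empty observation set yields minimum partitions and priors", {
  obs <- observation_set(integer(), numeric(), numeric(), n_frames = 0L,
                         fov = c(10, 10))
  cfg <- sampler_config(n_record = 5, min_sweeps = 2, check_every = 2,
                        max_sweeps = 4)
  run <- run_sampler(obs, cfg, seed = 3)
  for (ch in run$chains) {
    expect_true(all(vapply(ch$partitions, n_tracks, integer(1)) == 0L))
    expect_true(all(ch$theta_trace$p_o > 0 & ch$theta_trace$p_o < 1))
  }
})

test_that("convergence criterion accepts agreeing and rejects stuck chains", {
  real <- sim_realisation(121, lambda_b = 2.5, fov = c(30, 30),
                          n_frames = 20)
  obs <- real$obs
  set.seed(7)
  th <- as.data.frame(matrix(rnorm(4 * 30, mean = 1, sd = 0.1), 30, 4,
                             dimnames = list(NULL, c("lambda_b", "lambda_c",
                                                     "p_o", "p_s"))))
  parts <- lapply(1:30, function(i) warmed_partition(obs, 50L))
  chain <- list(partitions = parts, theta_trace = th)
  rep_same <- check_convergence(chain, chain, obs)
  expect_true(rep_same$converged)
  expect_equal(rep_same$cross_ged_mean, rep_same$inner_ged_means[1],
               tolerance = 0.5)
  # two chains frozen at different partitions: cross = g, inner = 0
  pa <- true_partition(real)
  pb <- minimum_partition(obs)
  g <- ged(pa, pb, obs)
  skip_if(g == 0)
  ch_a <- list(partitions = rep(list(pa), 30), theta_trace = th)
  ch_b <- list(partitions = rep(list(pb), 30), theta_trace = th)
  rep_stuck <- check_convergence(ch_a, ch_b, obs)
  expect_false(rep_stuck$converged)
  expect_equal(rep_stuck$cross_ged_mean, g)
  expect_equal(rep_stuck$inner_ged_means, c(0, 0))
})
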