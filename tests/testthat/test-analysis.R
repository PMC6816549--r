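test_that("msd handles degenerate and deterministic tracks", {
  obs_still <- observation_set(t = 0:4, x = rep(2, 5), y = rep(3, 5),
                               fov = c(5, 5))
  m0 <- msd(partition(list(1:5), integer()), obs_still, max_lag = 3)
  expect_true(all(m0$msd == 0))
  # unit-velocity track: msd(tau) = tau^2
  obs_line <- observation_set(t = 0:9, x = 0:9 + 0.0, y = rep(0, 10),
                              fov = c(11, 2))
  ml <- msd(partition(list(1:10), integer()), obs_line, max_lag = 4)
  expect_equal(ml$msd, ml$tau^2)
  expect_equal(ml$n_pairs, c(9L, 8L, 7L, 6L))
})

test_that("msd slope recovers 4D for simulated random walks", {
  set.seed(1)
  D <- 0.08
  gt <- simulate_ground_truth(2, 0.98, list(mode = "random_walk", D = D),
                              c(100, 100), 80)
  real <- realise(gt, p_o = 1, loc_error = 0, lambda_c = 0)
  curve <- msd(true_partition(real), real$obs, max_lag = 4)
  expect_equal(diffusion_coefficient(curve), D, tolerance = 0.15 * D)
})

test_that("diffusion coefficient is the slope over four", {
  curve <- data.frame(tau = c(1, 2), msd = c(0.32, 0.64), n_pairs = c(5, 5))
  expect_equal(diffusion_coefficient(curve, 1:2), 0.08)
  flat <- data.frame(tau = 1:4, msd = rep(0, 4), n_pairs = rep(3, 4))
  expect_equal(diffusion_coefficient(flat), 0)
  expect_error(diffusion_coefficient(curve[1, ], 1:2), "lags")
})

test_that("localisation noise inflates the intercept, not the slope", {
  set.seed(2)
  D <- 0.08
  sigma <- 0.3
  gt <- simulate_ground_truth(3, 0.99, list(mode = "random_walk", D = D),
                              c(100, 100), 80)
  real_clean <- realise(gt, p_o = 1, loc_error = 0, lambda_c = 0)
  set.seed(3)
  real_noisy <- realise(gt, p_o = 1, loc_error = sigma, lambda_c = 0)
  c_clean <- msd(true_partition(real_clean), real_clean$obs, max_lag = 4)
  c_noisy <- msd(true_partition(real_noisy), real_noisy$obs, max_lag = 4)
  fit_n <- lm(msd ~ tau, data = c_noisy, weights = c_noisy$n_pairs)
  expect_equal(diffusion_coefficient(c_noisy),
               diffusion_coefficient(c_clean), tolerance = 0.25 * D)
  # intercept approximately 4 sigma^2
  expect_equal(unname(coef(fit_n)[1]), 4 * sigma^2,
               tolerance = 0.3 * 4 * sigma^2)
})

test_that("smallest interval matches an exhaustive window scan", {
  expect_equal(smallest_interval_ci(1:10, 0.5), c(1, 5))
  expect_equal(smallest_interval_ci(c(4, 9, 1, 7), 1), c(1, 9))
  brute <- function(v, level) {
    v <- sort(v)
    n <- length(v)
    m <- ceiling(level * n)
    best <- c(Inf, NA, NA)
    for (s in seq_len(n - m + 1)) {
      w <- v[s + m - 1] - v[s]
      if (w < best[1]) best <- c(w, v[s], v[s + m - 1])
    }
    best[2:3]
  }
  set.seed(4)
  for (k in 1:20) {
    v <- rnorm(sample(10:60, 1))
    lv <- runif(1, 0.3, 0.99)
    expect_equal(smallest_interval_ci(v, lv), brute(v, lv))
  }
  # unimodal: smallest interval is no wider than the equal-tailed one
  v <- rnorm(2000)
  si <- smallest_interval_ci(v, 0.9)
  et <- quantile(v, c(0.05, 0.95))
  expect_lte(diff(si), diff(unname(et)) + 1e-12)
})

test_that("coverage counts hits and is calibrated on Gaussians", {
  ex_hit <- list(list(D_samples = rep(0.08, 50), D_gtr = 0.08))
  expect_equal(ci_coverage(ex_hit, 0.9), 1)
  ex_miss <- list(list(D_samples = rnorm(50, 10), D_gtr = 0))
  expect_equal(ci_coverage(ex_miss, 0.9), 0)
  set.seed(5)
  exps <- lapply(1:400, function(i) {
    mu <- rnorm(1)
    list(D_samples = rnorm(400, mean = mu), D_gtr = rnorm(1, mean = mu))
  })
  cov <- ci_coverage(exps, 0.8)
  expect_lt(abs(cov - 0.8), 3 * sqrt(0.8 * 0.2 / 400) + 0.02)
})
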