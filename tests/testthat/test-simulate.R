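test_that("birth counts follow the area-scaled Poisson rate", {
  set.seed(1)
  lb <- 0.5
  Tn <- 20L
  mu <- lb * Tn          # fov 100x100 equals the unit area
  n <- replicate(200, length(simulate_ground_truth(
    lb, 0.9, list(mode = "random_walk", D = 0.05), c(100, 100), Tn)$tracks))
  expect_lt(abs(mean(n) - mu), 3 * sqrt(mu / 200))
})

test_that("zero survival gives single-frame tracks", {
  set.seed(2)
  gt <- simulate_ground_truth(1, 0, list(mode = "random_walk", D = 0.05),
                              c(100, 100), 10)
  expect_true(all(vapply(gt$tracks, nrow, integer(1)) == 1L))
})

test_that("random-walk steps have per-axis variance 2D", {
  set.seed(3)
  D <- 0.25
  gt <- simulate_ground_truth(2, 0.99, list(mode = "random_walk", D = D),
                              c(100, 100), 50)
  dx <- unlist(lapply(gt$tracks, function(tr) diff(tr$x)))
  skip_if(length(dx) < 500)
  expect_equal(var(dx), 2 * D, tolerance = 0.15 * 2 * D)
})

test_that("directed tracks move at constant speed", {
  set.seed(4)
  gt <- simulate_ground_truth(
    1, 0.99, list(mode = "directed", speed = 1.5, turn_sd = 0.1),
    c(100, 100), 30)
  steps <- unlist(lapply(gt$tracks, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  }))
  skip_if(is.null(steps) || length(steps) < 10)
  expect_equal(unname(range(steps)), c(1.5, 1.5), tolerance = 1e-9)
})

test_that("a noiseless full realisation reproduces the states exactly", {
  set.seed(5)
  gt <- simulate_ground_truth(0.5, 0.95, list(mode = "random_walk", D = 0.05),
                              c(50, 50), 20)
  real <- realise(gt, p_o = 1, loc_error = 0, lambda_c = 0)
  expect_identical(sum(is.na(real$labels)), 0L)
  st <- do.call(rbind, gt$tracks)
  inside <- st$x >= 0 & st$x < 50 & st$y >= 0 & st$y < 50
  expect_identical(nrow(real$obs), sum(inside))
  expect_setequal(round(real$obs$x, 9), round(st$x[inside], 9))
})

test_that("realisation conserves observations and rates", {
  set.seed(6)
  gt <- simulate_ground_truth(0.5, 0.95, list(mode = "random_walk", D = 0.05),
                              c(100, 100), 100)
  real <- realise(gt, p_o = 0.9, loc_error = 0.1, lambda_c = 0.4)
  expect_identical(sum(is.na(real$labels)) + sum(!is.na(real$labels)),
                   nrow(real$obs))
  # clutter count ~ Poisson(0.4 * 100)
  ncl <- sum(is.na(real$labels))
  expect_lt(abs(ncl - 40), 4 * sqrt(40))
  # true links connect observations of the same track in time order
  tl <- real$true_links
  expect_true(all(real$obs$t[match(tl[, "b"], real$obs$id)] >
                    real$obs$t[match(tl[, "a"], real$obs$id)]))
  expect_identical(validate_partition(true_partition(real), real$obs),
                   character(0))
})

test_that("track lifetimes are geometric with mean 1/(1-p_s)", {
  set.seed(7)
  p_s <- 0.9
  gt <- simulate_ground_truth(2, p_s, list(mode = "random_walk", D = 0.05),
                              c(100, 100), 400)
  lives <- vapply(gt$tracks, nrow, integer(1))
  # drop truncated tracks (born too late to die naturally)
  births <- vapply(gt$tracks, function(tr) tr$t[1], numeric(1))
  keep <- births < 200
  skip_if(sum(keep) < 100)
  expect_equal(mean(lives[keep]), 1 / (1 - p_s), tolerance = 0.15)
})

test_that("crossing-lines pattern keeps one observation per line and frame", {
  set.seed(8)
  real <- simulate_crossing_lines(n_lines = 3, n_frames = 15)
  expect_identical(nrow(real$obs), 45L)
  expect_identical(nrow(real$true_links), 3L * 14L)
  expect_identical(validate_partition(true_partition(real), real$obs),
                   character(0))
})
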