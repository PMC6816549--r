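test_that("partition validation flags each broken invariant", {
  obs <- observation_set(t = c(0, 1, 2, 0), x = c(1, 2, 3, 8),
                         y = c(1, 1, 1, 8), fov = c(10, 10))
  expect_identical(validate_partition(minimum_partition(obs), obs),
                   character(0))
  expect_match(validate_partition(partition(list(2L), c(1L, 3L, 4L)), obs),
               "size < 2", all = FALSE)
  p_dup <- partition(list(c(1L, 2L), c(2L, 3L)), 4L)
  expect_match(validate_partition(p_dup, obs), "duplicated", all = FALSE)
  p_unknown <- partition(list(c(1L, 9L)), c(2L, 3L, 4L))
  expect_match(validate_partition(p_unknown, obs), "unknown", all = FALSE)
  p_missing <- partition(list(), c(1L, 2L, 3L))
  expect_match(validate_partition(p_missing, obs), "unassigned", all = FALSE)
  p_order <- partition(list(c(2L, 1L)), c(3L, 4L))
  expect_match(validate_partition(p_order, obs), "increasing", all = FALSE)
})

test_that("links_of counts consecutive pairs per track", {
  obs <- observation_set(t = 0:5, x = 1:6, y = rep(1, 6), fov = c(10, 10))
  expect_equal(nrow(links_of(partition(list(1:4), 5:6))), 3L)
  expect_equal(nrow(links_of(minimum_partition(obs))), 0L)
  expect_equal(nrow(links_of(partition(list(c(1L, 2L), c(3L, 4L)), 5:6))),
               2L)
})

test_that("graph edit distance is the link-set symmetric difference", {
  obs <- observation_set(t = c(0, 0, 1, 1, 2, 2), x = c(1, 5, 1, 5, 1, 5),
                         y = rep(1, 6), fov = c(8, 8))
  a <- partition(list(c(1L, 3L, 5L), c(2L, 4L, 6L)), integer())
  expect_identical(ged(a, a, obs), 0L)
  # one merge of two tracks differs by exactly one link
  b <- partition(list(c(1L, 3L), c(5L), c(2L, 4L, 6L)), integer())
  b <- partition(list(c(1L, 3L), c(2L, 4L, 6L)), 5L)
  expect_identical(ged(a, b, obs), 1L)
  # brute-force symmetric difference over explicit link sets
  c_ <- partition(list(c(1L, 4L, 6L)), c(2L, 3L, 5L))
  la <- apply(links_of(a), 1L, paste, collapse = "-")
  lc <- apply(links_of(c_), 1L, paste, collapse = "-")
  expect_identical(ged(a, c_, obs),
                   length(setdiff(la, lc)) + length(setdiff(lc, la)))
  expect_error(ged(a, partition(list(), 1:5), obs), "universe")
})

test_that("ged is a metric on random partition triples", {
  real <- sim_realisation(11, lambda_b = 0.6, fov = c(30, 30), n_frames = 20)
  obs <- real$obs
  set.seed(2)
  ps <- lapply(c(100L, 400L, 900L), function(n) warmed_partition(obs, n))
  for (i in 1:3) for (j in 1:3) {
    expect_gte(ged(ps[[i]], ps[[j]], obs), 0L)
    expect_identical(ged(ps[[i]], ps[[j]], obs), ged(ps[[j]], ps[[i]], obs))
  }
  expect_lte(ged(ps[[1]], ps[[3]], obs),
             ged(ps[[1]], ps[[2]], obs) + ged(ps[[2]], ps[[3]], obs))
})

test_that("minimum partition has no tracks, no links, and validates", {
  obs <- observation_set(t = rep(0:4, 2), x = runif(10, 0, 9),
                         y = runif(10, 0, 9), fov = c(10, 10))
  p <- minimum_partition(obs)
  expect_identical(n_tracks(p), 0L)
  expect_identical(length(p$clutter), 10L)
  expect_identical(nrow(links_of(p)), 0L)
  expect_identical(validate_partition(p, obs), character(0))
})

test_that("greedy maximum partition is maximal and seed-dependent", {
  real <- sim_realisation(21, lambda_b = 2.5, fov = c(40, 40), n_frames = 25)
  obs <- real$obs
  expect_gte(nrow(obs), 50L)
  parts <- lapply(1:3, function(s) {
    set.seed(s)
    p <- greedy_maximum_partition(obs, max_speed = 5, gate_frames = 2L)
    expect_identical(validate_partition(p, obs), character(0))
    expect_false(sptmcmc:::.addable_link_exists(p, obs, 5, 2L))
    p
  })
  # forced link: two close observations in consecutive frames
  obs2 <- observation_set(t = c(0, 1), x = c(1, 1.5), y = c(1, 1),
                          fov = c(5, 5))
  set.seed(1)
  p2 <- greedy_maximum_partition(obs2, max_speed = 5)
  expect_identical(n_tracks(p2), 1L)
  # single-frame data cannot be linked at all
  obs3 <- observation_set(t = c(0, 0, 0), x = 1:3, y = rep(1, 3),
                          fov = c(5, 5))
  expect_identical(n_tracks(greedy_maximum_partition(obs3, 5)), 0L)
})
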