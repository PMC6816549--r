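test_that("every move type's proposal masses sum to one", {
  toy <- toy_two_tracks()
  cfg <- sampler_config(max_speed = 6, gate_frames = 2)
  for (part in list(toy$part, minimum_partition(toy$obs),
                    partition(list(c(1L, 3L, 5L, 7L)),
                              c(2L, 4L, 6L, 8L, 9L, 10L)))) {
    for (mv in sptmcmc:::.move_names) {
      en <- enumerate_proposals(part, toy$obs, mv, cfg)
      tot <- sum(vapply(en$leaves, function(l) l$prob, numeric(1))) +
        en$identity_mass
      expect_equal(tot, 1, tolerance = 1e-12,
                   label = sprintf("mass of %s", mv))
      for (l in en$leaves)
        expect_identical(validate_partition(l$partition, toy$obs),
                         character(0))
    }
  }
})

test_that("kernel forward and reverse masses match the enumerator", {
  toy <- toy_two_tracks()
  cfg <- sampler_config(max_speed = 6, gate_frames = 2)
  inv <- c(birth = "death", death = "birth", extend = "reduce",
           reduce = "extend", split = "merge", merge = "split",
           update = "update", transfer = "transfer",
           cross_over = "cross_over")
  set.seed(99)
  n_checked <- 0L
  for (k in 1:400) {
    pr <- propose(toy$part, toy$obs, cfg)
    if (pr$is_identity) next
    expect_equal(q_mass(toy$part, pr$proposal, pr$move_type, toy$obs, cfg),
                 pr$log_q_fwd, tolerance = 1e-10)
    expect_equal(q_mass(pr$proposal, toy$part, inv[[pr$move_type]],
                        toy$obs, cfg),
                 pr$log_q_rev, tolerance = 1e-10)
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 100L)
})

test_that("reduce forward mass is the four-factor branch product", {
  toy <- toy_two_tracks()
  cfg <- sampler_config(max_speed = 6, gate_frames = 2)
  K <- n_tracks(toy$part)
  set.seed(3)
  found <- FALSE
  for (k in 1:200) {
    pr <- propose(toy$part, toy$obs, cfg, move = "reduce")
    if (pr$is_identity) next
    found <- TRUE
    # both tracks have 4 observations: c = 4 - 2 = 2 allowed cut points
    expect_equal(pr$log_q_fwd, log(1 / 9 * 1 / K * 1 / 2 * 1 / 2),
                 tolerance = 1e-12)
  }
  expect_true(found)
})

test_that("dead-end branches return identity proposals", {
  # a lone clutter observation cannot seed a two-observation track
  obs <- observation_set(t = c(0, 5), x = c(1, 1), y = c(1, 1),
                         n_frames = 6, fov = c(5, 5))
  cfg <- sampler_config(gate_frames = 2)
  set.seed(1)
  for (k in 1:20) {
    pr <- propose(minimum_partition(obs), obs, cfg, move = "birth")
    expect_true(pr$is_identity)
  }
  # death on a partition without tracks
  pr <- propose(minimum_partition(obs), obs, cfg, move = "death")
  expect_true(pr$is_identity)
})

test_that("move footprints respect the per-move GED bounds", {
  real <- sim_realisation(71, lambda_b = 3, fov = c(40, 40),
                          n_frames = 30)
  obs <- real$obs
  cfg <- sampler_config()
  set.seed(8)
  part <- warmed_partition(obs, 3000L)
  b <- propose_batch(part, obs, 8000L, cfg)
  b <- b[!b$is_identity, ]
  mx <- tapply(b$ged, b$move_type, max)
  expect_equal(unname(mx[["merge"]]), 1)
  expect_equal(unname(mx[["split"]]), 1)
  expect_lte(mx[["cross_over"]], 4L)
  expect_lte(mx[["update"]], 4L)
  expect_lte(mx[["transfer"]], 6L)
  # single-track moves touch one track: GED below T
  expect_lt(max(b$ged), n_frames(obs))
})

test_that("no proposal ever creates a link beyond the speed gate", {
  real <- sim_realisation(81, lambda_b = 3, fov = c(30, 30),
                          n_frames = 20)
  obs <- real$obs
  cfg <- sampler_config(max_speed = 3, gate_frames = 3)
  set.seed(12)
  part <- warmed_partition(obs, 1500L, cfg = cfg)
  n_links_seen <- 0L
  for (k in 1:200) {
    pr <- propose(part, obs, cfg)
    l <- links_of(pr$proposal)
    if (nrow(l) == 0L) next
    dt <- obs$t[match(l[, "b"], obs$id)] - obs$t[match(l[, "a"], obs$id)]
    d <- sqrt((obs$x[match(l[, "a"], obs$id)] -
                 obs$x[match(l[, "b"], obs$id)])^2 +
              (obs$y[match(l[, "a"], obs$id)] -
                 obs$y[match(l[, "b"], obs$id)])^2)
    n_links_seen <- n_links_seen + nrow(l)
    expect_true(all(dt >= 1 & dt <= cfg$gate_frames))
    expect_true(all(d <= cfg$max_speed * dt + 1e-9))
  }
  expect_gt(n_links_seen, 0L)
})

test_that("the chain reaches every partition of a toy from the minimum", {
  obs <- toy_bipartite()
  cfg <- sampler_config(gate_frames = 2)
  all_p <- enumerate_all_partitions(obs, cfg)
  set.seed(17)
  res <- sptmcmc:::.run_core(minimum_partition(obs), obs, toy_theta(),
                             cfg, 30000L, record_mode = 2L)
  visited <- unique(res$masks)
  expect_setequal(visited, vapply(all_p, function(e) e$mask, numeric(1)))
})
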