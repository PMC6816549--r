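# Shared sampler runs for the performance tests: simulated under the study
# conditions (random-walk D = 0.08 px^2/frame, p_o = 0.9, p_s = 0.98,
# localisation error 0.1 px, clutter 0.4E over T = 100 frames; birth rate
# 0.1E on a 100x100 px field of view or 1.6E on a 25x25 px one). Computed
# once and reused across test files.
.run_cache <- new.env(parent = emptyenv())

fig5_case <- function(case_seed, lambda_b, fov, max_sweeps) {
  key <- sprintf("case_%d_%g", case_seed, lambda_b)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  set.seed(case_seed)
  gt <- simulate_ground_truth(lambda_b, 0.98,
                              list(mode = "random_walk", D = 0.08),
                              fov, 100)
  real <- realise(gt, p_o = 0.9, loc_error = 0.1, lambda_c = 0.4)
  cfg <- sampler_config(n_record = 300, max_sweeps = max_sweeps,
                        check_every = 200)
  run <- run_sampler(real$obs, cfg, seed = case_seed + 7L)
  out <- list(real = real, run = run,
              lp = link_probabilities(pooled_samples(run), real$obs))
  .run_cache[[key]] <- out
  out
}

fig5_low <- function() lapply(1:3, function(i)
  fig5_case(9000L + i, 0.1, c(100, 100), 20000L))

fig5_high <- function() lapply(1:3, function(i)
  fig5_case(9500L + i, 1.6, c(25, 25), 16000L))
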