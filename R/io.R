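#' Read an observation table
#'
#' Delimited text with a header containing at least `frame`, `x`, `y`
#' (extra columns are ignored). Ids are assigned by row order; `T` defaults
#' to `max(frame) + 1` and the field of view to the data extent rounded up,
#' unless overridden.
#'
#' @param path file path.
#' @param n_frames,fov optional overrides.
#' @param sep field separator (default comma).
#' @return An `spt_observations` object.
#' @export
read_observations <- function(path, n_frames = NULL, fov = NULL, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(observation_set(integer(), numeric(), numeric(),
                           n_frames = if (is.null(n_frames)) 0L else n_frames,
                           fov = fov))
  need <- c("frame", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (cl in need)
    if (!is.numeric(df[[cl]]))
      stop("non-numeric values in column ", cl)
  if (any(df$frame < 0)) stop("negative frame indices")
  observation_set(df$frame, df$x, df$y, n_frames = n_frames, fov = fov)
}

#' Write an observation table
#' @param obs an `spt_observations` object.
#' @param path output path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(data.frame(frame = obs$t, x = obs$x, y = obs$y),
                   path, row.names = FALSE, quote = FALSE)
}

#' Write partition samples as JSON lines
#'
#' One sample per line: a JSON array of tracks, each a list of observation
#' ids. Compact and streamable; the clutter set is implicit (all ids not
#' in any track).
#'
#' @param samples list of `spt_partition`.
#' @param path output path.
#' @export
write_partitions_jsonl <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in samples)
    writeLines(jsonlite::toJSON(p$tracks), con)
  invisible(path)
}

#' Read partition samples from JSON lines
#' @param path file path.
#' @param obs the `spt_observations` the partitions refer to.
#' @export
read_partitions_jsonl <- function(path, obs) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    tracks <- jsonlite::fromJSON(l, simplifyVector = FALSE)
    tracks <- lapply(tracks, function(tr) as.integer(unlist(tr)))
    partition(tracks, setdiff(obs$id, unlist(tracks, use.names = FALSE)))
  })
}

#' Write the outputs of a sampler run
#'
#' Writes, under `dir`: `links.csv` (posterior link probabilities with
#' frames), `theta_trace.csv` (one row per recorded parameter draw, both
#' chains), `partitions_chain1.jsonl` / `partitions_chain2.jsonl`,
#' `convergence.json`, `move_stats.txt` (per-move rejected / identity /
#' accepted table) and `manifest.json` (configuration, seed, versions).
#'
#' @param run an `spt_chains` object from [run_sampler()].
#' @param obs the `spt_observations` that were tracked.
#' @param dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(run, obs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lp <- link_probabilities(pooled_samples(run), obs)
  links <- data.frame(obs_a = lp$a, obs_b = lp$b,
                      frame_a = obs$t[match(lp$a, obs$id)],
                      frame_b = obs$t[match(lp$b, obs$id)],
                      p_hat = lp$p_hat)
  utils::write.csv(links, file.path(dir, "links.csv"), row.names = FALSE,
                   quote = FALSE)
  tt <- rbind(cbind(chain = 1L, run$chains[[1]]$theta_trace),
              cbind(chain = 2L, run$chains[[2]]$theta_trace))
  utils::write.csv(tt, file.path(dir, "theta_trace.csv"),
                   row.names = FALSE, quote = FALSE)
  write_partitions_jsonl(run$chains[[1]]$partitions,
                         file.path(dir, "partitions_chain1.jsonl"))
  write_partitions_jsonl(run$chains[[2]]$partitions,
                         file.path(dir, "partitions_chain2.jsonl"))
  conv <- run$convergence
  if (is.null(conv))
    conv <- list(cross_ged_mean = NA, inner_ged_means = c(NA, NA),
                 psrf = c(lambda_b = NA, lambda_c = NA, p_o = NA, p_s = NA))
  jsonlite::write_json(
    list(converged = run$converged,
         cross_ged_mean = conv$cross_ged_mean,
         inner_ged_means = conv$inner_ged_means,
         psrf = as.list(conv$psrf),
         burnin_sweeps = run$burnin_sweeps),
    file.path(dir, "convergence.json"), auto_unbox = TRUE, digits = NA)
  ms <- lapply(run$chains, function(ch) {
    m <- ch$move_stats
    tot <- pmax(rowSums(m), 1)
    cbind(round(100 * m / tot, 1), total = rowSums(m))
  })
  con <- file(file.path(dir, "move_stats.txt"), "w")
  for (i in 1:2) {
    writeLines(sprintf("chain %d (%% of proposals per move type)", i), con)
    utils::write.table(ms[[i]], con, quote = FALSE, sep = "\t",
                       col.names = NA)
    writeLines("", con)
  }
  close(con)
  manifest <- list(
    package = "sptmcmc",
    version = as.character(utils::packageVersion("sptmcmc")),
    r_version = as.character(getRversion()),
    seed = run$seed,
    burnin_sweeps = run$burnin_sweeps,
    steps_per_sweep = run$steps_per_sweep,
    thin_n = c(run$chains[[1]]$thin_n, run$chains[[2]]$thin_n),
    n_record = length(run$chains[[1]]$partitions),
    config = run$cfg[!vapply(run$cfg, is.null, logical(1))])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
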