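#' Simulate ground-truth tracks
#'
#' Per frame, `Poisson(lambda_b * fov/A)` new tracks are born at uniform
#' positions; each track survives from frame to frame with probability
#' `p_s` (geometric lifetime, truncated by the end of the movie). States
#' evolve according to the chosen motion mode:
#' \itemize{
#' \item `random_walk`: per-axis Gaussian steps of variance `2 D` per frame
#'   (so the 2-D mean squared displacement grows as `4 D tau`);
#' \item `directed`: constant speed along a heading that turns by a
#'   Gaussian angle each frame;
#' \item `mixture`: each track picks one of the two modes with equal
#'   probability at birth;
#' \item `switching`: tracks flip between the two modes with a per-frame
#'   switch probability.
#' }
#' States may wander outside the field of view; cropping happens at
#' realisation time.
#'
#' @param lambda_b birth rate in E (events per frame per 100 px x 100 px).
#' @param p_s per-frame survival probability.
#' @param motion list with `mode` and mode parameters `D` (px^2/frame),
#'   `speed` (px/frame), `turn_sd` (radians), `switch_prob`.
#' @param fov numeric `(width, height)` in px.
#' @param n_frames number of frames.
#' @param area_unit rate normalisation area (px^2).
#' @return An object of class `spt_ground_truth`: list of per-track data
#'   frames with columns `t`, `x`, `y`, plus the generating parameters.
#' @export
simulate_ground_truth <- function(lambda_b = 0.1, p_s = 0.98,
                                  motion = list(mode = "random_walk",
                                                D = 0.08),
                                  fov = c(100, 100), n_frames = 100,
                                  area_unit = 1e4) {
  stopifnot(lambda_b >= 0, p_s >= 0, p_s <= 1)
  mode <- match.arg(motion$mode,
                    c("random_walk", "directed", "mixture", "switching"))
  D <- if (is.null(motion$D)) 0.08 else motion$D
  speed <- if (is.null(motion$speed)) 1.0 else motion$speed
  turn_sd <- if (is.null(motion$turn_sd)) 0.3 else motion$turn_sd
  switch_prob <- if (is.null(motion$switch_prob)) 0.05 else motion$switch_prob
  mu_b <- lambda_b * prod(fov) / area_unit
  tracks <- list()
  for (t0 in 0:(n_frames - 1L)) {
    for (k in seq_len(stats::rpois(1L, mu_b))) {
      life <- 1L + stats::rgeom(1L, prob = 1 - p_s)
      life <- min(life, n_frames - t0)
      xs <- numeric(life)
      ys <- numeric(life)
      xs[1L] <- stats::runif(1L, 0, fov[1L])
      ys[1L] <- stats::runif(1L, 0, fov[2L])
      diffusive <- switch(mode,
        random_walk = TRUE,
        directed = FALSE,
        mixture = stats::runif(1L) < 0.5,
        switching = stats::runif(1L) < 0.5)
      heading <- stats::runif(1L, 0, 2 * pi)
      if (life > 1L) for (i in 2:life) {
        if (mode == "switching" && stats::runif(1L) < switch_prob)
          diffusive <- !diffusive
        if (diffusive) {
          xs[i] <- xs[i - 1L] + stats::rnorm(1L, sd = sqrt(2 * D))
          ys[i] <- ys[i - 1L] + stats::rnorm(1L, sd = sqrt(2 * D))
        } else {
          heading <- heading + stats::rnorm(1L, sd = turn_sd)
          xs[i] <- xs[i - 1L] + speed * cos(heading)
          ys[i] <- ys[i - 1L] + speed * sin(heading)
        }
      }
      tracks[[length(tracks) + 1L]] <-
        data.frame(t = t0:(t0 + life - 1L), x = xs, y = ys)
    }
  }
  structure(list(tracks = tracks, lambda_b = lambda_b, p_s = p_s,
                 motion = list(mode = mode, D = D, speed = speed,
                               turn_sd = turn_sd,
                               switch_prob = switch_prob),
                 fov = fov, n_frames = n_frames, area_unit = area_unit),
            class = "spt_ground_truth")
}

#' @export
print.spt_ground_truth <- function(x, ...) {
  cat(sprintf("<spt_ground_truth> %d tracks over %d frames, fov %g x %g\n",
              length(x$tracks), x$n_frames, x$fov[1], x$fov[2]))
  invisible(x)
}

#' Realise a ground truth into observed data
#'
#' Each live state is observed with probability `p_o` and jittered by
#' isotropic Gaussian localisation noise; clutter observations arrive as a
#' per-frame Poisson with uniform positions; everything outside the field
#' of view is cropped away. The realisation keeps the labels: which
#' observation came from which track, and the set of true links
#' (consecutive surviving observations of a track). Tracks that retain
#' fewer than two observations contribute unlinkable singletons and no
#' true links.
#'
#' @param gt an `spt_ground_truth`.
#' @param p_o per-frame observation probability.
#' @param loc_error localisation error standard deviation (px).
#' @param lambda_c clutter rate in E.
#' @return An object of class `spt_realisation`: list with `obs` (an
#'   `spt_observations`), `labels` (integer vector per observation id:
#'   track number or `NA` for clutter) and `true_links` (matrix with
#'   columns `a`, `b`).
#' @export
realise <- function(gt, p_o = 0.9, loc_error = 0.1, lambda_c = 0.4) {
  mu_c <- lambda_c * prod(gt$fov) / gt$area_unit
  rows <- list()
  for (i in seq_along(gt$tracks)) {
    tr <- gt$tracks[[i]]
    seen <- stats::runif(nrow(tr)) < p_o
    if (!any(seen)) next
    ox <- tr$x[seen] + stats::rnorm(sum(seen), sd = loc_error)
    oy <- tr$y[seen] + stats::rnorm(sum(seen), sd = loc_error)
    keep <- ox >= 0 & ox < gt$fov[1L] & oy >= 0 & oy < gt$fov[2L]
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.frame(t = tr$t[seen][keep], x = ox[keep], y = oy[keep],
                 label = i)
  }
  for (f in 0:(gt$n_frames - 1L)) {
    nc <- stats::rpois(1L, mu_c)
    if (nc > 0L)
      rows[[length(rows) + 1L]] <-
        data.frame(t = f, x = stats::runif(nc, 0, gt$fov[1L]),
                   y = stats::runif(nc, 0, gt$fov[2L]), label = NA_integer_)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t = integer(), x = numeric(), y = numeric(),
               label = integer())
  df <- df[order(df$t, df$x), , drop = FALSE]
  obs <- observation_set(df$t, df$x, df$y, n_frames = gt$n_frames,
                         fov = gt$fov, area_unit = gt$area_unit)
  labels <- df$label
  true_links <- do.call(rbind, lapply(
    stats::na.omit(unique(labels)), function(lb) {
      ids <- obs$id[which(labels == lb)]
      ids <- ids[order(obs$t[match(ids, obs$id)])]
      if (length(ids) < 2L) return(NULL)
      cbind(a = ids[-length(ids)], b = ids[-1L])
    }))
  if (is.null(true_links)) true_links <- cbind(a = integer(), b = integer())
  structure(list(obs = obs, labels = labels, true_links = true_links,
                 gt = gt, p_o = p_o, loc_error = loc_error,
                 lambda_c = lambda_c),
            class = "spt_realisation")
}

#' @export
print.spt_realisation <- function(x, ...) {
  cat(sprintf(
    "<spt_realisation> N = %d observations (%d clutter), %d true links\n",
    nrow(x$obs), sum(is.na(x$labels)), nrow(x$true_links)))
  invisible(x)
}

#' True partition of a realisation
#'
#' The labelled assignment of the realised observations: one track per
#' ground-truth track with at least two surviving observations, everything
#' else (clutter and unlinkable singletons) in the clutter set.
#'
#' @param real an `spt_realisation`.
#' @export
true_partition <- function(real) {
  obs <- real$obs
  labs <- real$labels
  tracks <- list()
  for (lb in stats::na.omit(unique(labs))) {
    ids <- obs$id[which(labs == lb)]
    if (length(ids) < 2L) next
    tracks[[length(tracks) + 1L]] <- ids[order(obs$t[match(ids, obs$id)])]
  }
  partition(tracks, setdiff(obs$id, unlist(tracks, use.names = FALSE)))
}

#' Intersecting straight-line test pattern
#'
#' A deterministic-geometry data set of straight lines with additive white
#' noise, whose crossings exercise track split/merge ambiguity. Not drawn
#' from the birth-death model.
#'
#' @param n_lines number of lines.
#' @param n_frames frames.
#' @param fov field of view.
#' @param noise_sd white-noise standard deviation (px).
#' @return An `spt_realisation` (labels by line, all links true).
#' @export
simulate_crossing_lines <- function(n_lines = 3, n_frames = 21,
                                    fov = c(60, 60), noise_sd = 0.2) {
  rows <- list()
  for (i in seq_len(n_lines)) {
    x0 <- stats::runif(1L, 5, fov[1L] - 5)
    x1 <- stats::runif(1L, 5, fov[1L] - 5)
    y0 <- stats::runif(1L, 5, fov[2L] - 5)
    y1 <- stats::runif(1L, 5, fov[2L] - 5)
    s <- seq(0, 1, length.out = n_frames)
    rows[[i]] <- data.frame(
      t = 0:(n_frames - 1L),
      x = pmin(pmax(x0 + s * (x1 - x0) + stats::rnorm(n_frames, sd = noise_sd), 0),
               fov[1L] - 1e-6),
      y = pmin(pmax(y0 + s * (y1 - y0) + stats::rnorm(n_frames, sd = noise_sd), 0),
               fov[2L] - 1e-6),
      label = i)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$t, df$x), , drop = FALSE]
  obs <- observation_set(df$t, df$x, df$y, n_frames = n_frames, fov = fov)
  labels <- df$label
  true_links <- do.call(rbind, lapply(unique(labels), function(lb) {
    ids <- obs$id[which(labels == lb)]
    ids <- ids[order(obs$t[match(ids, obs$id)])]
    cbind(a = ids[-length(ids)], b = ids[-1L])
  }))
  gt <- structure(list(tracks = list(), lambda_b = NA, p_s = NA,
                       motion = list(mode = "lines"), fov = fov,
                       n_frames = n_frames, area_unit = 1e4),
                  class = "spt_ground_truth")
  structure(list(obs = obs, labels = labels, true_links = true_links,
                 gt = gt, p_o = 1, loc_error = noise_sd, lambda_c = 0),
            class = "spt_realisation")
}
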