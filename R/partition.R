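#' Construct a track partition
#'
#' A partition assigns every observation either to exactly one track or to
#' the clutter. A track is a time-ordered sequence of at least two
#' observations, at most one per frame; its birth and death times are the
#' frames of its first and last observations. A *link* is a pair of
#' consecutive observations within a track; the frames of a link need not be
#' adjacent (blinking gaps).
#'
#' @param tracks list of integer vectors of observation ids, each in
#'   increasing time order.
#' @param clutter integer vector of observation ids assigned to no track.
#' @return An object of class `spt_partition` with elements `tracks` and
#'   `clutter`.
#' @export
partition <- function(tracks = list(), clutter = integer()) {
  tracks <- lapply(tracks, function(tr) as.integer(tr))
  structure(list(tracks = tracks, clutter = as.integer(sort(clutter))),
            class = "spt_partition")
}

#' @export
print.spt_partition <- function(x, ...) {
  cat(sprintf("<spt_partition> K = %d tracks, |clutter| = %d\n",
              n_tracks(x), length(x$clutter)))
  invisible(x)
}

#' Number of tracks in a partition
#' @param part an `spt_partition`.
#' @export
n_tracks <- function(part) length(part$tracks)

#' Validate a partition against an observation set
#'
#' Checks every partition and track invariant: each observation appears in
#' exactly one track or in the clutter, tracks have at least two
#' observations in strictly increasing frame order with at most one
#' observation per frame, and all referenced ids exist. Violations are
#' reported, not thrown.
#'
#' @param part an `spt_partition`.
#' @param obs an `spt_observations` object.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_partition <- function(part, obs) {
  bad <- character()
  ids <- obs$id
  all_assigned <- c(unlist(part$tracks, use.names = FALSE), part$clutter)
  unknown <- setdiff(all_assigned, ids)
  if (length(unknown))
    bad <- c(bad, sprintf("unknown observation id referenced: %s",
                          paste(unknown, collapse = ",")))
  dup <- unique(all_assigned[duplicated(all_assigned)])
  if (length(dup))
    bad <- c(bad, sprintf("duplicated assignment of observation(s): %s",
                          paste(dup, collapse = ",")))
  missing <- setdiff(ids, all_assigned)
  if (length(missing))
    bad <- c(bad, sprintf("unassigned observation(s): %s",
                          paste(missing, collapse = ",")))
  tmap <- integer(0)
  if (nrow(obs) > 0L) {
    tmap <- obs$t
    names(tmap) <- as.character(obs$id)
  }
  for (i in seq_along(part$tracks)) {
    tr <- part$tracks[[i]]
    if (length(tr) < 2L) {
      bad <- c(bad, sprintf("track %d size < 2 (ids %s)", i,
                            paste(tr, collapse = ",")))
      next
    }
    if (any(!as.character(tr) %in% names(tmap))) next  # already reported
    tt <- unname(tmap[as.character(tr)])
    if (any(diff(tt) <= 0L))
      bad <- c(bad, sprintf(
        "track %d frames not strictly increasing (at most one observation per frame)", i))
  }
  bad
}

#' Extract the link set of a partition
#'
#' @param part an `spt_partition`.
#' @return Integer matrix with columns `a`, `b`: one row per link, where
#'   `a` precedes `b` within a track. Zero rows for the minimum partition.
#' @export
links_of <- function(part) {
  ls <- lapply(part$tracks, function(tr) {
    m <- length(tr)
    if (m < 2L) return(NULL)
    cbind(a = tr[-m], b = tr[-1L])
  })
  out <- do.call(rbind, ls)
  if (is.null(out)) out <- cbind(a = integer(), b = integer())
  out
}

# Encode links as single integers for fast set operations. Valid for
# observation ids below 2^26 or so; ids here are row indices, far smaller.
.link_keys <- function(links, n_ids) {
  if (nrow(links) == 0L) return(integer())
  as.numeric(links[, 1L]) * (n_ids + 1) + as.numeric(links[, 2L])
}

#' Graph edit distance between two partitions
#'
#' Partitions over the same observation set are compared as graphs whose
#' nodes are observations and whose edges are links; link insertion and
#' deletion are the edit operations, so the distance is the size of the
#' symmetric difference of the two link sets. Track birth/death times do
#' not enter the distance.
#'
#' @param a,b `spt_partition` objects over the same observation set.
#' @param obs the common `spt_observations` object.
#' @return Non-negative integer count of differing links.
#' @export
ged <- function(a, b, obs) {
  universe_a <- sort(c(unlist(a$tracks, use.names = FALSE), a$clutter))
  universe_b <- sort(c(unlist(b$tracks, use.names = FALSE), b$clutter))
  if (!identical(universe_a, universe_b))
    stop("partitions cover different observation universes")
  n <- max(0L, universe_a, nrow(obs))
  ka <- .link_keys(links_of(a), n)
  kb <- .link_keys(links_of(b), n)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' The minimum partition: all observations in the clutter
#'
#' The partition without any links; one of the two chain initialisations.
#' @param obs an `spt_observations` object.
#' @export
minimum_partition <- function(obs) partition(list(), obs$id)

#' A randomised greedy maximum partition
#'
#' Assigns as many observations as possible to tracks: frames are scanned in
#' time order and each observation is linked to the nearest compatible
#' (speed-gated) unassigned observation or open track end within the
#' preceding `gate_frames` frames, with scan order and distance ties
#' randomised by the current RNG state. The result is maximal: no further
#' legal link can be added between a clutter observation and a track end or
#' between two clutter observations. Many distinct maximum partitions exist;
#' different seeds may give different ones.
#'
#' @param obs an `spt_observations` object.
#' @param max_speed maximum particle speed in px/frame used to gate links.
#' @param gate_frames maximum frame gap of a link considered by the greedy
#'   scan (default 2).
#' @return An `spt_partition`.
#' @export
greedy_maximum_partition <- function(obs, max_speed, gate_frames = 2L) {
  stopifnot(max_speed > 0)
  n <- nrow(obs)
  if (n == 0L) return(minimum_partition(obs))
  succ <- integer(n)        # successor id (0 = none)
  has_pred <- logical(n)    # id has been linked to a predecessor
  taken <- logical(n)       # id already has a successor
  by_frame <- split(obs$id, factor(obs$t, levels = 0:(n_frames(obs) - 1L)))
  xs <- obs$x[order(obs$id)]; ys <- obs$y[order(obs$id)]
  for (fr in seq_along(by_frame)) {
    t_now <- fr - 1L
    cand_frames <- seq.int(max(0L, t_now - gate_frames), t_now - 1L)
    if (!length(cand_frames) || t_now == 0L) next
    here <- by_frame[[fr]]
    if (!length(here)) next
    here <- here[sample.int(length(here))]
    for (o in here) {
      # open ends: observations in the window with no successor yet, that are
      # either unassigned or the current last observation of a track
      prev_ids <- unlist(by_frame[cand_frames + 1L], use.names = FALSE)
      if (!length(prev_ids)) next
      prev_ids <- prev_ids[!taken[prev_ids]]
      if (!length(prev_ids)) next
      dt <- t_now - obs$t[match(prev_ids, obs$id)]
      d2 <- (xs[o] - xs[prev_ids])^2 + (ys[o] - ys[prev_ids])^2
      ok <- d2 <= (max_speed * dt)^2
      prev_ids <- prev_ids[ok]; d2 <- d2[ok]
      if (!length(prev_ids)) next
      pick <- prev_ids[order(d2, stats::runif(length(d2)))][1L]
      succ[pick] <- o
      taken[pick] <- TRUE
      has_pred[o] <- TRUE
    }
  }
  starts <- which(succ > 0L & !has_pred)
  tracks <- lapply(starts, function(s) {
    tr <- s
    while (succ[tr[length(tr)]] > 0L) tr <- c(tr, succ[tr[length(tr)]])
    tr
  })
  clutter <- setdiff(obs$id, unlist(tracks, use.names = FALSE))
  partition(tracks, clutter)
}

# Exhaustive scan for a link that could still legally be added between a
# clutter observation and a track end, or between two clutter observations at
# different frames. Used to verify maximality.
.addable_link_exists <- function(part, obs, max_speed, gate_frames = 2L) {
  ends <- vapply(part$tracks, function(tr) tr[length(tr)], integer(1))
  open <- c(ends, part$clutter)
  for (o in part$clutter) {
    to <- obs$t[match(o, obs$id)]
    for (e in open) {
      if (e == o) next
      te <- obs$t[match(e, obs$id)]
      dt <- to - te
      if (dt < 1L || dt > gate_frames) next
      d2 <- (obs$x[match(o, obs$id)] - obs$x[match(e, obs$id)])^2 +
        (obs$y[match(o, obs$id)] - obs$y[match(e, obs$id)])^2
      if (d2 <= (max_speed * dt)^2) return(TRUE)
    }
  }
  FALSE
}
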