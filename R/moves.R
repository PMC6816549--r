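#' @useDynLib sptmcmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.move_names <- c("birth", "death", "extend", "reduce", "split", "merge",
                 "update", "transfer", "cross_over")

.move_code <- function(move) {
  if (is.null(move)) return(-1L)
  m <- match.arg(move, .move_names)
  match(m, .move_names) - 1L
}

.theta_list <- function(theta) {
  list(lambda_b = theta$lambda_b, lambda_c = theta$lambda_c,
       p_o = theta$p_o, p_s = theta$p_s, R = theta$R)
}

.model_list <- function(cfg) {
  list(q_pos = cfg$q_pos, q_vel = cfg$q_vel,
       prior_sigma0 = cfg$prior_sigma0, prior_sigmav = cfg$prior_sigmav)
}

.cfg_list <- function(cfg) {
  list(max_speed = cfg$max_speed, gate_frames = as.integer(cfg$gate_frames),
       birth_stop = cfg$birth_stop)
}

.run_core <- function(part, obs, theta, cfg, n_steps, force_move = -1L,
                      propose_only = FALSE, record_every = 0L,
                      record_offset = 0L, record_max = 0L,
                      record_mode = 0L) {
  .bgl_run(obs$t, obs$x, obs$y, n_frames(obs), fov(obs), area_unit(obs),
           lapply(part$tracks, as.integer), as.integer(part$clutter),
           .theta_list(theta), .model_list(cfg), .cfg_list(cfg),
           as.integer(n_steps), as.integer(force_move), propose_only,
           as.integer(record_every), as.integer(record_offset),
           as.integer(record_max), as.integer(record_mode))
}

#' Draw one Metropolis-Hastings proposal
#'
#' Samples a proposal partition from the nine-move kernel by descending its
#' sampling tree: the move type is drawn uniformly (probability 1/9 each)
#' and every subsequent branch probability is multiplied into the forward
#' proposal mass. The probability of the unique inverse path is evaluated
#' in the proposed state, so both `Q(omega*|omega)` and `Q(omega|omega*)`
#' are exact. Dead ends (for example a death move on a partition without
#' tracks, or a birth chain that collects fewer than two observations)
#' return the current partition flagged as an identity proposal.
#'
#' @param current an `spt_partition`.
#' @param obs an `spt_observations` object.
#' @param cfg a [sampler_config()].
#' @param move optional move-type name to force (testing aid); by default
#'   the move type is drawn uniformly.
#' @return A list with `move_type`, `proposal` (`spt_partition`),
#'   `log_q_fwd`, `log_q_rev`, `is_identity` and `ged` (link edit distance
#'   between current and proposal).
#' @export
propose <- function(current, obs, cfg = sampler_config(), move = NULL) {
  res <- .run_core(current, obs, parameters(), cfg, 1L,
                   force_move = .move_code(move), propose_only = TRUE)
  tracks <- res$prop_first
  prop <- partition(tracks,
                    setdiff(obs$id, unlist(tracks, use.names = FALSE)))
  list(move_type = .move_names[res$prop_move[1L]],
       proposal = prop,
       log_q_fwd = res$prop_log_q_fwd[1L],
       log_q_rev = res$prop_log_q_rev[1L],
       is_identity = res$prop_identity[1L],
       ged = res$prop_ged[1L])
}

#' Batch of proposals from a fixed partition
#'
#' Draws `n` proposals from the current partition without applying any of
#' them, returning per-proposal bookkeeping. Used to profile move
#' footprints (link edit distances) over many draws.
#'
#' @inheritParams propose
#' @param n number of proposals.
#' @return A data frame with columns `move_type`, `is_identity`, `ged`,
#'   `log_q_fwd`, `log_q_rev`.
#' @export
propose_batch <- function(current, obs, n, cfg = sampler_config(),
                          move = NULL) {
  res <- .run_core(current, obs, parameters(), cfg, n,
                   force_move = .move_code(move), propose_only = TRUE)
  data.frame(move_type = .move_names[res$prop_move],
             is_identity = res$prop_identity,
             ged = res$prop_ged,
             log_q_fwd = res$prop_log_q_fwd,
             log_q_rev = res$prop_log_q_rev)
}

# ---------------------------------------------------------------------------
# Exhaustive enumeration of a move's sampling tree (reference implementation,
# tractable on toy problems). Probabilities are conditional on the move type.
# ---------------------------------------------------------------------------

.part_key <- function(part, obs) {
  l <- links_of(part)
  if (nrow(l) == 0L) return("")
  paste(sort(l[, 1L] * (nrow(obs) + 1L) + l[, 2L]), collapse = ",")
}

.enum_env <- function(part, obs, cfg) {
  tt <- obs$t
  xx <- obs$x
  yy <- obs$y
  link_ok <- function(a, b) {
    dt <- tt[b] - tt[a]
    dt >= 1L && dt <= cfg$gate_frames &&
      (xx[a] - xx[b])^2 + (yy[a] - yy[b])^2 <= (cfg$max_speed * dt)^2
  }
  clutter <- part$clutter
  cl_dir <- function(o, excl, forward) {
    cand <- setdiff(clutter, excl)
    keep <- vapply(cand, function(b) {
      if (forward) link_ok(o, b) else link_ok(b, o)
    }, logical(1))
    cand[keep]
  }
  list(t = tt, link_ok = link_ok, clutter = clutter, cl_dir = cl_dir,
       tracks = part$tracks, K = n_tracks(part), stopp = cfg$birth_stop)
}

#' Enumerate all proposals of one move type
#'
#' Walks the complete sampling tree of a move type on a (small) partition
#' and returns every reachable leaf with its exact probability, plus the
#' total identity mass from dead-end branches. The leaf probabilities and
#' the identity mass sum to one: the proposal distribution of each move
#' type is a proper probability mass function.
#'
#' @inheritParams propose
#' @param move move-type name.
#' @return A list with `leaves` (list of `list(partition, prob)`) and
#'   `identity_mass`. Leaf probabilities are conditional on the move type
#'   (the uniform 1/9 move-type factor is not included).
#' @export
enumerate_proposals <- function(current, obs, move, cfg = sampler_config()) {
  move <- match.arg(move, .move_names)
  en <- .enum_env(current, obs, cfg)
  leaves <- list()
  identity_mass <- 0
  emit <- function(tracks, clutter, prob) {
    leaves[[length(leaves) + 1L]] <<- list(
      partition = partition(tracks, clutter), prob = prob)
  }
  emit_id <- function(prob) identity_mass <<- identity_mass + prob
  K <- en$K
  tracks <- en$tracks
  clutter <- en$clutter
  stopp <- en$stopp

  chain_walk <- function(chain, prob, forward, done) {
    # done(chain, prob) emits the leaf for stopping with this chain
    cands <- en$cl_dir(chain[length(chain)], chain, forward)
    if (!length(cands)) {
      done(chain, prob)
      return(invisible())
    }
    done(chain, prob * stopp)
    for (cc in cands)
      chain_walk(c(chain, cc), prob * (1 - stopp) / length(cands),
                 forward, done)
  }

  switch(move,
    birth = {
      if (!length(clutter)) {
        emit_id(1)
      } else {
        for (seed in clutter) {
          chain_walk(seed, 1 / length(clutter), TRUE, function(chain, p) {
            if (length(chain) < 2L) emit_id(p)
            else emit(c(tracks, list(chain)), setdiff(clutter, chain), p)
          })
        }
      }
    },
    death = {
      if (K == 0L) emit_id(1)
      else for (i in seq_len(K))
        emit(tracks[-i], c(clutter, tracks[[i]]), 1 / K)
    },
    extend = {
      if (K == 0L) emit_id(1)
      else for (i in seq_len(K)) for (back in c(TRUE, FALSE)) {
        tr <- tracks[[i]]
        seed <- if (back) tr[length(tr)] else tr[1L]
        chain_walk(seed, 1 / (2 * K), back, function(chain, p) {
          added <- chain[-1L]
          if (!length(added)) {
            emit_id(p)
          } else {
            nt <- if (back) c(tr, added) else c(rev(added), tr)
            tr2 <- tracks
            tr2[[i]] <- nt
            emit(tr2, setdiff(clutter, added), p)
          }
        })
      }
    },
    reduce = {
      if (K == 0L) emit_id(1)
      else for (i in seq_len(K)) for (back in c(TRUE, FALSE)) {
        tr <- tracks[[i]]
        cc <- length(tr) - 2L
        if (cc <= 0L) {
          emit_id(1 / (2 * K))
        } else for (j in seq_len(cc)) {
          keep <- if (back) tr[seq_len(length(tr) - j)]
                  else tr[-seq_len(j)]
          rem <- setdiff(tr, keep)
          tr2 <- tracks
          tr2[[i]] <- keep
          emit(tr2, c(clutter, rem), 1 / (2 * K * cc))
        }
      }
    },
    split = {
      elig <- which(vapply(tracks, length, integer(1)) >= 4L)
      if (!length(elig)) emit_id(1)
      else for (i in elig) {
        tr <- tracks[[i]]
        len <- length(tr)
        for (a in 2:(len - 2L)) {
          tr2 <- c(tracks[-i], list(tr[seq_len(a)], tr[(a + 1L):len]))
          emit(tr2, clutter, 1 / (length(elig) * (len - 3L)))
        }
      }
    },
    merge = {
      pairs <- list()
      if (K >= 2L) for (i in seq_len(K)) for (j in seq_len(K)) {
        if (i == j) next
        u <- tracks[[i]]; v <- tracks[[j]]
        if (en$link_ok(u[length(u)], v[1L]))
          pairs[[length(pairs) + 1L]] <- c(i, j)
      }
      if (!length(pairs)) emit_id(1)
      else for (pr in pairs) {
        tr2 <- c(tracks[-pr], list(c(tracks[[pr[1]]], tracks[[pr[2]]])))
        emit(tr2, clutter, 1 / length(pairs))
      }
    },
    update = {
      if (K == 0L) emit_id(1)
      else for (i in seq_len(K)) {
        tr <- tracks[[i]]
        len <- length(tr)
        for (pos in seq_len(len)) {
          o <- tr[pos]
          cands <- Filter(function(b) {
            en$t[b] == en$t[o] &&
              (pos == 1L || en$link_ok(tr[pos - 1L], b)) &&
              (pos == len || en$link_ok(b, tr[pos + 1L]))
          }, clutter)
          if (!length(cands)) {
            emit_id(1 / (K * len))
          } else for (cc in cands) {
            nt <- tr
            nt[pos] <- cc
            tr2 <- tracks
            tr2[[i]] <- nt
            emit(tr2, c(setdiff(clutter, cc), o), 1 / (K * len * length(cands)))
          }
        }
      }
    },
    transfer = {
      if (K < 2L) emit_id(1)
      else for (src in seq_len(K)) {
        tr <- tracks[[src]]
        len <- length(tr)
        if (len < 3L) { emit_id(1 / K); next }
        for (pos in 2:(len - 1L)) {
          o <- tr[pos]
          if (!en$link_ok(tr[pos - 1L], tr[pos + 1L])) {
            emit_id(1 / (K * (len - 2L)))
            next
          }
          slot_of <- function(tg) {
            to <- en$t[o]
            if (to <= en$t[tg[1L]] || to >= en$t[tg[length(tg)]]) return(NA)
            k <- which(en$t[tg] > to)[1L]
            if (en$t[tg[k - 1L]] == to) return(NA)
            if (en$link_ok(tg[k - 1L], o) && en$link_ok(o, tg[k])) k else NA
          }
          targets <- Filter(function(j) j != src &&
                              !is.na(slot_of(tracks[[j]])), seq_len(K))
          if (!length(targets)) {
            emit_id(1 / (K * (len - 2L)))
          } else for (j in targets) {
            k <- slot_of(tracks[[j]])
            tg <- tracks[[j]]
            tr2 <- tracks
            tr2[[src]] <- tr[-pos]
            tr2[[j]] <- append(tg, o, after = k - 1L)
            emit(tr2, clutter, 1 / (K * (len - 2L) * length(targets)))
          }
        }
      }
    },
    cross_over = {
      if (K < 2L) emit_id(1)
      else {
        npair <- K * (K - 1) / 2
        for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
          A <- tracks[[i]]; B <- tracks[[j]]
          cuts <- list()
          for (a in seq_len(length(A) - 1L))
            for (b in seq_len(length(B) - 1L)) {
              lo <- max(en$t[A[a]], en$t[B[b]])
              hi <- min(en$t[A[a + 1L]], en$t[B[b + 1L]])
              if (lo >= hi) next
              if (en$link_ok(A[a], B[b + 1L]) && en$link_ok(B[b], A[a + 1L]))
                cuts[[length(cuts) + 1L]] <- c(a, b)
            }
          if (!length(cuts)) {
            emit_id(1 / npair)
          } else for (cut in cuts) {
            a <- cut[1L]; b <- cut[2L]
            n1 <- c(A[seq_len(a)], B[(b + 1L):length(B)])
            n2 <- c(B[seq_len(b)], A[(a + 1L):length(A)])
            tr2 <- c(tracks[-c(i, j)], list(n1, n2))
            emit(tr2, clutter, 1 / (npair * length(cuts)))
          }
        }
      }
    }
  )
  list(leaves = leaves, identity_mass = identity_mass)
}

#' Exact proposal mass between two partitions under one move type
#'
#' Sums the probabilities of every sampling-tree path of `move` that turns
#' `from` into `to`, by exhaustive enumeration (toy-scale partitions).
#' Includes the uniform 1/9 move-type factor so the value is comparable to
#' the `log_q_fwd` reported by [propose()].
#'
#' @param from,to `spt_partition` objects.
#' @param move move-type name.
#' @param obs an `spt_observations` object.
#' @param cfg a [sampler_config()].
#' @return Log proposal mass; `-Inf` if `to` is unreachable from `from`
#'   by this move type.
#' @export
q_mass <- function(from, to, move, obs, cfg = sampler_config()) {
  en <- enumerate_proposals(from, obs, move, cfg)
  key <- .part_key(to, obs)
  p <- 0
  for (leaf in en$leaves)
    if (.part_key(leaf$partition, obs) == key) p <- p + leaf$prob
  log(p / 9)
}
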