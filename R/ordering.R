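#' Ordering configuration for the cluster timeline
#'
#' @param block_size Timesteps per optimization block; the sweep runs
#'   within consecutive, non-overlapping blocks of this many timesteps
#'   (a short final block is allowed).
#' @param n_sweeps Number of forward+backward passes per block.
#' @return An `ordering_config` list.
#' @export
ordering_config <- function(block_size = 10L, n_sweeps = 4L) {
  block_size <- as.integer(block_size); n_sweeps <- as.integer(n_sweeps)
  if (block_size < 1L) abort("`block_size` must be >= 1.")
  if (n_sweeps < 1L) abort("`n_sweeps` must be >= 1.")
  structure(list(block_size = block_size, n_sweeps = n_sweeps),
            class = "ordering_config")
}

# Sizes of the blocks at timestep t, in index order.
sizes_at <- function(dcs, t) {
  b <- dcs$blocks[dcs$blocks$t == t, ]
  b$size[order(b$index)]
}

# Vertical centers for blocks in index order, given a top-to-bottom
# permutation `ord` of 0-based indices; unit height per electrode,
# gapless stacking.
centers_for <- function(sizes, ord) {
  h <- sizes[ord + 1L]
  tops <- cumsum(c(0, head(h, -1)))
  centers <- tops + h / 2
  centers[order(ord)]  # centers[i] = center of block index i-1
}

#' Weighted link-distance objective of a timeline ordering
#'
#' Sum over all transition links of `count * |source center - sink
#' center|`, with block vertical centers implied by the per-timestep
#' orderings (unit height per electrode, gapless stacking).
#'
#' @param dcs A `dyncomm_set` (see [track_communities()]).
#' @param ordering A `timeline_ordering` from [barycenter_order()], or a
#'   list of 0-based permutations (top-to-bottom block indices), one per
#'   timestep.
#' @return A non-negative scalar.
#' @export
link_distance_objective <- function(dcs, ordering) {
  ords <- if (inherits(ordering, "timeline_ordering")) ordering$order else ordering
  ts <- sort(unique(dcs$blocks$t))
  centers <- lapply(seq_along(ts), function(k) {
    centers_for(sizes_at(dcs, ts[k]), ords[[k]])
  })
  names(centers) <- as.character(ts)
  if (nrow(dcs$links) == 0) return(0)
  total <- 0
  for (k in seq_along(ts)[-length(ts)]) {
    lk <- dcs$links[dcs$links$t == ts[k], ]
    if (nrow(lk) == 0) next
    c0 <- centers[[k]]; c1 <- centers[[k + 1]]
    total <- total + sum(lk$count * abs(c0[lk$source + 1L] - c1[lk$sink + 1L]))
  }
  total
}

# All permutations of 0..(n-1), lexicographic order.
all_permutations <- function(n) {
  if (n == 1) return(list(0L))
  unlist(lapply(seq_len(n) - 1L, function(first) {
    lapply(all_permutations(n - 1L), function(p) {
      rest <- setdiff(seq_len(n) - 1L, first)
      c(first, rest[p + 1L])
    })
  }), recursive = FALSE)
}

# Crossing count of an ordering (reported for diagnostics): pairs of
# links between the same two timesteps whose endpoints are oppositely
# ordered.
count_crossings <- function(dcs, ordering) {
  ords <- if (inherits(ordering, "timeline_ordering")) ordering$order else ordering
  ts <- sort(unique(dcs$blocks$t))
  pos <- lapply(seq_along(ts), function(k) order(ords[[k]]))  # index -> rank
  total <- 0L
  for (k in seq_along(ts)[-length(ts)]) {
    lk <- dcs$links[dcs$links$t == ts[k], ]
    if (nrow(lk) < 2) next
    ps <- pos[[k]][lk$source + 1L]; pk <- pos[[k + 1]][lk$sink + 1L]
    for (a in seq_len(nrow(lk) - 1L)) {
      for (b in (a + 1L):nrow(lk)) {
        if ((ps[a] - ps[b]) * (pk[a] - pk[b]) < 0) total <- total + 1L
      }
    }
  }
  total
}

#' Order cluster blocks per timestep by barycenter sweeps
#'
#' Starts from a descending-size order at every timestep, then sweeps
#' forward and backward within consecutive blocks of
#' `cfg$block_size` timesteps. Each visit reorders one timestep's
#' clusters: candidates are the count-weighted barycenter order of the
#' linked neighbors' current vertical centers (ties: larger cluster
#' first, then smaller index) and, when the timestep has at most five
#' clusters, every permutation (exact one-layer refinement). A candidate
#' is kept only if it strictly reduces that timestep's link-distance
#' contribution, so the global objective is non-increasing across
#' sweeps and the procedure is deterministic.
#'
#' @param dcs A `dyncomm_set`.
#' @param cfg An [ordering_config()].
#' @return A `timeline_ordering`: list with `order` (per timestep, the
#'   0-based block indices top-to-bottom), `offsets` (per timestep, the
#'   top offset of each block in index order, unit height per
#'   electrode), `objective`, `crossings`, and `timesteps`.
#' @export
barycenter_order <- function(dcs, cfg = ordering_config()) {
  ts <- sort(unique(dcs$blocks$t))
  sizes <- lapply(ts, function(t) sizes_at(dcs, t))
  # initial order: descending size, ties by smaller index
  ords <- lapply(sizes, function(s) order(-s, seq_along(s)) - 1L)

  links_fwd <- lapply(seq_along(ts), function(k) {
    if (k == 1) NULL else dcs$links[dcs$links$t == ts[k - 1], ]
  })

  # objective contribution of timestep k's ordering: links to both
  # neighbors only (everything else is unchanged by reordering k)
  local_obj <- function(k, ord_k) {
    ctr <- centers_for(sizes[[k]], ord_k)
    total <- 0
    lk <- links_fwd[[k]]
    if (!is.null(lk) && nrow(lk) > 0) {
      prev <- centers_for(sizes[[k - 1L]], ords[[k - 1L]])
      total <- total + sum(lk$count * abs(prev[lk$source + 1L] - ctr[lk$sink + 1L]))
    }
    if (k < length(ts)) {
      ln <- links_fwd[[k + 1L]]
      if (!is.null(ln) && nrow(ln) > 0) {
        nxt <- centers_for(sizes[[k + 1L]], ords[[k + 1L]])
        total <- total + sum(ln$count * abs(ctr[ln$source + 1L] - nxt[ln$sink + 1L]))
      }
    }
    total
  }

  # one visit: candidate orders for timestep k are the count-weighted
  # barycenter proposal wrt the given neighbor plus, for small cluster
  # counts, every permutation (exact one-layer refinement). The best
  # strictly-improving candidate under the local objective is kept, so
  # the global objective never increases.
  visit <- function(k, neighbor, lk, src_col, snk_col) {
    s <- sizes[[k]]
    if (length(s) < 2) return(invisible())
    cands <- list()
    if (!is.null(lk) && nrow(lk) > 0) {
      ctr_nb <- centers_for(sizes[[neighbor]], ords[[neighbor]])
      ctr_here <- centers_for(s, ords[[k]])
      bary <- vapply(seq_along(s) - 1L, function(i) {
        rows <- lk[lk[[src_col]] == i, ]
        if (nrow(rows) == 0) return(ctr_here[i + 1L])
        sum(rows$count * ctr_nb[rows[[snk_col]] + 1L]) / sum(rows$count)
      }, numeric(1))
      cands <- list(order(bary, -s, seq_along(s)) - 1L)
    }
    if (length(s) <= 5) cands <- c(cands, all_permutations(length(s)))
    cur <- local_obj(k, ords[[k]])
    for (cand in cands) {
      val <- local_obj(k, cand)
      if (val < cur - 1e-12) {
        cur <- val
        ords[[k]] <<- cand
      }
    }
    invisible()
  }

  starts <- seq(1L, length(ts), by = cfg$block_size)
  for (sweep in seq_len(cfg$n_sweeps)) {
    for (bs in starts) {
      be <- min(bs + cfg$block_size - 1L, length(ts))
      if (be > bs) {
        for (k in (bs + 1L):be) {          # forward: align to t-1
          visit(k, k - 1L, links_fwd[[k]], "sink", "source")
        }
        for (k in (be - 1L):bs) {          # backward: align to t+1
          visit(k, k + 1L, links_fwd[[k + 1L]], "source", "sink")
        }
      }
    }
  }
  obj <- link_distance_objective(dcs, ords)

  offsets <- lapply(seq_along(ts), function(k) {
    h <- sizes[[k]][ords[[k]] + 1L]
    tops <- cumsum(c(0, head(h, -1)))
    tops[order(ords[[k]])]
  })
  structure(list(order = ords, offsets = offsets, timesteps = ts,
                 objective = obj,
                 crossings = count_crossings(dcs, ords)),
            class = "timeline_ordering")
}

#' @export
print.timeline_ordering <- function(x, ...) {
  cat(sprintf("<timeline_ordering> %d timesteps, objective=%.3f, crossings=%d\n",
              length(x$order), x$objective, x$crossings))
  invisible(x)
}

#' @method tidy timeline_ordering
#' @export
tidy.timeline_ordering <- function(x, ...) {
  bind_rows(lapply(seq_along(x$timesteps), function(k) {
    ord <- x$order[[k]]
    tibble(t = x$timesteps[k],
           index = seq_along(ord) - 1L,
           position = order(ord) - 1L,
           y0 = x$offsets[[k]])
  }))
}
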