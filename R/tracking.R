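#' Jaccard similarity of two node sets
#'
#' `|A ∩ B| / |A ∪ B|`, computed as an exact count ratio.
#'
#' @param a,b Non-empty vectors of node ids.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("Jaccard of an empty set is undefined.")
  a <- unique(a); b <- unique(b)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

# Partitions are lists of non-empty member vectors, indexed 0-based by
# position. Accepts a labels vector (named, 0-based labels) or a list.
as_partition <- function(p) {
  if (is.list(p)) {
    if (any(lengths(p) == 0)) abort("Partition blocks must be non-empty.")
    return(lapply(p, as.character))
  }
  if (is.null(names(p))) abort("Label vectors must be named by node id.")
  split(names(p), factor(p, levels = sort(unique(p))))
}

# Overlap-count matrix between two partitions (sources x sinks).
overlap_counts <- function(p_t, p_t1) {
  outer(seq_along(p_t), seq_along(p_t1),
        Vectorize(function(i, j) length(intersect(p_t[[i]], p_t1[[j]]))))
}

# Jaccard similarity matrix between two partitions.
similarity_matrix <- function(p_t, p_t1) {
  outer(seq_along(p_t), seq_along(p_t1),
        Vectorize(function(i, j) jaccard(p_t[[i]], p_t1[[j]])))
}

new_matching <- function(pairs, n_src, n_snk, method) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) {
    pairs <- tibble(source = integer(), sink = integer(), value = double())
  }
  structure(list(pairs = pairs,
                 unmatched_sources = setdiff(seq_len(n_src) - 1L, pairs$source),
                 unmatched_sinks = setdiff(seq_len(n_snk) - 1L, pairs$sink),
                 method = method),
            class = "cluster_matching")
}

#' @export
print.cluster_matching <- function(x, ...) {
  cat(sprintf("<cluster_matching> %s: %d pair(s), %d unmatched source(s), %d unmatched sink(s)\n",
              x$method, nrow(x$pairs), length(x$unmatched_sources),
              length(x$unmatched_sinks)))
  invisible(x)
}

#' Greedy maximum-overlap assignment on an overlap-count matrix
#'
#' Iteratively selects the unmatched (source, sink) pair sharing the
#' maximum number of electrodes, removes both, and repeats until no
#' remaining pair overlaps. Ties break row-major: smaller source index,
#' then smaller sink index. Pairs are returned in selection order.
#'
#' @param counts Non-negative matrix of overlap counts, sources x sinks
#'   (0-based indices correspond to rows/columns).
#' @return A `cluster_matching` whose `pairs` tibble has columns
#'   `source`, `sink`, `value` (the overlap count), in selection order.
#' @export
greedy_assignment <- function(counts) {
  counts <- as.matrix(counts)
  m <- counts
  pairs <- list()
  while (length(m) > 0 && max(m) >= 1) {
    hit <- which(m == max(m), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    pairs[[length(pairs) + 1L]] <- tibble(source = hit[[1]] - 1L,
                                          sink = hit[[2]] - 1L,
                                          value = m[hit[[1]], hit[[2]]])
    m[hit[[1]], ] <- -1
    m[, hit[[2]]] <- -1
  }
  new_matching(bind_rows(pairs), nrow(counts), ncol(counts), "greedy")
}

#' Greedy maximum-overlap matching between two partitions
#'
#' @param p_t,p_t1 Partitions at consecutive timesteps: either lists of
#'   member-id vectors or named 0-based label vectors.
#' @return A `cluster_matching` (see [greedy_assignment()]).
#' @export
greedy_match <- function(p_t, p_t1) {
  p_t <- as_partition(p_t); p_t1 <- as_partition(p_t1)
  greedy_assignment(overlap_counts(p_t, p_t1))
}

#' Globally optimal assignment on a similarity matrix
#'
#' Entries below `theta` are zeroed; over all injective partial
#' assignments of sources to sinks, returns the one maximizing the sum of
#' similarities. Zero-similarity pairings are left unmatched. Ties break
#' toward the lexicographically smallest pair list. The search is exact:
#' a depth-first enumeration over rows with an admissible bound (sum of
#' remaining row maxima) used for pruning.
#'
#' @param sim Non-negative similarity matrix, sources x sinks.
#' @param theta Similarity threshold; entries `< theta` cannot match.
#' @param method `"enumerate"` guards the enumerative path to at most 10
#'   clusters on the smaller side and errors beyond, advising
#'   `"solver"`; `"solver"` runs the same exact bounded search without
#'   the size guard.
#' @return A `cluster_matching` whose `pairs` tibble has columns
#'   `source`, `sink`, `value` (thresholded similarity), sorted by
#'   source, plus an `objective` element.
#' @export
optimal_assignment <- function(sim, theta = 0,
                               method = c("enumerate", "solver")) {
  method <- match.arg(method)
  sim <- as.matrix(sim)
  if (method == "enumerate" && min(dim(sim)) > 10) {
    abort(paste("More than 10 clusters on the smaller side; enumeration is",
                "guarded at 10. Use method = \"solver\" for the exact",
                "branch-and-bound search without the size guard."))
  }
  s <- sim
  s[s < theta] <- 0
  # orient so rows are the smaller side; remember orientation
  flipped <- nrow(s) > ncol(s)
  if (flipped) s <- t(s)
  nr <- nrow(s); nc <- ncol(s)
  row_max <- apply(s, 1, max)
  suffix_bound <- rev(cumsum(rev(row_max)))
  best <- list(obj = -1, pairs = NULL)
  assign_cols <- integer(nr)  # 0 = unmatched

  better_pairs <- function(a, b) {
    # TRUE if pair list a < b lexicographically ((source,sink) ascending)
    la <- nrow(a); lb <- nrow(b)
    for (i in seq_len(min(la, lb))) {
      if (a$source[i] != b$source[i]) return(a$source[i] < b$source[i])
      if (a$sink[i] != b$sink[i]) return(a$sink[i] < b$sink[i])
    }
    la < lb
  }
  pairs_of <- function(cols) {
    keep <- which(cols > 0L)
    tibble(source = keep - 1L, sink = cols[keep] - 1L,
           value = s[cbind(keep, cols[keep])])
  }
  used <- rep(FALSE, nc)
  recurse <- function(row, acc) {
    if (row > nr) {
      if (acc > best$obj + 1e-12) {
        best <<- list(obj = acc, pairs = pairs_of(assign_cols))
      } else if (abs(acc - best$obj) <= 1e-12) {
        cand <- pairs_of(assign_cols)
        if (better_pairs(cand, best$pairs)) best$pairs <<- cand
      }
      return(invisible())
    }
    if (acc + suffix_bound[row] < best$obj - 1e-12) return(invisible())
    for (col in seq_len(nc)) {
      if (!used[col] && s[row, col] > 0) {
        used[col] <<- TRUE
        assign_cols[row] <<- col
        recurse(row + 1L, acc + s[row, col])
        used[col] <<- FALSE
        assign_cols[row] <<- 0L
      }
    }
    recurse(row + 1L, acc)  # leave this row unmatched
  }
  recurse(1L, 0)
  pairs <- best$pairs
  if (flipped) {
    pairs <- tibble(source = pairs$sink, sink = pairs$source,
                    value = pairs$value)
    pairs <- arrange(pairs, .data$source, .data$sink)
  }
  out <- new_matching(pairs, nrow(sim), ncol(sim), "optimal")
  out$objective <- best$obj
  out$theta <- theta
  out
}

#' Globally optimal Jaccard matching between two partitions
#'
#' @inheritParams greedy_match
#' @param theta Jaccard threshold below which pairs cannot match
#'   (default 0.1).
#' @inheritParams optimal_assignment
#' @return A `cluster_matching` (see [optimal_assignment()]).
#' @export
optimal_match <- function(p_t, p_t1, theta = 0.1,
                          method = c("enumerate", "solver")) {
  p_t <- as_partition(p_t); p_t1 <- as_partition(p_t1)
  optimal_assignment(similarity_matrix(p_t, p_t1), theta, method)
}

#' Objective value of a matching under a similarity matrix
#'
#' Sum of thresholded similarities over the matched pairs; the common
#' scale on which greedy and optimal matchings are compared.
#'
#' @param matching A `cluster_matching`.
#' @param sim Similarity matrix, sources x sinks.
#' @param theta Threshold applied to `sim` before summing.
#' @return A non-negative scalar.
#' @export
matching_objective <- function(matching, sim, theta = 0) {
  s <- as.matrix(sim)
  s[s < theta] <- 0
  if (nrow(matching$pairs) == 0) return(0)
  sum(s[cbind(matching$pairs$source + 1L, matching$pairs$sink + 1L)])
}

#' Transition links between two consecutive partitions
#'
#' One link per (source, sink) pair sharing at least one electrode, with
#' the shared electrode count and Jaccard similarity. Link counts are
#' conservative: they sum to the source block size over sinks and to the
#' sink block size over sources.
#'
#' @inheritParams greedy_match
#' @return A tibble with columns `source`, `sink` (0-based block
#'   indices), `count` and `similarity`.
#' @export
transition_links <- function(p_t, p_t1) {
  p_t <- as_partition(p_t); p_t1 <- as_partition(p_t1)
  counts <- overlap_counts(p_t, p_t1)
  idx <- which(counts >= 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble(
    source = idx[, 1] - 1L,
    sink = idx[, 2] - 1L,
    count = counts[idx],
    similarity = vapply(seq_len(nrow(idx)), function(r) {
      jaccard(p_t[[idx[r, 1]]], p_t1[[idx[r, 2]]])
    }, numeric(1))
  )
}

#' Track communities across timesteps
#'
#' Matches clusters in consecutive timesteps (greedy maximum-overlap or
#' globally optimal Jaccard matching) and threads them into dynamic
#' communities with persistent identifiers: a matched sink inherits its
#' source's id; an unmatched sink starts a new community (birth); an
#' unmatched source's community ends (death). Ids are allocated in order
#' of first appearance. For the optimal method, pairs with Jaccard below
#' `theta` never match.
#'
#' @param clusterings A `timestep_clusterings` (or list of
#'   `timestep_clustering`, or list of named 0-based label vectors), one
#'   per timestep in time order.
#' @param method `"optimal"` (Jaccard, globally optimal) or `"greedy"`
#'   (raw overlap counts).
#' @param theta Jaccard threshold for the optimal method.
#' @param palette Qualitative RColorBrewer palette for community colors.
#' @return A `dyncomm_set`: list with `blocks` (tibble: t, index,
#'   persistent_id, size, members list-column), `links` (tibble: t,
#'   source, sink, count, similarity, source_id, sink_id), `colors`
#'   (named vector persistent_id -> hex), `profiles` (K-likelihood
#'   profiles if available), `node_ids`, `method`, `theta`.
#' @export
track_communities <- function(clusterings, method = c("optimal", "greedy"),
                              theta = 0.1, palette = "Set1") {
  method <- match.arg(method)
  if (length(clusterings) < 1) abort("Need at least one timestep.")
  is_cl <- vapply(clusterings, inherits, logical(1), "timestep_clustering")
  parts <- lapply(clusterings, function(cl) {
    as_partition(if (inherits(cl, "timestep_clustering")) cl$labels else cl)
  })
  ts <- if (all(is_cl)) {
    vapply(clusterings, function(cl) cl$t, integer(1))
  } else {
    seq_along(parts) - 1L
  }
  node_ids <- sort(unique(unlist(parts[[1]])))

  next_id <- 0L
  fresh_id <- function() {
    next_id <<- next_id + 1L
    sprintf("dc%d", next_id)
  }
  ids <- vector("list", length(parts))
  ids[[1]] <- vapply(seq_along(parts[[1]]), function(i) fresh_id(), character(1))

  blocks <- list(tibble(t = ts[1], index = seq_along(parts[[1]]) - 1L,
                        persistent_id = ids[[1]],
                        size = lengths(parts[[1]]),
                        members = unname(parts[[1]])))
  links <- list()
  for (k in seq_along(parts)[-1]) {
    p0 <- parts[[k - 1]]; p1 <- parts[[k]]
    m <- switch(method,
                greedy = greedy_match(p0, p1),
                optimal = optimal_match(p0, p1, theta = theta))
    lk <- transition_links(p0, p1)
    id1 <- character(length(p1))
    for (r in seq_len(nrow(m$pairs))) {
      id1[m$pairs$sink[r] + 1L] <- ids[[k - 1]][m$pairs$source[r] + 1L]
    }
    for (j in seq_along(id1)) if (id1[j] == "") id1[j] <- fresh_id()
    ids[[k]] <- id1
    lk$source_id <- ids[[k - 1]][lk$source + 1L]
    lk$sink_id <- id1[lk$sink + 1L]
    links[[k - 1]] <- mutate(lk, t = ts[k - 1], .before = 1)
    blocks[[k]] <- tibble(t = ts[k], index = seq_along(p1) - 1L,
                          persistent_id = id1, size = lengths(p1),
                          members = unname(p1))
  }
  dcs <- structure(
    list(blocks = bind_rows(blocks),
         links = if (length(links)) bind_rows(links) else
           tibble(t = integer(), source = integer(), sink = integer(),
                  count = integer(), similarity = double(),
                  source_id = character(), sink_id = character()),
         colors = NULL,
         profiles = if (all(is_cl)) k_profiles(clusterings),
         node_ids = node_ids, method = method, theta = theta),
    class = "dyncomm_set")
  dcs$colors <- assign_colors(dcs, palette)
  dcs
}

#' @export
print.dyncomm_set <- function(x, ...) {
  cat(sprintf("<dyncomm_set> %d timesteps, %d dynamic communities, method=%s, theta=%g\n",
              length(unique(x$blocks$t)), length(unique(x$blocks$persistent_id)),
              x$method, x$theta))
  invisible(x)
}

#' Assign qualitative colors to dynamic communities
#'
#' Persistent ids are colored in order of first appearance from a
#' qualitative ColorBrewer palette; an id keeps one color for its whole
#' lifetime. Beyond the palette size colors recycle (with a warning).
#'
#' @param dcs A `dyncomm_set`.
#' @param palette A qualitative RColorBrewer palette name (e.g. `"Set1"`,
#'   `"Dark2"`, `"Paired"`).
#' @return Named character vector persistent_id -> hex color.
#' @export
assign_colors <- function(dcs, palette = "Set1") {
  qual <- RColorBrewer::brewer.pal.info
  qual <- rownames(qual)[qual$category == "qual"]
  if (!palette %in% qual) {
    abort(sprintf("Unknown qualitative palette '%s'. Available: %s",
                  palette, paste(qual, collapse = ", ")))
  }
  ids <- unique(dcs$blocks$persistent_id[order(dcs$blocks$t, dcs$blocks$index)])
  size <- RColorBrewer::brewer.pal.info[palette, "maxcolors"]
  cols <- RColorBrewer::brewer.pal(size, palette)
  if (length(ids) > size) {
    warn(sprintf("%d dynamic communities exceed palette size %d; colors recycle.",
                 length(ids), size))
  }
  stats::setNames(cols[(seq_along(ids) - 1L) %% size + 1L], ids)
}

#' @method tidy dyncomm_set
#' @export
tidy.dyncomm_set <- function(x, ...) {
  dplyr::select(x$blocks, -"members")
}

#' @method glance dyncomm_set
#' @export
glance.dyncomm_set <- function(x, ...) {
  births <- x$blocks |>
    group_by(.data$persistent_id) |>
    summarise(first = min(.data$t)) |>
    filter(.data$first > min(x$blocks$t))
  tibble(n_timesteps = length(unique(x$blocks$t)),
         n_communities = length(unique(x$blocks$persistent_id)),
         n_births = nrow(births),
         method = x$method, theta = x$theta)
}

# Partition (list of member vectors, index order) of a dyncomm_set at t.
partition_at <- function(dcs, t) {
  b <- dcs$blocks[dcs$blocks$t == t, ]
  b <- b[order(b$index), ]
  b$members
}
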