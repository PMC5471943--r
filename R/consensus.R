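#' Consensus clustering parameters
#'
#' @param k_min,k_max Inclusive candidate range for the number of
#'   communities K; `k_min >= 2`.
#' @param n_runs Number of subsampled k-means runs per candidate K.
#' @param n_starts Random restarts per k-means run; restarts guard the
#'   base clusterer against poor local optima so that consensus
#'   ambiguity reflects the data, not the initialisation.
#' @param subsample_fraction Fraction of nodes drawn (without replacement)
#'   per run, in `(0, 1]`.
#' @param seed RNG seed; clustering is bit-reproducible for a fixed seed.
#' @param identity_epsilon Tolerance for the degenerate all-ones consensus
#'   test: if every consensus entry is within this of 1 for every K, the
#'   nodes are indistinguishable and a single community (K = 1) is reported
#'   with a flat zero likelihood profile.
#' @param pac_lower,pac_upper Consensus-value interval whose CDF mass
#'   defines the proportion of ambiguous clustering (PAC); co-clustering
#'   frequencies inside `(pac_lower, pac_upper]` count as ambiguous.
#' @param keep_consensus Retain the consensus matrices on the result.
#' @return A `consensus_params` list.
#' @export
consensus_params <- function(k_min = 2L, k_max = 8L, n_runs = 50L,
                             n_starts = 3L,
                             subsample_fraction = 0.8, seed = 1L,
                             identity_epsilon = 1e-6,
                             pac_lower = 0.1, pac_upper = 0.9,
                             keep_consensus = FALSE) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 2L) abort("`k_min` must be >= 2.")
  if (k_max < k_min) abort("`k_max` must be >= `k_min`.")
  if (n_runs < 1L) abort("`n_runs` must be >= 1.")
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    abort("`subsample_fraction` must be in (0, 1].")
  }
  if (n_starts < 1L) abort("`n_starts` must be >= 1.")
  structure(list(k_min = k_min, k_max = k_max, n_runs = as.integer(n_runs),
                 n_starts = as.integer(n_starts),
                 subsample_fraction = subsample_fraction,
                 seed = as.integer(seed),
                 identity_epsilon = identity_epsilon,
                 pac_lower = pac_lower, pac_upper = pac_upper,
                 keep_consensus = keep_consensus),
            class = "consensus_params")
}

#' Consensus matrix from repeated subsampled k-means runs
#'
#' Runs k-means `n_runs` times on row-subsamples of the feature matrix and
#' records, for every node pair, the fraction of runs in which both nodes
#' were sampled and assigned to the same cluster:
#' `M(i,j) = #co-clustered / #co-sampled`. Pairs never co-sampled get 0
#' (with a warning). The diagonal is 1 and M is symmetric by construction.
#'
#' @param features Numeric matrix with one row per node; for network
#'   clustering these are the rows of the timestep's adjacency matrix
#'   (connectivity profiles).
#' @param k Number of k-means centers; at most the number of nodes.
#' @param params A [consensus_params()]. The RNG state is taken as-is:
#'   callers seed once per timestep (see [cluster_timestep()]).
#' @param .seeded Internal; set to FALSE when the caller already manages
#'   the RNG state.
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal.
#' @export
consensus_matrix <- function(features, k, params = consensus_params(),
                             .seeded = FALSE) {
  n <- nrow(features)
  if (k > n) abort("`k` cannot exceed the number of nodes.")
  run <- function() {
    m <- max(2L, as.integer(floor(params$subsample_fraction * n)))
    hits <- matrix(0, n, n)
    draws <- matrix(0, n, n)
    for (h in seq_len(params$n_runs)) {
      idx <- sort(sample.int(n, m))
      kk <- min(k, m)
      km <- kmeans_labels(features[idx, , drop = FALSE], kk, params$n_starts)
      ind <- outer(km, km, "==") * 1
      hits[idx, idx] <- hits[idx, idx] + ind
      draws[idx, idx] <- draws[idx, idx] + 1
    }
    never <- draws == 0
    if (any(never[upper.tri(never)])) {
      warn("Some node pairs were never co-sampled; their consensus is 0. Increase n_runs or subsample_fraction.")
    }
    M <- ifelse(draws > 0, hits / pmax(draws, 1), 0)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    M
  }
  if (.seeded) run() else withr::with_seed(params$seed, run())
}

# k-means labels robust to duplicated rows (fewer distinct points than
# centers): falls back to clustering the distinct rows.
kmeans_labels <- function(x, k, nstart = 1L) {
  distinct <- unique(x)
  if (nrow(distinct) <= k) {
    key <- apply(x, 1, paste, collapse = "\r")
    return(as.integer(factor(key, levels = unique(key))))
  }
  kmeans(x, centers = k, iter.max = 30L, nstart = nstart)$cluster
}

# Area under the empirical CDF of the off-diagonal consensus entries
# (Monti et al. consensus criterion).
consensus_cdf_area <- function(M) {
  x <- M[lower.tri(M)]
  xs <- sort(unique(c(0, x, 1)))
  cdf <- ecdf(x)
  sum(diff(xs) * cdf(head(xs, -1)))
}

consensus_pac <- function(M, lower, upper) {
  x <- M[lower.tri(M)]
  mean(x <= upper) - mean(x <= lower)
}

#' K-likelihood profile and selection of the number of communities
#'
#' Computes, for each candidate K, the CDF of the off-diagonal consensus
#' entries, its area `A(K)` and the Monti relative change
#' `delta(K) = (A(K) - A(K-1)) / A(K-1)` (with `delta(k_min) = A(k_min)`),
#' plus the proportion of ambiguous clustering `PAC(K)`: the CDF mass of
#' consensus values strictly between the crisp extremes. The reported
#' likelihood is `1 - PAC` min-max rescaled to `[0, 1]` across the
#' candidate range, and the selected K is its argmax (ties toward smaller
#' K).
#'
#' Degenerate rule: when every consensus entry is within
#' `identity_epsilon` of 1 for every candidate K, the nodes are never
#' separated and no candidate carries information; all likelihoods are 0
#' and the selected K is 1.
#'
#' @param consensus_by_k Named list of consensus matrices, one per
#'   candidate K (names are the K values).
#' @param params A [consensus_params()].
#' @return A list with `profile` (tibble: k, area, delta, pac, likelihood),
#'   `k` (selected K) and `degenerate` (logical).
#' @export
k_likelihood_profile <- function(consensus_by_k, params = consensus_params()) {
  if (length(consensus_by_k) == 0) abort("Empty candidate K range.")
  ks <- as.integer(names(consensus_by_k))
  area <- map_dbl(consensus_by_k, consensus_cdf_area)
  delta <- numeric(length(ks))
  delta[1] <- area[1]
  if (length(ks) > 1) {
    delta[-1] <- diff(area) / head(area, -1)
  }
  pac <- map_dbl(consensus_by_k, consensus_pac,
                 lower = params$pac_lower, upper = params$pac_upper)
  degenerate <- all(map_dbl(consensus_by_k, function(M) {
    max(abs(M[lower.tri(M)] - 1))
  }) <= params$identity_epsilon)
  if (degenerate) {
    likelihood <- rep(0, length(ks))
    k_sel <- 1L
  } else {
    conf <- 1 - pac
    spread <- max(conf) - min(conf)
    likelihood <- if (spread > 0) (conf - min(conf)) / spread else rep(1, length(ks))
    k_sel <- ks[which.max(likelihood)]
  }
  list(profile = tibble(k = ks, area = unname(area), delta = unname(delta),
                        pac = unname(pac), likelihood = likelihood),
       k = k_sel, degenerate = degenerate)
}

#' Cluster one timestep of a dynamic network
#'
#' Features are the rows of the timestep's adjacency matrix (each node's
#' connectivity profile). For each candidate K a consensus matrix is
#' built; [k_likelihood_profile()] selects K; final labels come from
#' average-linkage hierarchical clustering of the distance `1 - M_K` cut
#' at K (K = 1 gives a single community). Labels are 0-based and
#' canonical: communities ordered by decreasing size, ties by smallest
#' member index.
#'
#' @param net A [dynamic_network()].
#' @param t 0-based timestep index.
#' @param params A [consensus_params()]. The effective seed is
#'   `params$seed + t`, so timesteps are independent and the whole run is
#'   reproducible.
#' @return A `timestep_clustering`: list with `t`, `labels` (named integer
#'   vector), `k`, `profile`, `degenerate`, and optionally `consensus`.
#' @export
cluster_timestep <- function(net, t, params = consensus_params()) {
  stopifnot(inherits(net, "dynamic_network"))
  if (t < 0 || t >= n_timesteps(net)) abort("Timestep out of range.")
  features <- net$adjacency[[t + 1L]]
  n <- nrow(features)
  # connectivity-profile features: the self-edge carries no information,
  # so replace the structural zero with the node's mean connectivity.
  # This keeps truly indistinguishable nodes (uniform complete graph)
  # bit-identical, which the degenerate K = 1 rule relies on.
  diag(features) <- rowSums(features) / max(n - 1L, 1L)
  ks <- seq.int(params$k_min, min(params$k_max, n))
  if (length(ks) == 0) abort("No candidate K fits the node count.")
  consensus_by_k <- withr::with_seed(params$seed + t, {
    res <- lapply(ks, function(k) consensus_matrix(features, k, params, .seeded = TRUE))
    names(res) <- ks
    res
  })
  sel <- k_likelihood_profile(consensus_by_k, params)
  labels <- if (sel$k == 1L) {
    rep(0L, n)
  } else {
    M <- consensus_by_k[[as.character(sel$k)]]
    hc <- hclust(as.dist(1 - M), method = "average")
    canonical_labels(cutree(hc, k = sel$k))
  }
  names(labels) <- net$node_ids
  structure(list(t = as.integer(t), labels = labels, k = length(unique(labels)),
                 profile = sel$profile, degenerate = sel$degenerate,
                 consensus = if (params$keep_consensus) consensus_by_k),
            class = "timestep_clustering")
}

# Relabel to 0-based canonical order: by decreasing community size,
# ties by smallest member index.
canonical_labels <- function(labels) {
  labels <- as.integer(labels)
  sizes <- tabulate(labels)
  firsts <- vapply(seq_along(sizes), function(l) match(l, labels), integer(1))
  ord <- order(-sizes, firsts)
  new <- integer(length(sizes))
  new[ord] <- seq_along(ord) - 1L
  new[labels]
}

#' Cluster every timestep of a dynamic network
#'
#' @inheritParams cluster_timestep
#' @param timesteps 0-based timesteps to cluster (default: all).
#' @return A `timestep_clusterings` list of [cluster_timestep()] results.
#' @export
cluster_timesteps <- function(net, params = consensus_params(),
                              timesteps = NULL) {
  timesteps <- timesteps %||% (seq_len(n_timesteps(net)) - 1L)
  res <- lapply(timesteps, function(t) cluster_timestep(net, t, params))
  structure(res, class = "timestep_clusterings")
}

#' @export
print.timestep_clustering <- function(x, ...) {
  cat(sprintf("<timestep_clustering> t=%d, K=%d%s\n", x$t, x$k,
              if (x$degenerate) " (degenerate: indistinguishable nodes)" else ""))
  invisible(x)
}

#' @method tidy timestep_clustering
#' @export
tidy.timestep_clustering <- function(x, ...) {
  tibble(t = x$t, node = names(x$labels), label = unname(x$labels))
}

#' @method glance timestep_clustering
#' @export
glance.timestep_clustering <- function(x, ...) {
  tibble(t = x$t, k = x$k, degenerate = x$degenerate,
         max_likelihood = if (x$degenerate) 0 else max(x$profile$likelihood))
}

#' @method tidy timestep_clusterings
#' @export
tidy.timestep_clusterings <- function(x, ...) {
  bind_rows(lapply(x, tidy))
}

#' @method glance timestep_clusterings
#' @export
glance.timestep_clusterings <- function(x, ...) {
  bind_rows(lapply(x, glance))
}

#' K-likelihood profiles of a set of clusterings as a tibble
#' @param clusterings A `timestep_clusterings` (or list of
#'   `timestep_clustering`).
#' @return A tibble with columns `t`, `k`, `area`, `delta`, `pac`,
#'   `likelihood`.
#' @export
k_profiles <- function(clusterings) {
  bind_rows(lapply(clusterings, function(cl) {
    mutate(cl$profile, t = cl$t, .before = 1)
  }))
}
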