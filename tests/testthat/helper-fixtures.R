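# Small in-code fixtures shared across the suite.

# Block-diagonal dynamic network: `sizes` nodes per block, high within /
# low between weights, optional noise; one timestep unless labels_by_t
# gives per-timestep label vectors.
block_network <- function(sizes = c(4, 4, 4), within = 0.9, between = 0.05,
                          noise_sd = 0, n_timesteps = 1, seed = 7,
                          labels_by_t = NULL) {
  n <- sum(sizes)
  base_labels <- rep(seq_along(sizes) - 1L, times = sizes)
  withr::with_seed(seed, {
    adjacency <- lapply(seq_len(n_timesteps), function(t) {
      lab <- if (is.null(labels_by_t)) base_labels else labels_by_t[[t]]
      m <- ifelse(outer(lab, lab, "=="), within, between)
      if (noise_sd > 0) {
        e <- matrix(rnorm(n * n, 0, noise_sd), n, n)
        m <- pmax(m + (e + t(e)) / 2, 0)
      }
      diag(m) <- 0
      m
    })
    dynamic_network(adjacency)
  })
}

# Random partition of node ids into k non-empty blocks (named 0-based
# label vector). Caller seeds.
random_partition <- function(node_ids, k) {
  n <- length(node_ids)
  repeat {
    lab <- sample.int(k, n, replace = TRUE) - 1L
    if (length(unique(lab)) == k) break
  }
  stats::setNames(canonical_relabel(lab), node_ids)
}

canonical_relabel <- function(lab) {
  as.integer(factor(lab, levels = unique(lab))) - 1L
}

# Partitions realizing the two-timestep worked example whose printed
# overlap matrix is [[11, 11], [10, 2]] (sources of sizes 22 and 12,
# sinks of sizes 21 and 13).
worked_example_partitions <- function() {
  ids <- sprintf("n%02d", 1:34)
  src <- list(ids[1:22], ids[23:34])
  snk <- list(c(ids[1:11], ids[23:32]), c(ids[12:22], ids[33:34]))
  list(p_t = src, p_t1 = snk)
}

# Tracked community set from explicit per-timestep label vectors.
tracked_from_labels <- function(labels_list, method = "greedy", theta = 0.1) {
  track_communities(labels_list, method = method, theta = theta)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

sizes_at_test <- function(dcs, t) {
  b <- dcs$blocks[dcs$blocks$t == t, ]
  b$size[order(b$index)]
}

# Named 0-based label vector -> list-of-member-sets partition.
as_partition_public <- function(labels) {
  unname(split(names(labels), labels))
}
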