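test_that("jaccard similarity is an exact count ratio", {
  expect_equal(jaccard(1:5, 1:5), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(1:15, 5:20), 11 / 20)
  expect_error(jaccard(integer(0), 1:3), "empty")
})

test_that("greedy matching reproduces the two-timestep worked example", {
  wx <- worked_example_partitions()
  counts <- matrix(c(11, 11, 10, 2), 2, 2, byrow = TRUE)
  m <- greedy_assignment(counts)
  # first iteration: overlap 11 (row-major tie-break), second: overlap 2
  expect_equal(m$pairs$value, c(11, 2))
  expect_equal(m$pairs$source, c(0L, 1L))
  expect_equal(m$pairs$sink, c(0L, 1L))
  # the same result from the explicit partitions
  m2 <- greedy_match(wx$p_t, wx$p_t1)
  expect_equal(m2$pairs, m$pairs)
})

test_that("greedy matching handles identity and single-node overlap", {
  p <- list(letters[1:3], letters[4:8])
  m <- greedy_match(p, p)
  expect_equal(m$pairs$source, m$pairs$sink)
  expect_equal(sort(m$pairs$value), sort(lengths(p)))
  m1 <- greedy_match(list(c("a", "b")), list(c("b", "z")))
  expect_equal(nrow(m1$pairs), 1L)
  expect_equal(m1$pairs$value, 1)
})

test_that("optimal matching picks the crossed pairing on the worked example", {
  counts <- matrix(c(11, 11, 10, 2), 2, 2, byrow = TRUE)
  m <- optimal_assignment(counts, theta = 0)
  expect_equal(m$objective, 21)
  expect_equal(m$pairs$source, c(0L, 1L))
  expect_equal(m$pairs$sink, c(1L, 0L))
  # greedy on the same matrix totals 13: optimal strictly improves
  expect_gt(m$objective, sum(greedy_assignment(counts)$pairs$value))
})

test_that("similarities below theta never match; all-below gives the empty matching", {
  sim <- matrix(c(0.05, 0.08, 0.09, 0.02), 2, 2)
  m <- optimal_assignment(sim, theta = 0.1)
  expect_equal(nrow(m$pairs), 0L)
  expect_equal(m$objective, 0)
  expect_setequal(m$unmatched_sources, 0:1)
  expect_setequal(m$unmatched_sinks, 0:1)
  # partial: only entries >= theta are eligible
  sim2 <- matrix(c(0.5, 0.08, 0.09, 0.4), 2, 2)
  m2 <- optimal_assignment(sim2, theta = 0.1)
  expect_true(all(m2$pairs$value >= 0.1))
})

test_that("enumeration guard directs large instances to the solver path", {
  sim <- matrix(runif(11 * 11), 11, 11)
  expect_error(optimal_assignment(sim, method = "enumerate"), "solver")
  m <- optimal_assignment(sim, method = "solver")
  expect_equal(m$objective, lap_objectives_oracle(list(sim)), tolerance = 1e-9)
})

test_that("optimal matching equals a linear-assignment solver on 200 seeded 6x6 instances", {
  mats <- withr::with_seed(99, lapply(1:200, function(i) matrix(runif(36), 6, 6)))
  ours <- vapply(mats, function(m) optimal_assignment(m)$objective, numeric(1))
  oracle <- lap_objectives_oracle(mats)
  expect_equal(ours, oracle, tolerance = 1e-9)
})

test_that("optimal matching is injective and at least as good as greedy (500 seeded instances)", {
  withr::with_seed(123, {
    for (rep in 1:500) {
      n <- 20L
      ids <- sprintf("n%02d", 1:n)
      p0 <- as_partition_public(random_partition(ids, sample(2:5, 1)))
      p1 <- as_partition_public(random_partition(ids, sample(2:5, 1)))
      sim <- outer(seq_along(p0), seq_along(p1),
                   Vectorize(function(i, j) jaccard(p0[[i]], p1[[j]])))
      g <- greedy_match(p0, p1)
      o <- optimal_match(p0, p1, theta = 0.1)
      og <- matching_objective(g, sim, theta = 0.1)
      oo <- matching_objective(o, sim, theta = 0.1)
      expect_gte(oo + 1e-12, og)
      expect_equal(anyDuplicated(o$pairs$source), 0L)
      expect_equal(anyDuplicated(o$pairs$sink), 0L)
      expect_true(all(o$pairs$value >= 0.1))
    }
  })
})

test_that("transition links conserve every block's electrode count", {
  p0 <- list(letters[1:7])
  p1 <- list(letters[1:3], letters[4:7])
  lk <- transition_links(p0, p1)
  expect_equal(lk$count, c(3L, 4L))
  expect_equal(sum(lk$count), 7L)

  # identical partitions -> diagonal links only
  p <- list(letters[1:3], letters[4:9])
  lkd <- transition_links(p, p)
  expect_equal(lkd$source, lkd$sink)
  expect_equal(lkd$count, lengths(p))

  # seeded random partitions match brute-force intersections
  withr::with_seed(7, {
    ids <- sprintf("n%02d", 1:30)
    q0 <- as_partition_public(random_partition(ids, 4))
    q1 <- as_partition_public(random_partition(ids, 3))
    lkr <- transition_links(q0, q1)
    for (r in seq_len(nrow(lkr))) {
      expect_equal(lkr$count[r],
                   length(intersect(q0[[lkr$source[r] + 1L]],
                                    q1[[lkr$sink[r] + 1L]])))
    }
    expect_equal(sum(lkr$count), 30L)
    for (i in seq_along(q0)) {
      expect_equal(sum(lkr$count[lkr$source == i - 1L]), length(q0[[i]]))
    }
  })
})

test_that("tracking threads persistent ids through births and deaths", {
  ids <- letters[1:9]
  stable <- stats::setNames(rep(0:2, each = 3), ids)
  dcs <- tracked_from_labels(list(stable, stable, stable), method = "optimal")
  expect_equal(length(unique(dcs$blocks$persistent_id)), 3L)
  per_t <- split(dcs$blocks$persistent_id, dcs$blocks$t)
  expect_true(all(vapply(per_t, function(p) setequal(p, per_t[[1]]), logical(1))))

  # a sink with best similarity below theta is a birth
  p0 <- stats::setNames(c(0, 0, 0, 0, 1, 1, 1, 1, 1), ids)
  p1 <- stats::setNames(c(0, 0, 0, 0, 1, 1, 1, 2, 2), ids)
  low_theta <- track_communities(list(p0, p1), method = "optimal", theta = 0.1)
  high_theta <- track_communities(list(p0, p1), method = "optimal", theta = 0.9)
  expect_equal(glance(low_theta)$n_births, 1L)   # only the genuinely new block
  # at theta = 0.9 only the unchanged block (Jaccard 1.0) survives; the
  # shrunken block (Jaccard 0.6) and the new block are births
  expect_equal(glance(high_theta)$n_births, 2L)

  # persistent id occupies at most one block per timestep
  occ <- table(dcs$blocks$persistent_id, dcs$blocks$t)
  expect_true(all(occ <= 1))
})

test_that("colors are qualitative, persistent over lifetimes, and recycle with a warning", {
  ids <- letters[1:9]
  stable <- stats::setNames(rep(0:2, each = 3), ids)
  dcs <- tracked_from_labels(list(stable, stable), method = "optimal")
  expect_equal(length(unique(dcs$colors)), 3L)
  # same id -> same color at every timestep
  col_t <- split(dcs$colors[dcs$blocks$persistent_id], dcs$blocks$t)
  expect_equal(col_t[[1]], col_t[[2]])
  expect_error(assign_colors(dcs, "NotAPalette"), "palette")

  # 10 ids against palette size 8: the 9th and 10th reuse colors 1 and 2
  labs <- list(
    stats::setNames(0:9, sprintf("n%02d", 1:10))
  )
  # construction already recycles under the default 9-color palette
  dcs10 <- suppressWarnings(tracked_from_labels(labs, method = "optimal"))
  expect_warning(cols <- assign_colors(dcs10, "Dark2"), "recycle")
  expect_equal(length(cols), 10L)
  expect_equal(unname(cols[9]), unname(cols[1]))
  expect_equal(unname(cols[10]), unname(cols[2]))
})

test_that("flow conservation holds across every tracked timestep pair", {
  withr::with_seed(31, {
    ids <- sprintf("n%02d", 1:24)
    labs <- lapply(1:5, function(t) random_partition(ids, sample(2:4, 1)))
    for (method in c("greedy", "optimal")) {
      dcs <- tracked_from_labels(labs, method = method)
      for (t in 0:3) {
        expect_equal(sum(dcs$links$count[dcs$links$t == t]), 24L)
      }
      # partitions exhaustive at every timestep
      for (t in 0:4) {
        b <- dcs$blocks[dcs$blocks$t == t, ]
        expect_setequal(unlist(b$members), ids)
        expect_equal(sum(b$size), 24L)
      }
    }
  })
})
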