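test_that("expansion factor follows the width model and its feasibility bound", {
  ef <- expansion_factor(5, 5, w_max = 1000, w_min = 100, c = 1)
  expect_equal(ef$s_f, 2)
  expect_equal(ef$w_i, 200)
  # boundary: C*W_max == w_min * max(N) gives S_f exactly 1
  ef1 <- expansion_factor(4, 2, w_max = 400, w_min = 100, c = 1)
  expect_equal(ef1$s_f, 1)
  expect_equal(ef1$w_i, 100)
  # the denominator uses the busier axis
  ef2 <- expansion_factor(7, 3, w_max = 1400, w_min = 100, c = 1)
  expect_equal(ef2$s_f, 2)
  # infeasible layouts name the largest feasible w_min
  expect_error(expansion_factor(10, 10, w_max = 500, w_min = 100, c = 1),
               "50\\.000")
})

test_that("view planning spans the timeline with alternating axes", {
  one <- plan_views(30, 30)
  expect_equal(nrow(one), 1L)
  expect_equal(one$from, 0L); expect_equal(one$to, 30L)
  expect_equal(one$axis, "x1")

  four <- plan_views(4, 1)
  expect_equal(four$axis, c("x1", "x2", "x1", "x2"))
  expect_equal(four$from, 0:3)

  three <- plan_views(30, 10)
  expect_equal(nrow(three), 3L)
  expect_equal(three$from, c(0L, 10L, 20L))
  expect_equal(three$to, c(10L, 20L, 30L))
  expect_equal(three$width_share, rep(1, 3))

  # a short final span gets a proportional width share
  ragged <- plan_views(25, 10)
  expect_equal(ragged$to - ragged$from, c(10L, 10L, 5L))
  expect_equal(ragged$width_share, c(1, 1, 0.5))

  expect_error(plan_views(10, 0), "granularity")
  expect_error(plan_views(10, 11), "granularity")
})

test_that("glyph aggregation slices time in clockwise order with community colors", {
  ids <- letters[1:6]
  p_a <- stats::setNames(c(0, 0, 0, 1, 1, 1), ids)
  p_b <- stats::setNames(c(0, 0, 1, 1, 1, 0), ids)  # c and f switch at t=1
  dcs <- tracked_from_labels(list(p_a, p_a, p_b), method = "optimal")
  act <- activation_series(matrix(0.9, 6, 3, dimnames = list(ids, NULL)))

  g1 <- aggregate_glyphs(dcs, act, span = c(1, 2))
  expect_equal(unique(g1$slice), 0L)  # single full-disc slice
  expect_equal(nrow(g1), 6L)

  g <- aggregate_glyphs(dcs, act, span = c(0, 3))
  expect_equal(sort(unique(g$slice)), 0:2)
  # an electrode staying in one community keeps one color, opacity 0.9
  ga <- g[g$node == "a", ]
  expect_equal(length(unique(ga$color)), 1L)
  expect_equal(ga$opacity, rep(0.9, 3))
  # a switching electrode changes color exactly at the switch timestep
  gc <- g[g$node == "c", ]
  expect_equal(gc$color[1], gc$color[2])
  expect_false(gc$color[2] == gc$color[3])
  expect_equal(gc$t[gc$color != gc$color[1]], 2L)
})

test_that("alluvial rendering conserves height, stacks blocks, and is byte-stable", {
  ids <- sprintf("n%02d", 1:12)
  labs <- withr::with_seed(12, lapply(1:4, function(t) random_partition(ids, 3)))
  dcs <- tracked_from_labels(labs, method = "optimal")
  ord <- barycenter_order(dcs)
  doc <- render_alluvial(dcs, ord, width = 640, height = 360)
  blocks <- doc$scene$blocks
  per_t <- tapply(blocks$h, blocks$t, sum)
  expect_true(all(abs(per_t - per_t[[1]]) < 1e-9))  # total height constant
  # one rect per block, deterministic output
  expect_equal(nrow(blocks), nrow(dcs$blocks))
  expect_identical(as.character(doc),
                   as.character(render_alluvial(dcs, ord, width = 640, height = 360)))
  expect_error(render_alluvial(dcs, ord, width = 0), "positive")

  # a single community over all timesteps: one rect per timestep, one
  # unbroken ribbon per consecutive pair
  one <- tracked_from_labels(lapply(1:3, function(t) {
    stats::setNames(rep(0, 5), letters[1:5])
  }))
  d1 <- render_alluvial(one, barycenter_order(one))
  expect_equal(nrow(d1$scene$blocks), 3L)
  expect_equal(nrow(d1$scene$links), 2L)
})

test_that("K heatmap cells encode likelihood in grayscale with white degenerate columns", {
  prof <- tibble::tibble(t = rep(0:1, each = 3), k = rep(2:4, 2),
                         likelihood = c(1, 0, 0.5, 0, 0, 0))
  doc <- render_k_heatmap(prof)
  cells <- doc$scene
  expect_equal(cells$fill[cells$t == 0 & cells$k == 2], "#000000")
  expect_equal(cells$fill[cells$t == 0 & cells$k == 3], "#FFFFFF")
  # degenerate timestep: fully white column
  expect_true(all(cells$fill[cells$t == 1] == "#FFFFFF"))
  # |K_range| cells for every timestep
  expect_equal(unname(table(cells$t)), rep(3L, 2), ignore_attr = TRUE)
  expect_identical(as.character(doc), as.character(render_k_heatmap(prof)))
})

test_that("composed electrode views place views at cumulative offsets on alternating axes", {
  syn <- generate_synthetic(synthetic_spec(n_electrodes = 12, n_timesteps = 6,
                                           noise_sd = 0.01, seed = 4))
  labs <- lapply(1:6, function(t) {
    stats::setNames(syn$truth$labels[, t], rownames(syn$truth$labels))
  })
  dcs <- tracked_from_labels(labs, method = "optimal")
  ord <- barycenter_order(dcs)
  doc <- render_electrode_views(dcs, ord, syn$activation, syn$layout,
                                granularity = 2, w_max = 600, w_min = 100)
  plan <- doc$scene$plan
  expect_equal(plan$x, cumsum(c(0, head(plan$width, -1))))
  expect_equal(plan$axis, c("x1", "x2", "x1"))
  # every glyph has one slice per aggregated timestep
  expect_true(all(doc$scene$glyphs$n_slices == 2))
  expect_identical(as.character(doc),
                   as.character(render_electrode_views(dcs, ord, syn$activation,
                                                       syn$layout, granularity = 2,
                                                       w_max = 600, w_min = 100)))
  # missing coordinates are reported by id
  bad_layout <- electrode_layout(syn$layout$coordinates[-1, ])
  expect_error(render_electrode_views(dcs, ord, syn$activation, bad_layout,
                                      granularity = 2),
               syn$layout$coordinates$id[1])
})

test_that("crop regions remap glyphs affinely, preserving relative distances", {
  syn <- generate_synthetic(synthetic_spec(n_electrodes = 12, n_timesteps = 4,
                                           noise_sd = 0.01, seed = 8))
  labs <- lapply(1:4, function(t) {
    stats::setNames(syn$truth$labels[, t], rownames(syn$truth$labels))
  })
  dcs <- tracked_from_labels(labs)
  ord <- barycenter_order(dcs)
  crop <- c(-1, -1, 5, 4)
  lay2 <- electrode_layout(syn$layout$coordinates, crop_region = crop)
  doc <- render_electrode_views(dcs, ord, syn$activation, lay2,
                                granularity = 4, w_max = 400, w_min = 100)
  g <- doc$scene$glyphs
  co <- syn$layout$coordinates
  co <- co[match(g$node, co$id), ]
  # fit the affine map from two reference points, check all others
  s_x <- diff(range(g$cx)) / diff(range(co$x))
  s_y <- diff(range(g$cy)) / diff(range(co$y))
  expect_equal(s_x, s_y, tolerance = 1e-9)  # uniform scale
  pred_x <- min(g$cx) + s_x * (co$x - min(co$x))
  pred_y <- min(g$cy) + s_y * (co$y - min(co$y))
  expect_equal(g$cx, pred_x, tolerance = 1e-9)
  expect_equal(g$cy, pred_y, tolerance = 1e-9)
})

test_that("zero activation renders transparent fills with visible outlines", {
  ids <- letters[1:4]
  labs <- list(stats::setNames(c(0, 0, 1, 1), ids))
  dcs <- tracked_from_labels(labs)
  ord <- barycenter_order(dcs)
  act <- activation_series(matrix(0, 4, 1, dimnames = list(ids, NULL)))
  lay <- electrode_layout(data.frame(id = ids, x = c(0, 1, 0, 1),
                                     y = c(0, 0, 1, 1)))
  doc <- render_electrode_views(dcs, ord, act, lay, granularity = 1,
                                w_max = 300, w_min = 100)
  txt <- as.character(doc)
  expect_true(grepl("fill-opacity=\"0.00\"", txt, fixed = TRUE))
  expect_true(grepl("stroke=\"#444444\"", txt, fixed = TRUE))
})
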