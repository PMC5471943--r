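#' Specification of a controlled synthetic dataset
#'
#' Describes a planted dynamic-community study: a fixed electrode set on
#' a near-square grid, a schedule of stable and random community
#' intervals, per-community activation modes, and a two-level planted
#' adjacency (high within-community weight, low between) with additive
#' truncated Gaussian noise. The defaults reproduce the controlled case
#' study this package is evaluated on: 54 electrodes, 30 timesteps,
#' three communities with activation modes 0.9 / 0.6 / 0.3, stable over
#' timesteps `[0, 10)` and `[20, 30)` and randomly assigned over
#' `[10, 20)`.
#'
#' @param n_electrodes Number of electrodes.
#' @param n_timesteps Number of timesteps.
#' @param n_communities Number of planted communities.
#' @param activation_modes One activation level in `[0, 1]` per
#'   community.
#' @param schedule Tibble with columns `from`, `to` (half-open timestep
#'   intervals partitioning `[0, n_timesteps)`) and `assignment`
#'   (`"stable"` or `"random"`). Default: stable / random / stable
#'   thirds.
#' @param within_weight,between_weight Planted adjacency weights for
#'   same-community and cross-community edges; `within > between`.
#' @param noise_sd Standard deviation of the additive Gaussian weight
#'   noise (truncated at zero after addition).
#' @param seed RNG seed; generation is bit-reproducible.
#' @param contiguous Plant communities as contiguous runs in grid
#'   row-major order (otherwise electrodes interleave via modulo).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_electrodes = 54L, n_timesteps = 30L,
                           n_communities = 3L,
                           activation_modes = c(0.9, 0.6, 0.3),
                           schedule = NULL,
                           within_weight = 0.9, between_weight = 0.05,
                           noise_sd = 0.02, seed = 1L, contiguous = TRUE) {
  n_electrodes <- as.integer(n_electrodes)
  n_timesteps <- as.integer(n_timesteps)
  n_communities <- as.integer(n_communities)
  if (length(activation_modes) != n_communities) {
    abort("`activation_modes` must have one level per community.")
  }
  if (any(activation_modes < 0 | activation_modes > 1)) {
    abort("Activation modes must be within [0, 1].")
  }
  if (within_weight <= between_weight) {
    abort("`within_weight` must exceed `between_weight`.")
  }
  if (is.null(schedule)) {
    b <- unique(round(seq(0, n_timesteps, length.out = 4)))
    schedule <- tibble(from = head(b, -1), to = tail(b, -1),
                       assignment = c("stable", "random", "stable")[seq_len(length(b) - 1)])
  }
  schedule <- as_tibble(schedule)
  schedule$from <- as.integer(schedule$from)
  schedule$to <- as.integer(schedule$to)
  if (schedule$from[1] != 0L || schedule$to[nrow(schedule)] != n_timesteps ||
      (nrow(schedule) > 1 && any(schedule$from[-1] != head(schedule$to, -1)))) {
    abort("`schedule` intervals must partition [0, n_timesteps).")
  }
  if (!all(schedule$assignment %in% c("stable", "random"))) {
    abort("Schedule assignments must be 'stable' or 'random'.")
  }
  structure(list(n_electrodes = n_electrodes, n_timesteps = n_timesteps,
                 n_communities = n_communities,
                 activation_modes = activation_modes, schedule = schedule,
                 within_weight = within_weight,
                 between_weight = between_weight,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 contiguous = contiguous),
            class = "synthetic_spec")
}

# Near-square grid dimensions: the divisor pair of n closest to square,
# falling back to a ceiling grid with a partial last row.
grid_dims <- function(n) {
  div <- which(n %% seq_len(n) == 0)
  best <- div[which.min(abs(div - sqrt(n)))]
  if (max(best, n / best) <= 2 * sqrt(n)) {
    c(rows = min(best, n / best), cols = max(best, n / best))
  } else {
    cols <- ceiling(sqrt(n))
    c(rows = ceiling(n / cols), cols = cols)
  }
}

planted_partition <- function(spec) {
  n <- spec$n_electrodes; k <- spec$n_communities
  if (spec$contiguous) {
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    rep(seq_len(k) - 1L, times = sizes)
  } else {
    (seq_len(n) - 1L) %% k
  }
}

#' Generate a controlled synthetic dataset
#'
#' Stable intervals use a fixed planted partition (electrodes split as
#' evenly as possible, contiguous on the grid); random intervals draw
#' independent uniform labels per electrode per timestep. The adjacency
#' at each timestep is `within_weight` for same-label pairs and
#' `between_weight` otherwise, plus symmetric Gaussian noise truncated
#' at zero. Activation equals the community's mode level during stable
#' intervals and a uniformly drawn mode during random intervals.
#'
#' @param spec A [synthetic_spec()].
#' @param overlay Internal hook: a function
#'   `(labels, activation, layout) -> list(labels, activation)` applied
#'   after all random draws, used by [generate_seizure_like()].
#' @return A `synthetic_dataset` list with elements `network`
#'   ([dynamic_network()]), `activation` ([activation_series()]),
#'   `layout` ([electrode_layout()]) and `truth` (list: `labels` and
#'   `activation` matrices electrodes x timesteps, `schedule`).
#' @export
generate_synthetic <- function(spec = synthetic_spec(), overlay = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_electrodes; tt <- spec$n_timesteps; k <- spec$n_communities
  ids <- default_node_ids(n)
  dims <- grid_dims(n)
  coords <- tibble(id = ids,
                   x = (seq_len(n) - 1L) %% dims[["cols"]],
                   y = (seq_len(n) - 1L) %/% dims[["cols"]])
  layout <- electrode_layout(coords)
  base <- planted_partition(spec)
  stable <- rep(TRUE, tt)
  for (r in seq_len(nrow(spec$schedule))) {
    if (spec$schedule$assignment[r] == "random") {
      stable[(spec$schedule$from[r] + 1L):spec$schedule$to[r]] <- FALSE
    }
  }
  withr::with_seed(spec$seed, {
    labels <- matrix(0L, n, tt, dimnames = list(ids, NULL))
    for (t in seq_len(tt)) {
      labels[, t] <- if (stable[t]) base else
        sample.int(k, n, replace = TRUE) - 1L
    }
    act <- matrix(0, n, tt, dimnames = list(ids, NULL))
    for (t in seq_len(tt)) {
      act[, t] <- if (stable[t]) spec$activation_modes[base + 1L] else
        spec$activation_modes[sample.int(k, n, replace = TRUE)]
    }
    noise <- lapply(seq_len(tt), function(t) {
      if (spec$noise_sd == 0) return(matrix(0, n, n))
      e <- matrix(rnorm(n * n, 0, spec$noise_sd), n, n)
      (e + t(e)) / 2
    })
    if (!is.null(overlay)) {
      mod <- overlay(labels, act, layout)
      labels <- mod$labels; act <- mod$activation
    }
    adjacency <- lapply(seq_len(tt), function(t) {
      same <- outer(labels[, t], labels[, t], "==")
      m <- ifelse(same, spec$within_weight, spec$between_weight)
      m <- pmax(m + noise[[t]], 0)
      diag(m) <- 0
      m
    })
    structure(list(network = dynamic_network(adjacency, node_ids = ids),
                   activation = activation_series(act),
                   layout = layout,
                   truth = list(labels = labels, activation = act,
                                schedule = spec$schedule),
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' Generate a seizure-like focal-spread dataset
#'
#' Overlays a growing focal region on [generate_synthetic()]: electrodes
#' within grid distance `spread_rate * t` of the focus electrode join
#' one dominant community and their activation ramps toward 1; with a
#' large enough spread rate the final timesteps approach a single
#' community. `spread_rate = 0` reduces exactly to
#' [generate_synthetic()]. Intended for demos of the views, not as a
#' biophysical seizure model.
#'
#' @inheritParams generate_synthetic
#' @param focus Electrode id of the focal onset; defaults to the grid
#'   electrode closest to the layout centroid.
#' @param spread_rate Radius growth in grid units per timestep.
#' @return A `synthetic_dataset` (see [generate_synthetic()]).
#' @export
generate_seizure_like <- function(spec = synthetic_spec(), focus = NULL,
                                  spread_rate = 0.5) {
  overlay <- function(labels, act, layout) {
    co <- layout$coordinates
    if (is.null(focus)) {
      cx <- mean(co$x); cy <- mean(co$y)
      focus <- co$id[which.min((co$x - cx)^2 + (co$y - cy)^2)]
    }
    if (!focus %in% co$id) abort("`focus` must be an electrode id in the layout.")
    fc <- co[co$id == focus, ]
    d <- sqrt((co$x - fc$x)^2 + (co$y - fc$y)^2)
    tt <- ncol(labels)
    for (t in seq_len(tt)) {
      captured <- d < spread_rate * (t - 1L)
      if (any(captured)) {
        labels[captured, t] <- 0L
        ramp <- (t - 1) / max(tt - 1, 1)
        act[captured, t] <- pmax(act[captured, t], ramp)
      }
    }
    list(labels = labels, activation = act)
  }
  generate_synthetic(spec, overlay = overlay)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d electrodes x %d timesteps, %d planted communities\n",
              x$spec$n_electrodes, x$spec$n_timesteps, x$spec$n_communities))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `network.csv` (long edge list), `network.dynstack` (matrix
#' stack), `coordinates.csv`, `activation.csv` and `ground_truth.json`.
#'
#' @param data A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dynamic_network(data$network, file.path(dir, "network.csv"), "long")
  write_dynamic_network(data$network, file.path(dir, "network.dynstack"), "stack")
  write_electrode_layout(data$layout, file.path(dir, "coordinates.csv"))
  write_activation_series(data$activation, file.path(dir, "activation.csv"))
  jsonlite::write_json(
    list(labels = unname(apply(data$truth$labels, 2, as.integer, simplify = FALSE)),
         node_ids = rownames(data$truth$labels),
         activation = unname(apply(data$truth$activation, 2, identity, simplify = FALSE)),
         schedule = data$truth$schedule),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
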