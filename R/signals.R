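#' Construct a multichannel signal recording
#'
#' @param samples Numeric matrix, electrodes x time samples (arbitrary
#'   amplitude units). Rownames are electrode ids.
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param window_length Samples per analysis timestep; at least 2.
#' @return A `signal_recording` object.
#' @export
signal_recording <- function(samples, sampling_rate, window_length) {
  if (!is.matrix(samples)) abort("`samples` must be a matrix (electrodes x samples).")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be > 0.")
  }
  window_length <- as.integer(window_length)
  if (window_length < 2L) abort("`window_length` must be >= 2 samples.")
  if (is.null(rownames(samples))) rownames(samples) <- default_node_ids(nrow(samples))
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 window_length = window_length),
            class = "signal_recording")
}

# Half-open sample windows [start, start + len); returns integer start indices.
signal_windows <- function(rec, overlap_fraction = 0) {
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    abort("`overlap_fraction` must be in [0, 1).")
  }
  len <- rec$window_length
  total <- ncol(rec$samples)
  if (len > total) abort("window_length exceeds the number of samples.")
  step <- max(1L, as.integer(round(len * (1 - overlap_fraction))))
  seq.int(1L, total - len + 1L, by = step)
}

#' Build a windowed correlation network from a signal recording
#'
#' One timestep per (possibly overlapping) analysis window. The edge
#' weight between two electrodes is the absolute Pearson correlation of
#' their windowed signals; the sign is discarded because clustering uses
#' connectivity strength only. Channels that are constant within a window
#' get weight 0 against all partners (with a warning).
#'
#' @param rec A [signal_recording()].
#' @param overlap_fraction Fraction of window overlap in `[0, 1)`;
#'   0 gives non-overlapping consecutive windows.
#' @return A [dynamic_network()] with one timestep per window and
#'   `timestep_duration` derived from the sampling rate.
#' @export
build_correlation_network <- function(rec, overlap_fraction = 0) {
  stopifnot(inherits(rec, "signal_recording"))
  starts <- signal_windows(rec, overlap_fraction)
  len <- rec$window_length
  any_constant <- FALSE
  adjacency <- lapply(starts, function(s) {
    x <- t(rec$samples[, s:(s + len - 1L), drop = FALSE])
    sds <- apply(x, 2, stats::sd)
    const <- sds == 0
    if (any(const)) any_constant <<- TRUE
    m <- matrix(0, ncol(x), ncol(x))
    if (sum(!const) >= 2) {
      m[!const, !const] <- abs(stats::cor(x[, !const, drop = FALSE]))
    }
    diag(m) <- 0
    m
  })
  if (any_constant) {
    warn("Constant channel(s) in at least one window; their correlations were set to 0.")
  }
  dynamic_network(adjacency, node_ids = rownames(rec$samples),
                  timestep_duration = 1000 * len / rec$sampling_rate)
}

#' Compute per-electrode activation from a signal recording
#'
#' Summarises each electrode's signal within each analysis window by a
#' magnitude statistic, then min-max rescales across the whole recording
#' to `[0, 1]`. A constant recording maps to all zeros.
#'
#' @inheritParams build_correlation_network
#' @param mode `"mean-abs"` (mean absolute amplitude) or `"rms"`.
#' @return An [activation_series()] (electrodes x windows).
#' @export
compute_activation <- function(rec, overlap_fraction = 0,
                               mode = c("mean-abs", "rms")) {
  stopifnot(inherits(rec, "signal_recording"))
  mode <- match.arg(mode)
  starts <- signal_windows(rec, overlap_fraction)
  len <- rec$window_length
  stat <- switch(mode,
                 "mean-abs" = function(v) mean(abs(v)),
                 "rms" = function(v) sqrt(mean(v^2)))
  vals <- vapply(starts, function(s) {
    apply(rec$samples[, s:(s + len - 1L), drop = FALSE], 1, stat)
  }, numeric(nrow(rec$samples)))
  vals <- matrix(vals, nrow = nrow(rec$samples),
                 dimnames = list(rownames(rec$samples), NULL))
  rng <- range(vals)
  if (rng[2] > rng[1]) {
    vals <- (vals - rng[1]) / (rng[2] - rng[1])
  } else {
    vals[] <- 0
  }
  activation_series(vals)
}
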