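#' Expansion factor and width of the electrode views
#'
#' The composed display places electrode views on two horizontal axes
#' (above, `x1`, and below, `x2`, the cluster evolution band). Each view
#' gets width `w_i = w_min * S_f` with expansion factor
#' `S_f = C * W_max / (w_min * max(N_x1, N_x2))`, which must be at least
#' 1 for the layout to be feasible.
#'
#' @param n_x1,n_x2 Number of electrode views on the upper/lower axis;
#'   `max(n_x1, n_x2) >= 1`.
#' @param w_max Maximum horizontal display width in px.
#' @param w_min Minimal electrode-view width in px.
#' @param c User constant scaling the share of `w_max` used.
#' @return A list with `s_f` and `w_i`.
#' @export
expansion_factor <- function(n_x1, n_x2, w_max, w_min, c = 1) {
  if (max(n_x1, n_x2) < 1) abort("Need at least one electrode view.")
  if (w_max <= 0 || w_min <= 0 || c <= 0) abort("Widths and C must be positive.")
  s_f <- c * w_max / (w_min * max(n_x1, n_x2))
  if (s_f < 1) {
    abort(sprintf(
      "Layout infeasible: S_f = %.3f < 1. Reduce w_min to at most %.3f px (= C*W_max/max(N_x1,N_x2)).",
      s_f, c * w_max / max(n_x1, n_x2)))
  }
  list(s_f = s_f, w_i = w_min * s_f)
}

#' Plan electrode views over the timeline
#'
#' Splits `t_total` timesteps into consecutive half-open spans of length
#' `granularity` (the last may be shorter). Views alternate between the
#' upper (`x1`) and lower (`x2`) axis left-to-right in timeline order.
#' When spans are unequal, a view's width share is proportional to its
#' span length.
#'
#' @param t_total Total number of timesteps.
#' @param granularity Timesteps aggregated per electrode view, in
#'   `[1, t_total]`.
#' @return A tibble with columns `view` (0-based), `from`, `to`
#'   (half-open span), `axis` (`"x1"`/`"x2"`), `width_share`.
#' @export
plan_views <- function(t_total, granularity) {
  if (granularity < 1) abort("`granularity` must be >= 1.")
  if (granularity > t_total) abort("`granularity` cannot exceed `t_total`.")
  from <- seq.int(0L, t_total - 1L, by = granularity)
  to <- pmin(from + granularity, t_total)
  tibble(view = seq_along(from) - 1L, from = from, to = to,
         axis = ifelse(seq_along(from) %% 2 == 1, "x1", "x2"),
         width_share = (to - from) / granularity)
}

#' Aggregate cluster membership and activation into glyph slices
#'
#' For one electrode view spanning timesteps `[from, to)`, every
#' electrode gets one clock slice per timestep, clockwise from 12
#' o'clock in time order; the slice color is the electrode's dynamic
#' community color at that timestep and the slice opacity its activation.
#'
#' @param dcs A `dyncomm_set` (see [track_communities()]).
#' @param activation An [activation_series()].
#' @param span Half-open timestep interval `c(from, to)`.
#' @param timesteps Explicit timestep vector overriding `span` (used for
#'   non-contiguous tracked timesteps).
#' @return A `glyph_spec` tibble: `node`, `slice` (0-based, clockwise
#'   from top), `t`, `color`, `opacity`.
#' @export
aggregate_glyphs <- function(dcs, activation, span, timesteps = NULL) {
  ts_avail <- sort(unique(dcs$blocks$t))
  span_ts <- timesteps %||% seq.int(span[1], span[2] - 1L)
  if (!all(span_ts %in% ts_avail)) abort("`span` outside the tracked timesteps.")
  act <- unclass(activation)
  if (max(span_ts) + 1L > ncol(act)) abort("`span` outside the activation series.")
  rows <- lapply(seq_along(span_ts), function(s) {
    step <- span_ts[s]
    b <- dcs$blocks[dcs$blocks$t == step, ]
    node <- unlist(b$members)
    id <- rep(b$persistent_id, lengths(b$members))
    opacity <- unname(act[node, step + 1L])
    tibble(node = node, slice = s - 1L, t = step,
           color = unname(dcs$colors[id]),
           opacity = opacity)
  })
  out <- arrange(bind_rows(rows), .data$node, .data$slice)
  class(out) <- c("glyph_spec", class(out))
  out
}
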