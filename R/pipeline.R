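#' Run the full dynamic-community pipeline on a network
#'
#' Clusters every timestep by consensus clustering, tracks the clusters
#' into dynamic communities, and computes a timeline ordering for the
#' alluvial view.
#'
#' @param net A [dynamic_network()].
#' @param consensus A [consensus_params()].
#' @param method Tracking method, `"optimal"` or `"greedy"`.
#' @param theta Jaccard threshold for optimal tracking.
#' @param ordering An [ordering_config()].
#' @param palette Qualitative palette for community colors.
#' @return A `dyncomm_result` list with `clusterings`, `communities`
#'   (the `dyncomm_set`) and `ordering`.
#' @export
dyncomm_pipeline <- function(net, consensus = consensus_params(),
                             method = c("optimal", "greedy"), theta = 0.1,
                             ordering = ordering_config(),
                             palette = "Set1") {
  method <- match.arg(method)
  clusterings <- cluster_timesteps(net, consensus)
  dcs <- track_communities(clusterings, method = method, theta = theta,
                           palette = palette)
  ord <- barycenter_order(dcs, ordering)
  structure(list(clusterings = clusterings, communities = dcs,
                 ordering = ord),
            class = "dyncomm_result")
}

#' @export
print.dyncomm_result <- function(x, ...) {
  print(x$communities)
  cat(sprintf("  ordering objective %.2f (%d crossings)\n",
              x$ordering$objective, x$ordering$crossings))
  invisible(x)
}

#' @method glance dyncomm_result
#' @export
glance.dyncomm_result <- function(x, ...) {
  mutate(glance(x$communities),
         ordering_objective = x$ordering$objective,
         crossings = x$ordering$crossings)
}

#' @method tidy dyncomm_result
#' @export
tidy.dyncomm_result <- function(x, ...) {
  tidy(x$communities)
}
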