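#' Write a tracked dynamic-community set to JSON
#'
#' The document carries per-timestep partitions with persistent ids,
#' transition links (electrode counts and Jaccard similarities),
#' K-likelihood profiles when available, the color map and the tracking
#' settings. [read_dynamic_communities()] inverts it: all id, index and
#' count fields round-trip bit-exactly; floats are written at full
#' precision.
#'
#' @param dcs A `dyncomm_set` (see [track_communities()]).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_dynamic_communities <- function(dcs, path) {
  ts <- sort(unique(dcs$blocks$t))
  timesteps <- lapply(ts, function(t) {
    b <- dcs$blocks[dcs$blocks$t == t, ]
    b <- b[order(b$index), ]
    list(t = t, communities = lapply(seq_len(nrow(b)), function(r) {
      list(index = b$index[r], persistent_id = b$persistent_id[r],
           members = as.list(b$members[[r]]))
    }))
  })
  doc <- list(
    schema = "dynamic-communities/1",
    node_ids = as.list(dcs$node_ids),
    method = dcs$method,
    theta = dcs$theta,
    timesteps = timesteps,
    links = dcs$links,
    k_profiles = dcs$profiles,
    colors = as.list(dcs$colors)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a dynamic-community JSON document
#'
#' @param path Path written by [write_dynamic_communities()].
#' @return A `dyncomm_set`.
#' @export
read_dynamic_communities <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "dynamic-communities/1")) {
    abort(sprintf("Not a dynamic-communities document: %s", path))
  }
  blocks <- bind_rows(lapply(doc$timesteps, function(entry) {
    if (length(entry$communities) == 0) return(NULL)
    bind_rows(lapply(entry$communities, function(cm) {
      tibble(t = as.integer(entry$t), index = as.integer(cm$index),
             persistent_id = cm$persistent_id,
             size = length(cm$members),
             members = list(unlist(cm$members)))
    }))
  }))
  links <- if (length(doc$links) == 0) {
    tibble(t = integer(), source = integer(), sink = integer(),
           count = integer(), similarity = double(),
           source_id = character(), sink_id = character())
  } else {
    bind_rows(lapply(doc$links, function(l) {
      tibble(t = as.integer(l$t), source = as.integer(l$source),
             sink = as.integer(l$sink), count = as.integer(l$count),
             similarity = as.numeric(l$similarity),
             source_id = l$source_id, sink_id = l$sink_id)
    }))
  }
  profiles <- if (is.null(doc$k_profiles)) NULL else {
    bind_rows(lapply(doc$k_profiles, function(p) {
      tibble(t = as.integer(p$t), k = as.integer(p$k),
             area = as.numeric(p$area), delta = as.numeric(p$delta),
             pac = as.numeric(p$pac),
             likelihood = as.numeric(p$likelihood))
    }))
  }
  structure(list(blocks = blocks, links = links,
                 colors = unlist(doc$colors),
                 profiles = profiles,
                 node_ids = unlist(doc$node_ids),
                 method = doc$method, theta = doc$theta),
            class = "dyncomm_set")
}
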