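#' Construct a dynamic network
#'
#' A dynamic network is an ordered sequence of symmetric, non-negative
#' weighted adjacency matrices over a fixed electrode set. Edge weights are
#' correlation magnitudes in typical use, but any non-negative symmetric
#' weights are accepted.
#'
#' @param adjacency A list of square numeric matrices, one per timestep, all
#'   of the same dimension. Matrices must be symmetric within `tol`, have a
#'   zero diagonal and no negative entries.
#' @param node_ids Character vector of electrode identifiers, one per
#'   matrix row. Defaults to the rownames of the first matrix, or
#'   `"e01".."eNN"` if unnamed.
#' @param timestep_duration Optional duration of one timestep in
#'   milliseconds (metadata only).
#' @param tol Symmetry tolerance; asymmetries up to `1e-6` are symmetrized
#'   by averaging, larger ones are an error.
#'
#' @return An object of class `dynamic_network` with elements `node_ids`,
#'   `adjacency` (list of named matrices) and `timestep_duration`.
#' @export
dynamic_network <- function(adjacency, node_ids = NULL,
                            timestep_duration = NULL, tol = 1e-6) {
  if (!is.list(adjacency) || length(adjacency) < 1L) {
    abort("`adjacency` must be a non-empty list of matrices (T_total >= 1).")
  }
  n <- nrow(adjacency[[1]])
  if (is.null(node_ids)) {
    node_ids <- rownames(adjacency[[1]]) %||% default_node_ids(n)
  }
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) abort("`node_ids` must be unique.")
  if (length(node_ids) != n) abort("`node_ids` length must match matrix dimension.")
  adjacency <- lapply(seq_along(adjacency), function(t) {
    m <- adjacency[[t]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != n) {
      abort(sprintf("Adjacency at timestep %d is not a %dx%d matrix.", t - 1L, n, n))
    }
    storage.mode(m) <- "double"
    asym <- max(abs(m - t(m)))
    if (asym > tol) {
      abort(sprintf("Adjacency at timestep %d is asymmetric (max |A - t(A)| = %.3g > %.1g).",
                    t - 1L, asym, tol))
    }
    if (min(m) < 0) {
      abort(sprintf("Adjacency at timestep %d has negative weights.", t - 1L))
    }
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(node_ids, node_ids)
    m
  })
  structure(
    list(node_ids = node_ids, adjacency = adjacency,
         timestep_duration = timestep_duration),
    class = "dynamic_network"
  )
}

default_node_ids <- function(n) {
  sprintf(paste0("e%0", max(2L, nchar(n)), "d"), seq_len(n))
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf("<dynamic_network> %d electrodes x %d timesteps\n",
              n_nodes(x), n_timesteps(x)))
  invisible(x)
}

#' Number of nodes / timesteps of a dynamic network
#' @param net A `dynamic_network`.
#' @return An integer.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname n_nodes
#' @export
n_timesteps <- function(net) length(net$adjacency)

#' @method as_tibble dynamic_network
#' @export
as_tibble.dynamic_network <- function(x, ...) {
  n <- n_nodes(x)
  ut <- upper.tri(x$adjacency[[1]])
  ij <- which(ut, arr.ind = TRUE)
  bind_rows(lapply(seq_along(x$adjacency), function(step) {
    tibble(t = step - 1L,
           i = x$node_ids[ij[, 1]],
           j = x$node_ids[ij[, 2]],
           w = x$adjacency[[step]][ut])
  }))
}

#' Read a dynamic network from disk
#'
#' Two plain-text formats are supported. `"long"` is a delimited edge list
#' with header `t,i,j,w` (0-based timestep, node ids, weight); edges absent
#' from a timestep have weight zero, and a timestep with no rows is the
#' empty graph. `"stack"` is the `dynstack` text format written by
#' [write_dynamic_network()]: a header line `dynstack 1`, a line `T N`, a
#' tab-separated line of node ids, then `T` blocks of `N` tab-separated
#' matrix rows.
#'
#' @param path Path to the file.
#' @param format `"long"` or `"stack"`.
#' @param node_ids For `"long"`: the full node set. Defaults to the sorted
#'   union of ids seen in the file; pass explicitly if isolated nodes exist.
#' @param n_timesteps For `"long"`: total number of timesteps. Defaults to
#'   `max(t) + 1`.
#' @return A [dynamic_network()].
#' @export
read_dynamic_network <- function(path, format = c("long", "stack"),
                                 node_ids = NULL, n_timesteps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (format == "stack") return(read_dynstack(path))

  df <- readr::read_csv(path, col_types = readr::cols(
    t = readr::col_integer(), i = readr::col_character(),
    j = readr::col_character(), w = readr::col_double()
  ), progress = FALSE)
  if (!all(c("t", "i", "j", "w") %in% names(df))) {
    abort("Long edge list must have columns t,i,j,w.")
  }
  if (is.null(node_ids)) node_ids <- sort(unique(c(df$i, df$j)))
  unknown <- setdiff(c(df$i, df$j), node_ids)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown node id(s) in edge list: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(df$w < 0)) abort("Negative edge weights are not allowed.")
  if (is.null(n_timesteps)) n_timesteps <- max(df$t) + 1L
  n <- length(node_ids)
  adjacency <- lapply(seq_len(n_timesteps) - 1L, function(tt) {
    m <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
    rows <- df[df$t == tt, ]
    if (nrow(rows) > 0) {
      ii <- match(rows$i, node_ids); jj <- match(rows$j, node_ids)
      # duplicate (i,j)/(j,i) entries: check consistency, then average
      a <- matrix(NA_real_, n, n)
      for (r in seq_len(nrow(rows))) {
        if (!is.na(a[ii[r], jj[r]]) && abs(a[ii[r], jj[r]] - rows$w[r]) > 1e-6) {
          abort(sprintf(
            "Asymmetric duplicate edge (%s,%s) at timestep %d: %g vs %g.",
            rows$i[r], rows$j[r], tt, a[ii[r], jj[r]], rows$w[r]))
        }
        a[ii[r], jj[r]] <- rows$w[r]
      }
      both <- !is.na(a) & !is.na(t(a))
      asym <- abs(a - t(a))
      if (any(asym[both] > 1e-6)) abort(
        sprintf("Asymmetry > 1e-6 in edge list at timestep %d.", tt))
      a[is.na(a)] <- t(a)[is.na(a)]
      a[is.na(a)] <- 0
      m <- (a + t(a)) / 2
      dimnames(m) <- list(node_ids, node_ids)
    }
    diag(m) <- 0
    m
  })
  dynamic_network(adjacency, node_ids = node_ids)
}

#' Write a dynamic network to disk
#'
#' @param net A [dynamic_network()].
#' @param path Output file path.
#' @param format `"long"` (edge list, zero edges omitted) or `"stack"`
#'   (full-precision text matrix stack; round-trips within 1e-12).
#' @return `path`, invisibly.
#' @export
write_dynamic_network <- function(net, path, format = c("long", "stack")) {
  format <- match.arg(format)
  if (format == "long") {
    df <- as_tibble(net)
    df <- df[df$w != 0, ]
    readr::write_csv(df, path, progress = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("dynstack 1", con)
    writeLines(sprintf("%d %d", n_timesteps(net), n_nodes(net)), con)
    writeLines(paste(net$node_ids, collapse = "\t"), con)
    for (m in net$adjacency) {
      writeLines(apply(m, 1, function(r)
        paste(formatC(r, format = "g", digits = 17), collapse = "\t")), con)
    }
  }
  invisible(path)
}

read_dynstack <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "dynstack 1") {
    abort(sprintf("Not a dynstack file: %s", path))
  }
  dims <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  tt <- dims[1]; n <- dims[2]
  node_ids <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(node_ids) != n) abort("dynstack node id count does not match header.")
  body <- lines[-(1:3)]
  if (length(body) != tt * n) abort("dynstack row count does not match header.")
  vals <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                 ncol = n, byrow = TRUE)
  adjacency <- lapply(seq_len(tt), function(k) {
    vals[((k - 1) * n + 1):(k * n), , drop = FALSE]
  })
  dynamic_network(adjacency, node_ids = node_ids)
}

#' Construct an electrode layout
#'
#' @param coordinates A data frame with columns `id`, `x`, `y`: one finite
#'   2-D position per electrode, in view units.
#' @param background_image Optional path/URI of a raster underlay.
#' @param crop_region Optional numeric vector `c(xmin, ymin, xmax, ymax)`
#'   restricting the drawn region.
#' @return An `electrode_layout` object.
#' @export
electrode_layout <- function(coordinates, background_image = NULL,
                             crop_region = NULL) {
  coordinates <- as_tibble(coordinates)
  if (!all(c("id", "x", "y") %in% names(coordinates))) {
    abort("`coordinates` must have columns id, x, y.")
  }
  coordinates$id <- as.character(coordinates$id)
  if (anyDuplicated(coordinates$id)) abort("Duplicate electrode id in layout.")
  if (!all(is.finite(coordinates$x)) || !all(is.finite(coordinates$y))) {
    abort("Electrode coordinates must be finite.")
  }
  if (!is.null(crop_region) && length(crop_region) != 4) {
    abort("`crop_region` must be c(xmin, ymin, xmax, ymax).")
  }
  structure(list(coordinates = coordinates,
                 background_image = background_image,
                 crop_region = crop_region),
            class = "electrode_layout")
}

#' Read / write electrode coordinates (`id,x,y` delimited text)
#' @param path File path.
#' @param ... Passed to [electrode_layout()].
#' @return An [electrode_layout()] (reader) or `path` (writer).
#' @export
read_electrode_layout <- function(path, ...) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), x = readr::col_double(),
    y = readr::col_double()), progress = FALSE)
  electrode_layout(df, ...)
}

#' @rdname read_electrode_layout
#' @param layout An [electrode_layout()].
#' @export
write_electrode_layout <- function(layout, path) {
  readr::write_csv(layout$coordinates, path, progress = FALSE)
  invisible(path)
}

#' Construct an activation series
#'
#' Per-electrode, per-timestep activation in `[0, 1]`, used as glyph
#' opacity in the electrode views.
#'
#' @param values Numeric matrix, electrodes x timesteps, all entries in
#'   `[0, 1]`. Rownames are node ids.
#' @return An `activation_series` (a classed matrix).
#' @export
activation_series <- function(values) {
  if (!is.matrix(values)) abort("`values` must be a matrix.")
  if (any(!is.finite(values)) || min(values) < 0 || max(values) > 1) {
    abort("Activation values must be finite and within [0, 1].")
  }
  if (is.null(rownames(values))) rownames(values) <- default_node_ids(nrow(values))
  structure(values, class = c("activation_series", class(values)))
}

#' Read / write an activation series (delimited text, `id` + one column
#' per timestep)
#' @param path File path.
#' @return An [activation_series()] (reader) or `path` (writer).
#' @export
read_activation_series <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$id
  colnames(m) <- NULL
  activation_series(m)
}

#' @rdname read_activation_series
#' @param activation An [activation_series()].
#' @export
write_activation_series <- function(activation, path) {
  m <- unclass(activation)
  df <- as.data.frame(m)
  names(df) <- sprintf("t%d", seq_len(ncol(m)) - 1L)
  readr::write_csv(cbind(tibble(id = rownames(m)), df), path,
                   progress = FALSE)
  invisible(path)
}

#' @method tidy activation_series
#' @export
tidy.activation_series <- function(x, ...) {
  m <- unclass(x)
  tibble(node = rep(rownames(m), ncol(m)),
         t = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
         activation = as.vector(m))
}

check_layout_covers <- function(layout, node_ids) {
  missing <- setdiff(node_ids, layout$coordinates$id)
  if (length(missing) > 0) {
    abort(sprintf("Missing coordinates for electrode(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
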