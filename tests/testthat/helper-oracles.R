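# Independent oracles used to cross-check the package's own algorithms.

# Area under the empirical CDF of off-diagonal consensus entries,
# by rectangle-rule numerical integration on a fine grid (independent
# of the exact-breakpoint computation in the package).
cdf_area_oracle <- function(M, step = 1e-4) {
  x <- M[lower.tri(M)]
  grid <- seq(0, 1 - step, by = step)
  cdf <- stats::ecdf(x)
  sum(cdf(grid)) * step
}

delta_profile_oracle <- function(consensus_by_k) {
  a <- vapply(consensus_by_k, cdf_area_oracle, numeric(1))
  d <- numeric(length(a))
  d[1] <- a[1]
  if (length(a) > 1) d[-1] <- diff(a) / head(a, -1)
  unname(d)
}

# Maximum-weight linear assignment objectives for a batch of matrices,
# via scipy.optimize.linear_sum_assignment (single python call).
lap_objectives_oracle <- function(matrices) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(matrices, function(m) {
      lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    }),
    infile, digits = NA)
  script <- sprintf('
import json, numpy as np
from scipy.optimize import linear_sum_assignment
with open(%s) as fh:
    mats = json.load(fh)
out = []
for m in mats:
    a = np.array(m, dtype=float)
    r, c = linear_sum_assignment(a, maximize=True)
    out.append(float(a[r, c].sum()))
with open(%s, "w") as fh:
    json.dump(out, fh)
', deparse(infile), deparse(outfile))
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) stop("python/scipy oracle failed")
  unlist(jsonlite::read_json(outfile, simplifyVector = TRUE))
}

# Exhaustive minimum of the weighted link-distance objective over all
# per-timestep orderings (tiny instances only).
exhaustive_ordering_optimum <- function(dcs) {
  ts <- sort(unique(dcs$blocks$t))
  perms_of <- function(n) {
    if (n == 1) return(list(0L))
    unlist(lapply(seq_len(n), function(i) {
      lapply(perms_of(n - 1L), function(p) {
        rest <- setdiff(seq_len(n) - 1L, i - 1L)
        c(i - 1L, rest[p + 1L])
      })
    }), recursive = FALSE)
  }
  sizes <- lapply(ts, function(t) {
    b <- dcs$blocks[dcs$blocks$t == t, ]
    b$size[order(b$index)]
  })
  options <- lapply(sizes, function(s) perms_of(length(s)))
  idx <- rep(1L, length(ts))
  best <- Inf
  repeat {
    ords <- lapply(seq_along(ts), function(k) options[[k]][[idx[k]]])
    best <- min(best, link_distance_objective(dcs, ords))
    k <- 1L
    repeat {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= length(options[[k]])) break
      idx[k] <- 1L
      k <- k + 1L
      if (k > length(ts)) return(best)
    }
  }
}
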