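#' Grid search over cluster-count pairs
#'
#' For every pair (n, m) in the supplied ranges, runs `trials` random
#' restarts of [bicluster()] on the transformed response and records each
#' restart's SSEbc together with the SSEni of [fit_blockwise()] applied to
#' that restart's partition on the *raw* phenotype (SSEni is always measured
#' on the raw scale, whatever response was clustered).  Mean and minimum of
#' both metrics are aggregated per pair: means describe typical restarts,
#' minima describe the best run one would keep in practice.  As both counts
#' approach the table dimensions every observation sits in its own cell and
#' all metrics converge to zero.
#'
#' @param x a [phenotype_table()] of raw phenotype means.
#' @param kind response kind for clustering (see [gei_response()]);
#'   default 2.
#' @param row_range,col_range integer vectors of cluster counts to evaluate.
#' @param trials restarts per pair (default 30).
#' @param base_seed seed of the first restart; restart t uses
#'   `base_seed + t - 1`, identically for every pair, so a grid is
#'   reproducible bit for bit.
#' @inheritParams bicluster
#' @return An object of class `gei_grid`: `row_range`, `col_range`,
#'   matrices `mean_sse_bc`, `min_sse_bc`, `mean_sse_ni`, `min_sse_ni`
#'   (rows = `row_range`, columns = `col_range`), `trials`,
#'   `response_kind`.
#' @export
grid_search <- function(x, kind = 2L, row_range, col_range, trials = 30L,
                        base_seed = 1L, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(x, "phenotype_table"))
  row_range <- as.integer(row_range)
  col_range <- as.integer(col_range)
  if (length(row_range) == 0L || length(col_range) == 0L) {
    stop("empty cluster-count range")
  }
  if (any(row_range < 1L) || any(row_range > nrow(x))) {
    stop("row_range must lie in 1..", nrow(x))
  }
  if (any(col_range < 1L) || any(col_range > ncol(x))) {
    stop("col_range must lie in 1..", ncol(x))
  }
  resp <- gei_response(x, kind)
  dims <- list(row_range, col_range)
  mk <- function() matrix(NA_real_, length(row_range), length(col_range),
                          dimnames = dims)
  mean_bc <- mk(); min_bc <- mk(); mean_ni <- mk(); min_ni <- mk()
  for (a in seq_along(row_range)) {
    for (b in seq_along(col_range)) {
      bc <- numeric(trials)
      ni <- numeric(trials)
      for (t in seq_len(trials)) {
        run <- bicluster(resp, row_range[a], col_range[b],
                         seed = base_seed + t - 1L,
                         max_iter = max_iter, tol = tol)
        bc[t] <- run$sse_bc
        ni[t] <- fit_blockwise(x, run$partition)$sse_ni
      }
      mean_bc[a, b] <- mean(bc); min_bc[a, b] <- min(bc)
      mean_ni[a, b] <- mean(ni); min_ni[a, b] <- min(ni)
    }
  }
  structure(list(
    row_range = row_range, col_range = col_range,
    mean_sse_bc = mean_bc, min_sse_bc = min_bc,
    mean_sse_ni = mean_ni, min_sse_ni = min_ni,
    trials = as.integer(trials),
    response_kind = as.integer(kind)
  ), class = "gei_grid")
}

#' @export
print.gei_grid <- function(x, ...) {
  cat(sprintf("gei_grid: response %d, %d trials per pair\nmin SSEni:\n",
              x$response_kind, x$trials))
  print(signif(x$min_sse_ni, 6))
  invisible(x)
}

#' Suggest a cluster-count pair from a grid
#'
#' Advisory elbow rule: among pairs whose minimum SSEni is within a fraction
#' `tol` (default 10%) of the best minimum achieved anywhere on the grid,
#' returns the one with the smallest `n + m`; remaining ties break to
#' smaller n, then smaller m.  The grid itself is the primary output — the
#' intended use is visual inspection of the SSE surfaces.
#'
#' @param grid a `gei_grid` from [grid_search()].
#' @param tol relative slack off the best minimum SSEni (default 0.1).
#' @return Named integer vector `c(n = , m = )`.
#' @export
suggest_pair <- function(grid, tol = 0.1) {
  stopifnot(inherits(grid, "gei_grid"))
  v <- grid$min_sse_ni
  best <- min(v)
  ok <- which(v <= best * (1 + tol), arr.ind = TRUE)
  n <- grid$row_range[ok[, 1]]
  m <- grid$col_range[ok[, 2]]
  o <- order(n + m, n, m)[1L]
  c(n = n[o], m = m[o])
}
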