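#' Row/column partition of a phenotype table
#'
#' Assigns each genotype to one of `n` row clusters and each environment to
#' one of `m` column clusters.  The intersection of a row cluster and a
#' column cluster is a *cell*, the unit within which GEI is modeled as
#' homogeneous.
#'
#' @param rows integer vector of row-cluster indices in `1..n`, one per
#'   genotype.
#' @param cols integer vector of column-cluster indices in `1..m`, one per
#'   environment.
#' @param n,m cluster counts; default to the maximum index used.
#' @return An object of class `gei_partition`.
#' @export
gei_partition <- function(rows, cols, n = max(rows), m = max(cols)) {
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  n <- as.integer(n)
  m <- as.integer(m)
  if (anyNA(rows) || anyNA(cols)) stop("cluster assignments must not be NA")
  if (any(rows < 1L) || any(rows > n)) stop("row assignment out of range 1..n")
  if (any(cols < 1L) || any(cols > m)) stop("column assignment out of range 1..m")
  if (n > length(rows)) stop("n exceeds the number of genotypes")
  if (m > length(cols)) stop("m exceeds the number of environments")
  structure(list(rows = rows, cols = cols, n = n, m = m),
            class = "gei_partition")
}

#' @export
print.gei_partition <- function(x, ...) {
  cat(sprintf("gei_partition: %d row clusters x %d column clusters (%d x %d table)\n",
              x$n, x$m, length(x$rows), length(x$cols)))
  invisible(x)
}

check_partition <- function(x, partition) {
  stopifnot(inherits(x, "phenotype_table"), inherits(partition, "gei_partition"))
  if (length(partition$rows) != nrow(x) || length(partition$cols) != ncol(x)) {
    stop("partition dimensions do not match the table")
  }
  invisible(partition)
}

# Per-cell sums/counts/sums-of-squares for the observed entries.
cell_stats <- function(x, partition) {
  W <- !is.na(x)
  Y <- unclass(x)
  Y[!W] <- 0
  Rm <- outer(seq_len(partition$n), partition$rows, "==") + 0 # n x I
  Cm <- outer(partition$cols, seq_len(partition$m), "==") + 0 # J x m
  list(
    S = Rm %*% Y %*% Cm,
    N = Rm %*% W %*% Cm,
    Q = Rm %*% (Y^2) %*% Cm
  )
}

#' Within-cell sum of squared errors (SSEbc)
#'
#' The biclustering objective: for every cell, the sum of squared deviations
#' of the observed entries from the cell's observed mean, summed over all
#' cells.  Cells with no observed entry contribute 0.  Adding an unobserved
#' cell never changes the value, and the value is invariant under relabeling
#' of clusters.
#'
#' @param x a [phenotype_table()] (typically a transformed response, see
#'   [gei_response()]).
#' @param partition a [gei_partition()] matching the table.
#' @return Nonnegative scalar in squared response units.
#' @export
sse_bc <- function(x, partition) {
  check_partition(x, partition)
  cs <- cell_stats(x, partition)
  pos <- cs$N > 0
  # the difference form can dip a hair below zero in floating point
  max(0, sum(cs$Q[pos]) - sum(cs$S[pos]^2 / cs$N[pos]))
}

# One full sweep of sequential exact best moves: every row, then every
# column, is moved (one at a time, with cell sums updated after each move) to
# the cluster that most decreases SSEbc; ties go to the lowest cluster index,
# and a move that would empty its source cluster is not considered.  Each
# accepted move is exactly evaluated, so SSEbc is non-increasing move by move
# and hence sweep by sweep.
h_gain <- function(S, N) {
  # "explained" sum Sigma S^2/N; SSEbc = TQ - h
  out <- S^2 / N
  out[N == 0] <- 0
  out
}

bicluster_run <- function(Y, W, n, m, rowc, colc, max_iter, tol) {
  I <- nrow(Y)
  J <- ncol(Y)
  YW <- Y * W
  Q <- YW * Y
  TQ <- sum(Q)
  agg_cols <- function() {
    Cm <- outer(colc, seq_len(m), "==") + 0
    list(SY = YW %*% Cm, SN = W %*% Cm) # I x m
  }
  agg_rows <- function() {
    Rm <- outer(seq_len(n), rowc, "==") + 0
    list(SY = t(Rm %*% YW), SN = t(Rm %*% W)) # J x n
  }
  cellS <- function() {
    Rm <- outer(seq_len(n), rowc, "==") + 0
    Cm <- outer(colc, seq_len(m), "==") + 0
    list(S = Rm %*% YW %*% Cm, N = Rm %*% W %*% Cm)
  }
  cs <- cellS()
  S <- cs$S
  N <- cs$N
  obj <- function() max(0, TQ - sum(h_gain(S, N)))
  sweep_axis <- function(axis) {
    # axis 1: move rows against column-cluster profiles; axis 2: columns.
    if (axis == 1L) {
      prof <- agg_cols()
      nk <- n
      assign_vec <- rowc
    } else {
      prof <- agg_rows()
      nk <- m
      assign_vec <- colc
    }
    sizes <- tabulate(assign_vec, nk)
    changed <- FALSE
    for (i in seq_along(assign_vec)) {
      a <- assign_vec[i]
      if (sizes[a] <= 1L) next
      s_i <- prof$SY[i, ]
      n_i <- prof$SN[i, ]
      if (axis == 1L) {
        Sadd <- sweep(S, 2L, s_i, `+`)
        Nadd <- sweep(N, 2L, n_i, `+`)
        base <- rowSums(h_gain(S, N))
        gain_add <- rowSums(h_gain(Sadd, Nadd)) - base
        rem <- sum(h_gain(S[a, ] - s_i, N[a, ] - n_i)) -
          sum(h_gain(S[a, ], N[a, ]))
      } else {
        Sadd <- S + matrix(s_i, n, m)
        Nadd <- N + matrix(n_i, n, m)
        base <- colSums(h_gain(S, N))
        gain_add <- colSums(h_gain(Sadd, Nadd)) - base
        rem <- sum(h_gain(S[, a] - s_i, N[, a] - n_i)) -
          sum(h_gain(S[, a], N[, a]))
      }
      # score[p]: increase in explained h from moving item i to cluster p
      # (staying put scores exactly 0); ties -> lowest cluster index
      score <- gain_add + rem
      score[a] <- 0
      p <- which(score == max(score))[1L]
      if (p != a) {
        if (axis == 1L) {
          S[a, ] <- S[a, ] - s_i
          N[a, ] <- N[a, ] - n_i
          S[p, ] <- S[p, ] + s_i
          N[p, ] <- N[p, ] + n_i
        } else {
          S[, a] <- S[, a] - s_i
          N[, a] <- N[, a] - n_i
          S[, p] <- S[, p] + s_i
          N[, p] <- N[, p] + n_i
        }
        sizes[a] <- sizes[a] - 1L
        sizes[p] <- sizes[p] + 1L
        assign_vec[i] <- p
        changed <- TRUE
      }
    }
    if (axis == 1L) rowc <<- assign_vec else colc <<- assign_vec
    S <<- S
    N <<- N
    changed
  }
  trace <- obj()
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    ch1 <- sweep_axis(1L)
    ch2 <- sweep_axis(2L)
    cur <- obj()
    prev <- trace[length(trace)]
    trace <- c(trace, cur)
    if (!ch1 && !ch2) {
      converged <- TRUE
      break
    }
    if (prev > 0 && (prev - cur) / prev < tol) {
      converged <- TRUE
      break
    }
  }
  list(rowc = rowc, colc = colc, sse = trace[length(trace)],
       iterations = iter, converged = converged, sse_trace = trace)
}

random_assignment <- function(k, len) {
  # uniform given every cluster nonempty: first k shuffled items pin 1..k
  a <- integer(len)
  perm <- sample.int(len)
  a[perm[seq_len(k)]] <- seq_len(k)
  if (len > k) a[perm[(k + 1L):len]] <- sample.int(k, len - k, replace = TRUE)
  a
}

#' Bicluster a phenotype table by alternating least squares
#'
#' Minimizes [sse_bc()] over partitions of genotypes into `n` clusters and
#' environments into `m` clusters.  Rows and columns are seeded uniformly at
#' random (every cluster nonempty), then sweeps of sequential exact
#' best-moves alternate over rows and columns: each row (column) is moved to
#' the cluster that most decreases the objective, with cell statistics
#' updated after every accepted move, so the objective is non-increasing
#' throughout.  Moves that would empty their source cluster are skipped and
#' zero-gain ties resolve to the lowest cluster index, making a run fully
#' deterministic given its seed.  The algorithm converges to a local optimum;
#' use [best_bicluster()] for random restarts.
#'
#' @inheritParams sse_bc
#' @param n,m row and column cluster counts.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of full sweeps (default 100).
#' @param tol stop when the relative objective decrease over a sweep falls
#'   below this (default 1e-8).
#' @return An object of class `gei_bicluster`: `partition`
#'   ([gei_partition()]), `sse_bc`, `iterations`, `converged`, `seed`,
#'   `response_kind` (attribute of `x` if it was produced by
#'   [gei_response()]), `sse_trace` (objective after each sweep) and
#'   `n_empty_cells`.
#' @export
bicluster <- function(x, n, m, seed = 1L, max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(x, "phenotype_table"))
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L || n > nrow(x)) stop("n must be in 1..", nrow(x))
  if (m < 1L || m > ncol(x)) stop("m must be in 1..", ncol(x))
  W <- (!is.na(x)) + 0
  Y <- unclass(x)
  Y[W == 0] <- 0
  init <- with_seed(seed, list(
    rowc = random_assignment(n, nrow(x)),
    colc = random_assignment(m, ncol(x))
  ))
  run <- bicluster_run(Y, W, n, m, init$rowc, init$colc, max_iter, tol)
  part <- gei_partition(run$rowc, run$colc, n, m)
  cs <- cell_stats(x, part)
  structure(list(
    partition = part,
    sse_bc = run$sse,
    iterations = run$iterations,
    converged = run$converged,
    seed = as.integer(seed),
    response_kind = attr(x, "response_kind", exact = TRUE),
    sse_trace = run$sse_trace,
    n_empty_cells = sum(cs$N == 0)
  ), class = "gei_bicluster")
}

#' @export
print.gei_bicluster <- function(x, ...) {
  cat(sprintf(
    "gei_bicluster: %d x %d clusters, SSEbc = %.6g (%d sweeps, %s, seed %d)\n",
    x$partition$n, x$partition$m, x$sse_bc, x$iterations,
    if (x$converged) "converged" else "max_iter reached", x$seed
  ))
  invisible(x)
}

#' Best biclustering over random restarts
#'
#' Runs [bicluster()] with seeds `base_seed .. base_seed + trials - 1` and
#' returns the run with the smallest SSEbc; ties break to the lowest seed.
#' The local search converges to a local optimum, so in practice one keeps
#' the best of a batch of restarts (30 by default).
#'
#' @inheritParams bicluster
#' @param trials number of restarts (default 30).
#' @param base_seed seed of the first restart.
#' @return The winning `gei_bicluster`.
#' @export
best_bicluster <- function(x, n, m, trials = 30L, base_seed = 1L,
                           max_iter = 100L, tol = 1e-8) {
  trials <- as.integer(trials)
  if (trials < 1L) stop("trials must be >= 1")
  best <- NULL
  for (s in base_seed + seq_len(trials) - 1L) {
    cand <- bicluster(x, n, m, seed = s, max_iter = max_iter, tol = tol)
    if (is.null(best) || cand$sse_bc < best$sse_bc) best <- cand
  }
  best
}

# All set partitions of 1..len into exactly k nonempty blocks, as restricted
# growth strings (canonical labels: block of element 1 is 1, etc.).
set_partitions_k <- function(len, k) {
  out <- list()
  a <- integer(len)
  recurse <- function(i, used) {
    if (len - i + 1L < k - used) return()
    if (i > len) {
      if (used == k) out[[length(out) + 1L]] <<- a
      return()
    }
    for (b in seq_len(min(used + 1L, k))) {
      a[i] <<- b
      recurse(i + 1L, max(used, b))
    }
  }
  recurse(1L, 0L)
  out
}

stirling2 <- function(n, k) {
  if (k == 0) return(as.numeric(n == 0))
  S <- matrix(0, n + 1, k + 1)
  S[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      S[i + 1, j + 1] <- j * S[i, j + 1] + S[i, j]
    }
  }
  S[n + 1, k + 1]
}

#' Exhaustive biclustering oracle for tiny tables
#'
#' Enumerates every partition of the rows into exactly `n` nonempty clusters
#' and of the columns into `m` nonempty clusters, and returns a global
#' minimizer of [sse_bc()].  Finding the optimum is NP-hard in general, so
#' the enumeration is guarded: the product of the two Stirling partition
#' counts must not exceed `limit`.  Intended as an independent test oracle
#' for [bicluster()] / [best_bicluster()].
#'
#' @inheritParams bicluster
#' @param limit maximum number of row-partition x column-partition
#'   combinations (default 1e6).
#' @return A `gei_bicluster` (with `seed = NA` and a single "iteration").
#' @export
exhaustive_bicluster <- function(x, n, m, limit = 1e6) {
  stopifnot(inherits(x, "phenotype_table"))
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L || n > nrow(x)) stop("n must be in 1..", nrow(x))
  if (m < 1L || m > ncol(x)) stop("m must be in 1..", ncol(x))
  n_comb <- stirling2(nrow(x), n) * stirling2(ncol(x), m)
  if (n_comb > limit) {
    stop("instance too large for exhaustive search: ", format(n_comb),
         " combinations exceed the limit of ", format(limit))
  }
  row_parts <- set_partitions_k(nrow(x), n)
  col_parts <- set_partitions_k(ncol(x), m)
  best <- Inf
  best_rp <- NULL
  best_cp <- NULL
  for (rp in row_parts) {
    for (cp in col_parts) {
      v <- sse_bc(x, gei_partition(rp, cp, n, m))
      if (v < best) {
        best <- v
        best_rp <- rp
        best_cp <- cp
      }
    }
  }
  structure(list(
    partition = gei_partition(best_rp, best_cp, n, m),
    sse_bc = best,
    iterations = 1L,
    converged = TRUE,
    seed = NA_integer_,
    response_kind = attr(x, "response_kind", exact = TRUE),
    sse_trace = best,
    n_empty_cells = NA_integer_
  ), class = "gei_bicluster")
}
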