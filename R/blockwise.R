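#' Blockwise no-interaction model
#'
#' The headline model: a separate additive (no-interaction) fit
#' \eqn{\mu_{ij} = \mu + G_i + \tilde E_j^p + \epsilon_{ij}} on the *raw*
#' phenotype inside every cell of a partition, where \eqn{\tilde E_j^p = E_j
#' + GEI_j^p} is the environment effect local to row cluster p.  The total
#' within-cell error summed over cells is SSEni, the model-selection metric.
#'
#' With missing-not-at-random data a cell's observed submatrix may be
#' disconnected; each connected component is then fitted separately (no
#' imputation, no cross-cell borrowing) and the cell's SSE and df sum over
#' its components: `df = n_observed - n_estimable_parameters`.  Saturated
#' cells (df 0) are legal and simply contribute SSE 0.  Setting `n = m = 1`
#' reproduces the global additive model; `n = |I|`, `m = |J|` reproduces the
#' cell-means model (SSEni 0).
#'
#' @inheritParams sse_bc
#' @return An object of class `gei_blockwise`: `partition`, `cells` (a data
#'   frame with one row per cell: `row_cluster`, `col_cluster`,
#'   `n_genotypes`, `n_environments`, `n_obs`, `n_components`, `sse`, `df`),
#'   `cell_fits` (per-cell component fits with `mu`, `g_effects`, and the
#'   block environment effects `e_tilde`), `sse_ni` and `df_ni`.
#' @export
fit_blockwise <- function(x, partition) {
  check_partition(x, partition)
  obs <- which(!is.na(x), arr.ind = TRUE)
  y <- x[obs]
  rp <- partition$rows[obs[, 1]]
  cp <- partition$cols[obs[, 2]]
  cells <- vector("list", partition$n * partition$m)
  cell_fits <- vector("list", partition$n * partition$m)
  k <- 0L
  sse_ni <- 0
  df_ni <- 0L
  for (p in seq_len(partition$n)) {
    gen_in <- which(partition$rows == p)
    for (l in seq_len(partition$m)) {
      env_in <- which(partition$cols == l)
      k <- k + 1L
      sel <- which(rp == p & cp == l)
      if (length(sel) == 0L) {
        cells[[k]] <- data.frame(
          row_cluster = p, col_cluster = l,
          n_genotypes = length(gen_in), n_environments = length(env_in),
          n_obs = 0L, n_components = 0L, sse = 0, df = 0L
        )
        cell_fits[[k]] <- list(row_cluster = p, col_cluster = l,
                               components = list())
        next
      }
      gi <- match(obs[sel, 1], gen_in)
      ei <- match(obs[sel, 2], env_in)
      fit <- additive_lsq(gi, ei, y[sel], length(gen_in), length(env_in))
      comps <- lapply(fit$components, function(cc) {
        list(
          genotypes = rownames(x)[gen_in[cc$genotypes]],
          environments = colnames(x)[env_in[cc$environments]],
          mu = cc$mu,
          g_effects = stats::setNames(cc$g_effects,
                                      rownames(x)[gen_in[cc$genotypes]]),
          e_tilde = stats::setNames(cc$e_effects,
                                    colnames(x)[env_in[cc$environments]])
        )
      })
      cells[[k]] <- data.frame(
        row_cluster = p, col_cluster = l,
        n_genotypes = length(gen_in), n_environments = length(env_in),
        n_obs = length(sel), n_components = fit$n_comp,
        sse = fit$sse, df = fit$df
      )
      cell_fits[[k]] <- list(row_cluster = p, col_cluster = l,
                             components = comps)
      sse_ni <- sse_ni + fit$sse
      df_ni <- df_ni + fit$df
    }
  }
  structure(list(
    partition = partition,
    genotypes = rownames(x),
    environments = colnames(x),
    cells = do.call(rbind, cells),
    cell_fits = cell_fits,
    sse_ni = sse_ni,
    df_ni = df_ni
  ), class = "gei_blockwise")
}

#' @export
print.gei_blockwise <- function(x, ...) {
  cat(sprintf(
    "gei_blockwise: %d x %d cells, SSEni = %.6g on %d df\n",
    x$partition$n, x$partition$m, x$sse_ni, x$df_ni
  ))
  invisible(x)
}

#' Predict a phenotype from a blockwise model
#'
#' Locates the unique cell containing (genotype, environment) and returns
#' \eqn{\hat\mu + \hat G_i + \hat{\tilde E}_j} from that cell's fit.  The
#' prediction is available only when the genotype and the environment each
#' have at least one observation inside the *same* connected component of the
#' cell; otherwise `NA` is returned (an explicit "unavailable" — the model
#' never silently borrows effects across cells or components).
#'
#' @param object a `gei_blockwise` model.
#' @param genotype,environment labels (single strings).
#' @param ... unused.
#' @return Scalar prediction, or `NA_real_` when inestimable.
#' @export
predict.gei_blockwise <- function(object, genotype, environment, ...) {
  gi <- match(genotype, object$genotypes)
  ei <- match(environment, object$environments)
  if (is.na(gi)) stop("unknown genotype: ", genotype)
  if (is.na(ei)) stop("unknown environment: ", environment)
  p <- object$partition$rows[gi]
  l <- object$partition$cols[ei]
  k <- (p - 1L) * object$partition$m + l
  for (cc in object$cell_fits[[k]]$components) {
    if (genotype %in% cc$genotypes && environment %in% cc$environments) {
      return(unname(cc$mu + cc$g_effects[genotype] + cc$e_tilde[environment]))
    }
  }
  NA_real_
}
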