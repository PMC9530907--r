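# Core additive least-squares machinery: fit mu + G_i + E_j to observed
# (genotype, environment, value) triples, one fit per connected component of
# the observed bipartite graph.  Used by the global benchmark models and by
# the per-cell blockwise fits.

# gi, ei: integer level indices in 1..ng / 1..ne; y: values.
# Within a connected component the additive two-way design has rank
# (r + c - 1), so df = n_obs - r - c + 1 there; the rank from the QR is used
# anyway as a guard.  Effects are reported per component under unweighted
# sum-to-zero constraints over the levels present in that component.
additive_lsq <- function(gi, ei, y, ng, ne) {
  comp <- bipartite_components(gi, ei, ng, ne)
  obs_comp <- comp$g_comp[gi]
  fitted <- numeric(length(y))
  sse <- 0
  df <- 0L
  components <- vector("list", comp$n_comp)
  for (cid in seq_len(comp$n_comp)) {
    sel <- which(obs_comp == cid)
    gl <- sort(unique(gi[sel]))
    el <- sort(unique(ei[sel]))
    gf <- factor(gi[sel], levels = gl)
    ef <- factor(ei[sel], levels = el)
    yv <- y[sel]
    kg <- length(gl) - 1L
    ke <- length(el) - 1L
    X <- matrix(1, length(yv), 1L)
    if (kg > 0L) X <- cbind(X, stats::model.matrix(~gf)[, -1L, drop = FALSE])
    if (ke > 0L) X <- cbind(X, stats::model.matrix(~ef)[, -1L, drop = FALSE])
    fit <- stats::lm.fit(X, yv)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    fv <- fit$fitted.values
    rank <- fit$rank
    b0 <- cf[1L]
    bg <- stats::setNames(c(0, cf[1L + seq_len(kg)]), gl)
    be <- stats::setNames(c(0, cf[1L + kg + seq_len(ke)]), el)
    mu <- b0 + mean(bg) + mean(be)
    components[[cid]] <- list(
      genotypes = gl,
      environments = el,
      mu = unname(mu),
      g_effects = bg - mean(bg),
      e_effects = be - mean(be)
    )
    fitted[sel] <- fv
    sse <- sse + sum((yv - fv)^2)
    df <- df + length(sel) - rank
  }
  list(
    sse = sse, df = as.integer(df), fitted = fitted,
    components = components, n_comp = comp$n_comp,
    g_comp = comp$g_comp, e_comp = comp$e_comp
  )
}

# Convenience: additive fit of the observed cells of a phenotype_table.
additive_lsq_table <- function(x) {
  obs <- which(!is.na(x), arr.ind = TRUE)
  additive_lsq(obs[, 1], obs[, 2], x[obs], nrow(x), ncol(x))
}
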