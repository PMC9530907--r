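# Benchmark models for GEI on a two-way table of means: additive
# (no-interaction), cell means (all-interaction), Finlay-Wilkinson regression
# on the mean, and AMMI.  Each carries a sequential (Type I) ANOVA table with
# genotypes entered before environments.

new_anova_table <- function(term, df, ss, model) {
  structure(
    data.frame(term = term, df = as.integer(df), ss = as.numeric(ss),
               stringsAsFactors = FALSE),
    class = c("gei_anova", "data.frame"), model = model
  )
}

#' @export
print.gei_anova <- function(x, ...) {
  cat("**", attr(x, "model"), "**\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-10s %6d  %s\n", x$term[i], x$df[i],
                format(x$ss[i], big.mark = ",", digits = 10)))
  }
  invisible(x)
}

# Sequential sums of squares shared by all benchmark models: SS(G) and SS(E)
# from nested SSE differences, with G entered first.
sequential_main_effects <- function(x) {
  if (!is_connected(x)) {
    stop("observed-cell pattern is disconnected; global additive effects are not estimable")
  }
  obs <- which(!is.na(x), arr.ind = TRUE)
  y <- x[obs]
  n_obs <- length(y)
  sse_mu <- sum((y - mean(y))^2)
  rm <- rowMeans(x, na.rm = TRUE)
  sse_mu_g <- sum((y - rm[obs[, 1]])^2)
  full <- additive_lsq(obs[, 1], obs[, 2], y, nrow(x), ncol(x))
  list(
    obs = obs, y = y, n_obs = n_obs,
    ss_g = sse_mu - sse_mu_g,
    ss_e = sse_mu_g - full$sse,
    df_g = nrow(x) - 1L,
    df_e = ncol(x) - 1L,
    full = full
  )
}

#' Additive (no-interaction) model
#'
#' Least-squares fit of \eqn{\mu_{ij} = \mu + G_i + E_j + \epsilon_{ij}} over
#' the observed cells, with unweighted sum-to-zero constraints on the
#' genotype and environment effects.  The ANOVA is sequential (Type I) with G
#' entered before E, matching the conventional presentation; on complete data
#' the order does not matter.  Error df is
#' `n_obs - (n_genotypes - 1) - (n_environments - 1) - 1`.
#'
#' @param x a [phenotype_table()]; its observed pattern must be connected
#'   (see [is_connected()]).
#' @return An object of class `gei_additive` with elements `mu`, `g_effects`,
#'   `e_effects`, `fitted` and `residuals` (matrices with `NA` at unobserved
#'   cells), `sse`, `df`, and `anova` (a `gei_anova` table with rows G, E,
#'   Error).
#' @export
fit_additive <- function(x) {
  stopifnot(inherits(x, "phenotype_table"))
  sq <- sequential_main_effects(x)
  full <- sq$full
  comp <- full$components[[1L]]
  g_eff <- stats::setNames(comp$g_effects[as.character(seq_len(nrow(x)))],
                           rownames(x))
  e_eff <- stats::setNames(comp$e_effects[as.character(seq_len(ncol(x)))],
                           colnames(x))
  fitted <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  fitted[sq$obs] <- full$fitted
  residuals <- unclass(x) - fitted
  err_df <- sq$n_obs - sq$df_g - sq$df_e - 1L
  structure(list(
    mu = comp$mu, g_effects = g_eff, e_effects = e_eff,
    fitted = fitted, residuals = residuals,
    sse = full$sse, df = as.integer(err_df),
    anova = new_anova_table(
      c("G", "E", "Error"),
      c(sq$df_g, sq$df_e, err_df),
      c(sq$ss_g, sq$ss_e, full$sse),
      "No-interaction model"
    )
  ), class = "gei_additive")
}

#' @export
print.gei_additive <- function(x, ...) {
  print(x$anova)
  invisible(x)
}

#' Cell-means (all-interaction) model
#'
#' One free parameter per observed cell: on a table of means the model fits
#' every observed cell exactly, so the GEI row absorbs the additive model's
#' Error df and SS and the Error row is (0, 0).
#'
#' @inheritParams fit_additive
#' @return A `gei_anova` table with rows G, E, GEI, Error.
#' @export
fit_cell_means <- function(x) {
  add <- fit_additive(x)
  a <- add$anova
  new_anova_table(
    c("G", "E", "GEI", "Error"),
    c(a$df[1:2], add$df, 0L),
    c(a$ss[1:2], add$sse, 0),
    "All-interaction model"
  )
}

#' Finlay-Wilkinson regression on the mean
#'
#' Two-stage fit of \eqn{\mu_{ij} = \mu + G_i + E_j + b_i E_j +
#' \epsilon_{ij}}: the additive model is fitted first, then for each genotype
#' the slope \eqn{b_i} is the OLS slope of that genotype's additive residuals
#' on the estimated environment effects \eqn{\hat E_j} over its observed
#' environments (so \eqn{b_i = 0} means average stability).  The "GEI Ind"
#' row carries \eqn{\sum_i b_i^2 \sum_j \hat E_j^2} on
#' `n_genotypes - 1` df; its Error row is the additive Error minus that.
#' Genotypes observed in fewer than two environments get slope 0 and are
#' listed in `inestimable`.
#'
#' @inheritParams fit_additive
#' @return An object of class `gei_fw` with `slopes` (named vector of b_i),
#'   `inestimable` (labels with pinned zero slopes), `sse`, `df`, and `anova`
#'   (rows G, E, GEI Ind, Error).
#' @export
fit_finlay_wilkinson <- function(x) {
  add <- fit_additive(x)
  e_hat <- add$e_effects
  slopes <- stats::setNames(numeric(nrow(x)), rownames(x))
  inest <- character(0)
  ss_reg <- 0
  sse <- 0
  for (i in seq_len(nrow(x))) {
    j <- which(!is.na(x[i, ]))
    r <- add$residuals[i, j]
    ej <- e_hat[j]
    den <- sum(ej^2)
    if (length(j) < 2L || den == 0) {
      inest <- c(inest, rownames(x)[i])
      sse <- sse + sum(r^2)
      next
    }
    b <- sum(r * ej) / den
    slopes[i] <- b
    ss_reg <- ss_reg + b^2 * den
    sse <- sse + sum((r - b * ej)^2)
  }
  a <- add$anova
  df_ind <- nrow(x) - 1L
  structure(list(
    slopes = slopes, inestimable = inest,
    sse = sse, df = as.integer(add$df - df_ind),
    anova = new_anova_table(
      c("G", "E", "GEI Ind", "Error"),
      c(a$df[1:2], df_ind, add$df - df_ind),
      c(a$ss[1:2], ss_reg, sse),
      "Regression on mean model"
    )
  ), class = "gei_fw")
}

#' @export
print.gei_fw <- function(x, ...) {
  print(x$anova)
  invisible(x)
}

#' Gollob degrees of freedom for an AMMI multiplicative term
#'
#' The k-th multiplicative term of an AMMI model with `g` genotypes and `e`
#' environments is assigned `g + e - 1 - 2k` degrees of freedom.
#'
#' @param g,e numbers of genotypes and environments.
#' @param k term index, `1 <= k <= min(g - 1, e - 1)`.
#' @return Integer degrees of freedom.
#' @export
#' @examples
#' gollob_df(237, 7, 1) # 241
gollob_df <- function(g, e, k) {
  g <- as.integer(g); e <- as.integer(e); k <- as.integer(k)
  if (any(k < 1L) || any(k > min(g - 1L, e - 1L))) {
    stop("k must be between 1 and min(g - 1, e - 1)")
  }
  g + e - 1L - 2L * k
}

#' AMMI: additive main effects and multiplicative interactions
#'
#' Fits \eqn{\mu_{ij} = \mu + G_i + E_j + \sum_{k=1}^K b_{ik} z_{jk} +
#' \epsilon_{ij}}.  The additive residuals are assembled into a full
#' genotype-by-environment matrix with unobserved positions set to 0 (their
#' conditional expectation under the additive model), the singular value
#' decomposition is taken, and term k's sum of squares is the squared rank-1
#' component evaluated over the observed cells.  ANOVA rows PC1..PCK carry
#' Gollob df ([gollob_df()]); the Error row is the additive Error minus the
#' multiplicative terms.  On complete data `term_ss[k]` equals the k-th
#' squared singular value.
#'
#' @inheritParams fit_additive
#' @param k number of multiplicative terms,
#'   `1 <= k <= min(n_genotypes - 1, n_environments - 1)`.
#' @return An object of class `gei_ammi` with `k`, `genotype_scores` and
#'   `environment_scores` (columns scaled by the square root of the singular
#'   value), `term_ss`, `sse`, `df`, and `anova` (rows G, E, PC1..PCk,
#'   Error).
#' @export
fit_ammi <- function(x, k = 2L) {
  add <- fit_additive(x)
  k <- as.integer(k)
  kmax <- min(nrow(x) - 1L, ncol(x) - 1L)
  if (length(k) != 1L || is.na(k) || k < 1L || k > kmax) {
    stop("k must be between 1 and min(g - 1, e - 1) = ", kmax)
  }
  R <- add$residuals
  R[is.na(R)] <- 0
  sv <- svd(R, nu = k, nv = k)
  obs <- !is.na(x)
  term_ss <- numeric(k)
  for (t in seq_len(k)) {
    comp_t <- sv$d[t] * tcrossprod(sv$u[, t], sv$v[, t])
    term_ss[t] <- sum(comp_t[obs]^2)
  }
  pc_df <- gollob_df(nrow(x), ncol(x), seq_len(k))
  err_ss <- add$sse - sum(term_ss)
  if (err_ss < 0) {
    if (abs(err_ss) < 1e-8 * add$sse) err_ss <- 0
    else stop("negative AMMI error sum of squares: inconsistent input")
  }
  err_df <- add$df - sum(pc_df)
  a <- add$anova
  scale_d <- sqrt(sv$d[seq_len(k)])
  structure(list(
    k = k,
    genotype_scores = sweep(sv$u, 2L, scale_d, `*`),
    environment_scores = sweep(sv$v, 2L, scale_d, `*`),
    term_ss = term_ss,
    sse = err_ss, df = as.integer(err_df),
    anova = new_anova_table(
      c("G", "E", paste0("PC", seq_len(k)), "Error"),
      c(a$df[1:2], pc_df, err_df),
      c(a$ss[1:2], term_ss, err_ss),
      "AMMI model"
    )
  ), class = "gei_ammi")
}

#' @export
print.gei_ammi <- function(x, ...) {
  print(x$anova)
  invisible(x)
}

#' Render stacked ANOVA tables as text or JSON
#'
#' Emits the benchmark-model ANOVA blocks in their printed order — df as
#' integers, SS both at full precision and with a human-readable rounding.
#'
#' @param fits nonempty list of `gei_anova` tables (or of fitted model
#'   objects carrying an `$anova` element).
#' @param format `"text"` or `"json"`.
#' @return A character scalar (text) or JSON string.
#' @export
render_anova_report <- function(fits, format = c("text", "json")) {
  format <- match.arg(format)
  if (length(fits) == 0L) stop("no ANOVA tables to render")
  fits <- lapply(fits, function(f) {
    if (inherits(f, "gei_anova")) f
    else if (!is.null(f$anova) && inherits(f$anova, "gei_anova")) f$anova
    else stop("not an ANOVA table or fitted model")
  })
  if (format == "text") {
    out <- character(0)
    for (a in fits) {
      out <- c(out, paste0("**", attr(a, "model"), "**"))
      out <- c(out, sprintf("%-10s %6d  %s", a$term, a$df,
                            format(round(a$ss), big.mark = ",", scientific = FALSE)))
    }
    paste(out, collapse = "\n")
  } else {
    blocks <- lapply(fits, function(a) {
      list(model = attr(a, "model"),
           rows = lapply(seq_len(nrow(a)), function(i) {
             list(term = a$term[i], df = a$df[i], ss = a$ss[i],
                  ss_rounded = round(a$ss[i]))
           }))
    })
    as.character(jsonlite::toJSON(blocks, auto_unbox = TRUE, digits = NA))
  }
}
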