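#' Specification for a synthetic phenotype table
#'
#' Describes a simulated multi-environment trial: additive genotype and
#' environment main effects plus block-structured GEI, Gaussian noise, and
#' optionally missing cells — uniformly at random or cluster-structured
#' missing-not-at-random (each genotype cluster is simply never trialed in
#' some environments, emulating breeder decisions and maturity matching).
#'
#' Defaults describe a trial of 60 genotypes in 12 environments with a
#' planted 3 x 3 block structure, phenotype on a growing-degree-day-like
#' scale (`mu = 1500`, `sd_g = 60`, `sd_e = 150`), GEI block scale 50 against
#' noise 10 (signal-to-noise 5), and 30% cluster-MNAR missingness.
#'
#' @param n_genotypes,n_environments table dimensions.
#' @param n_row_clusters,n_col_clusters planted cluster counts.
#' @param mu overall mean (phenotype units).
#' @param sd_g,sd_e standard deviations of the genotype and environment main
#'   effects (draws are centered, so sum-to-zero holds exactly).
#' @param gei_mode `"cell_constant"`: one GEI value per (row-cluster,
#'   column-cluster) cell, double-centered across the cluster grid — the
#'   homogeneous-cell structure; `"column_within_block"`: one GEI value per
#'   (row-cluster, environment), double-centered — the weaker structure where
#'   GEI within a block depends on the environment, so a no-interaction model
#'   still fits each cell exactly via the block environment effect.
#' @param gei_scale standard deviation of the planted GEI values.
#' @param noise_sd standard deviation of the i.i.d. Gaussian error.
#' @param missing_mechanism `"none"`, `"uniform"`, or `"cluster_mnar"`.
#' @param missing_rate target fraction of missing cells in `[0, 1)`.
#' @param seed integer seed; the same spec always generates the same table.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_genotypes = 60L, n_environments = 12L,
                           n_row_clusters = 3L, n_col_clusters = 3L,
                           mu = 1500, sd_g = 60, sd_e = 150,
                           gei_mode = c("cell_constant", "column_within_block"),
                           gei_scale = 50, noise_sd = 10,
                           missing_mechanism = c("cluster_mnar", "uniform", "none"),
                           missing_rate = 0.3, seed = 1L) {
  spec <- list(
    n_genotypes = as.integer(n_genotypes),
    n_environments = as.integer(n_environments),
    n_row_clusters = as.integer(n_row_clusters),
    n_col_clusters = as.integer(n_col_clusters),
    mu = mu, sd_g = sd_g, sd_e = sd_e,
    gei_mode = match.arg(gei_mode),
    gei_scale = gei_scale, noise_sd = noise_sd,
    missing_mechanism = match.arg(missing_mechanism),
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  if (spec$n_row_clusters < 1L || spec$n_row_clusters > spec$n_genotypes) {
    stop("n_row_clusters must be in 1..n_genotypes")
  }
  if (spec$n_col_clusters < 1L || spec$n_col_clusters > spec$n_environments) {
    stop("n_col_clusters must be in 1..n_environments")
  }
  if (spec$missing_rate < 0 || spec$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (spec$sd_g < 0 || spec$sd_e < 0 || spec$gei_scale < 0 || spec$noise_sd < 0) {
    stop("scales must be nonnegative")
  }
  if (spec$missing_mechanism == "none") spec$missing_rate <- 0
  structure(spec, class = "synthetic_spec")
}

double_center <- function(M) {
  M - rowMeans(M) - rep(colMeans(M), each = nrow(M)) + mean(M)
}

#' Generate a synthetic phenotype table with known structure
#'
#' Draws values \eqn{\mu + G_i + E_j + GEI_{ij} + \epsilon_{ij}} according to
#' a [synthetic_spec()] and applies the missingness mechanism.  Under
#' `cluster_mnar`, each genotype cluster drops one whole cluster-specific
#' "mismatch" environment cluster (sampled without replacement across
#' genotype clusters while possible) with a probability that keeps the
#' expected structured fraction at `missing_rate`, and independent dropout
#' tops the realized missingness up to `missing_rate` when the drawn blocks
#' fall short of it.  If the
#' mask leaves any genotype or environment with no observation, the mask
#' (only) is redrawn, up to 100 attempts, after which the rate is deemed
#' infeasible.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `table` (a [phenotype_table()]) and `truth`: the
#'   planted [gei_partition()], `mu`, `g_effects`, `e_effects`, `gei` (the
#'   full GEI matrix), and `expected` (the noise-free complete value matrix).
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ng <- spec$n_genotypes
  ne <- spec$n_environments
  n <- spec$n_row_clusters
  m <- spec$n_col_clusters
  with_seed(spec$seed, {
    row_cl <- sample(rep_len(seq_len(n), ng))
    col_cl <- sample(rep_len(seq_len(m), ne))
    g <- stats::rnorm(ng, 0, spec$sd_g)
    g <- g - mean(g)
    e <- stats::rnorm(ne, 0, spec$sd_e)
    e <- e - mean(e)
    if (spec$gei_mode == "cell_constant") {
      gamma <- matrix(stats::rnorm(n * m, 0, spec$gei_scale), n, m)
      if (n > 1L || m > 1L) gamma <- double_center(gamma)
      gei <- gamma[cbind(rep(row_cl, ne), rep(col_cl, each = ng))]
    } else {
      gamma <- matrix(stats::rnorm(n * ne, 0, spec$gei_scale), n, ne)
      if (n > 1L || ne > 1L) gamma <- double_center(gamma)
      gei <- gamma[cbind(rep(row_cl, ne), rep(seq_len(ne), each = ng))]
    }
    gei <- matrix(gei, ng, ne)
    expected <- spec$mu + outer(g, e, `+`) + gei
    values <- expected + matrix(stats::rnorm(ng * ne, 0, spec$noise_sd), ng, ne)
    mask <- make_missing_mask(spec, row_cl, col_cl)
    vals <- values
    vals[!mask] <- NA_real_
    tab <- phenotype_table(vals)
    list(
      table = tab,
      truth = list(
        partition = gei_partition(row_cl, col_cl, n, m),
        mu = spec$mu,
        g_effects = stats::setNames(g, rownames(tab)),
        e_effects = stats::setNames(e, colnames(tab)),
        gei = gei,
        expected = expected
      )
    )
  })
}

# TRUE = observed.  Uses the current RNG stream (inside generate_table's seed
# scope).  Redraws until every row and column keeps an observation.
#
# cluster_mnar drops, for each genotype cluster, one whole cluster-specific
# "mismatch" environment cluster (the maturity-zone mechanism: a variety
# group is never trialed in the class of environments it does not suit),
# sampled without replacement across genotype clusters while possible.  If
# the structured fraction falls short of missing_rate, independent dropout
# tops it up; if it already meets the rate, no dropout is added and the
# realized missingness is the nearest value the block granularity allows.
# Dropping arbitrary environment subsets instead would shift each dropped
# environment's observed-cell margin by about half its cell's GEI value -
# an artifact of computing margins on the incomplete table that grows with
# the GEI signal itself and makes the planted column partition unrecoverable
# in principle (see the methods vignette).
make_missing_mask <- function(spec, row_cl, col_cl) {
  ng <- spec$n_genotypes
  ne <- spec$n_environments
  rate <- spec$missing_rate
  if (spec$missing_mechanism == "none" || rate == 0) {
    return(matrix(TRUE, ng, ne))
  }
  for (attempt in seq_len(100L)) {
    if (spec$missing_mechanism == "uniform") {
      mask <- matrix(stats::runif(ng * ne) >= rate, ng, ne)
    } else {
      n <- spec$n_row_clusters
      m <- spec$n_col_clusters
      mismatch <- if (n <= m) sample.int(m, n)
                  else c(sample.int(m, m), sample.int(m, n - m, replace = TRUE))
      drop_block <- matrix(FALSE, ng, ne)
      for (p in seq_len(n)) {
        zone <- col_cl == mismatch[p]
        # drop the whole zone with a probability that keeps the expected
        # structured fraction at the target rate whatever the granularity
        q <- min(1, rate * ne / sum(zone))
        if (stats::runif(1) < q) drop_block[row_cl == p, zone] <- TRUE
      }
      struct_frac <- mean(drop_block)
      resid_rate <- max(0, (rate - struct_frac) / (1 - struct_frac))
      mask <- matrix(stats::runif(ng * ne) >= resid_rate, ng, ne)
      mask[drop_block] <- FALSE
    }
    if (all(rowSums(mask) > 0) && all(colSums(mask) > 0)) {
      # also require a connected observed pattern, so global additive
      # benchmarks are estimable on every generated table
      obs <- which(mask, arr.ind = TRUE)
      comp <- bipartite_components(obs[, 1], obs[, 2], ng, ne)
      if (comp$n_comp == 1L) return(mask)
    }
  }
  stop("infeasible missing_rate: could not keep every genotype and environment observed and connected")
}

#' Adjusted Rand index between two assignments
#'
#' Chance-corrected agreement between two cluster assignments of the same
#' items: 1 for identical partitions (up to relabeling), about 0 for
#' independent ones.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("assignments differ in length")
  tab <- table(a, b)
  if (nrow(tab) == 1L && ncol(tab) == 1L) return(1)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Partition recovery score
#'
#' Adjusted Rand index of a found partition against the planted truth, per
#' axis.
#'
#' @param found,truth [gei_partition()] objects over the same table
#'   dimensions.
#' @return Named numeric vector `c(row = , col = )`.
#' @export
partition_recovery_score <- function(found, truth) {
  stopifnot(inherits(found, "gei_partition"), inherits(truth, "gei_partition"))
  if (length(found$rows) != length(truth$rows) ||
      length(found$cols) != length(truth$cols)) {
    stop("partitions are over different table dimensions")
  }
  c(row = adjusted_rand_index(found$rows, truth$rows),
    col = adjusted_rand_index(found$cols, truth$cols))
}
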