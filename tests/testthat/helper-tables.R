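# Fixture builders: all fixtures are generated in code at test time.

# Random table with exactly n_missing masked cells, rejected and redrawn until
# every row/column keeps an observation and the observed pattern is connected.
mk_masked_table <- function(ng, ne, n_missing, seed, mean = 100, sd = 10) {
  set.seed(seed)
  repeat {
    vals <- matrix(rnorm(ng * ne, mean, sd), ng, ne)
    if (n_missing > 0) vals[sample(ng * ne, n_missing)] <- NA
    tab <- try(phenotype_table(vals), silent = TRUE)
    if (!inherits(tab, "try-error") && is_connected(tab)) return(tab)
  }
}

# Small random table with a random mask (possibly none); guaranteed valid.
mk_random_table <- function(ng, ne, p_missing = 0.2) {
  repeat {
    vals <- matrix(rnorm(ng * ne), ng, ne)
    vals[runif(ng * ne) < p_missing] <- NA
    tab <- try(phenotype_table(vals), silent = TRUE)
    if (!inherits(tab, "try-error")) return(tab)
  }
}

# Exactly additive complete table mu + g_i + e_j.
mk_additive_table <- function(g, e, mu = 10) {
  phenotype_table(mu + outer(g, e, `+`))
}

expect_partition_equal <- function(a, b) {
  # equality up to cluster relabeling, per axis
  expect_equal(adjusted_rand_index(a$rows, b$rows), 1)
  expect_equal(adjusted_rand_index(a$cols, b$cols), 1)
}
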