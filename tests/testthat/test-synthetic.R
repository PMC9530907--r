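test_that("generation is deterministic in the seed and validates its spec", {
  s <- synthetic_spec(n_genotypes = 20, n_environments = 8, seed = 5)
  a <- generate_table(s)
  b <- generate_table(s)
  expect_identical(unclass(a$table), unclass(b$table))
  expect_identical(a$truth$partition, b$truth$partition)
  expect_error(synthetic_spec(n_row_clusters = 99), "n_row_clusters")
  expect_error(synthetic_spec(missing_rate = 1), "missing_rate")
  expect_error(synthetic_spec(noise_sd = -1), "nonnegative")
})

test_that("uniform missingness hits its target rate", {
  sim <- generate_table(synthetic_spec(
    n_genotypes = 100, n_environments = 10,
    missing_mechanism = "uniform", missing_rate = 0.3, seed = 8
  ))
  frac <- mean(is.na(sim$table))
  expect_lt(abs(frac - 0.3), 0.05)
})

test_that("cluster_mnar removes whole mismatch zones and tops up the rate", {
  sim <- generate_table(synthetic_spec(seed = 12))
  tab <- sim$table
  truth <- sim$truth
  frac <- mean(is.na(tab))
  expect_gt(frac, 0.2)
  expect_lt(frac, 0.45)
  # any (row cluster x column cluster) block that is entirely missing is the
  # signature of a dropped mismatch zone; every row/column keeps data
  expect_true(all(rowSums(!is.na(tab)) > 0))
  expect_true(all(colSums(!is.na(tab)) > 0))
})

test_that("the generated values decompose as mu + G + E + GEI at zero noise", {
  sim <- generate_table(synthetic_spec(
    n_genotypes = 15, n_environments = 6, n_row_clusters = 3,
    n_col_clusters = 2, noise_sd = 0, missing_mechanism = "none", seed = 21
  ))
  tr <- sim$truth
  rebuilt <- tr$mu + outer(unname(tr$g_effects), unname(tr$e_effects), `+`) +
    tr$gei
  expect_equal(unclass(sim$table), rebuilt, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(sum(tr$g_effects), 0, tolerance = 1e-12)
  expect_equal(sum(tr$e_effects), 0, tolerance = 1e-12)
  # cell_constant GEI is constant within every planted cell
  for (p in 1:3) {
    for (l in 1:2) {
      cell <- tr$gei[tr$partition$rows == p, tr$partition$cols == l]
      expect_lt(max(cell) - min(cell), 1e-12)
    }
  }
})

test_that("blockwise fits at the truth recover the planted block effects", {
  sim <- generate_table(synthetic_spec(
    n_genotypes = 20, n_environments = 8, n_row_clusters = 2,
    n_col_clusters = 2, noise_sd = 0, missing_mechanism = "none", seed = 23
  ))
  bw <- fit_blockwise(sim$table, sim$truth$partition)
  expect_equal(bw$sse_ni, 0, tolerance = 1e-14)
  tr <- sim$truth
  for (cf in bw$cell_fits) {
    for (cc in cf$components) {
      js <- match(cc$environments, colnames(sim$table))
      p <- tr$partition$rows[match(cc$genotypes[1], rownames(sim$table))]
      planted <- tr$e_effects[js] + tr$gei[cbind(
        rep(match(cc$genotypes[1], rownames(sim$table)), length(js)), js)]
      # equality up to the cell's centering constant
      expect_lt(max(abs((cc$e_tilde - mean(cc$e_tilde)) -
                        (planted - mean(planted)))), 1e-8)
    }
  }
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(rep(1, 5), rep(1, 5)), 1)
  # oracle value computed by direct pair counting for a small case
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 1, 2, 2, 3, 3)
  pairs <- combn(length(a), 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  ri_parts <- c(sum(same_a & same_b), sum(same_a), sum(same_b))
  expected <- ri_parts[2] * ri_parts[3] / ncol(pairs)
  ari_oracle <- (ri_parts[1] - expected) /
    ((ri_parts[2] + ri_parts[3]) / 2 - expected)
  expect_equal(adjusted_rand_index(a, b), ari_oracle)
  # independent random labelings score near zero
  set.seed(27)
  scores <- replicate(50, adjusted_rand_index(sample(1:3, 200, TRUE),
                                              sample(1:3, 200, TRUE)))
  expect_lt(abs(mean(scores)), 0.1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("partition_recovery_score is label-invariant per axis", {
  p1 <- gei_partition(c(1, 1, 2, 2), c(1, 2, 2), 2, 2)
  p2 <- gei_partition(c(2, 2, 1, 1), c(2, 1, 1), 2, 2)
  expect_equal(partition_recovery_score(p1, p2), c(row = 1, col = 1))
  p3 <- gei_partition(c(1, 2, 1, 2), c(1, 2, 2), 2, 2)
  expect_lt(partition_recovery_score(p3, p1)["row"], 1)
  expect_error(partition_recovery_score(p1, gei_partition(c(1, 2), c(1, 2))),
               "dimensions")
})
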