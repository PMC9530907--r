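test_that("sse_bc matches hand-computed values", {
  tab <- phenotype_table(matrix(c(1, 3, 2, 5), 2, 2))
  one_cell <- gei_partition(c(1, 1), c(1, 1))
  expect_equal(sse_bc(tab, one_cell), 8.75)
  expect_equal(sse_bc(tab, gei_partition(1:2, 1:2)), 0)

  masked <- phenotype_table(matrix(c(1, 3, NA, 5), 2, 2))
  expect_equal(sse_bc(masked, one_cell), 8)
  expect_error(sse_bc(tab, gei_partition(c(1, 1, 2), c(1, 1))), "dimensions")
})

test_that("sse_bc matches a brute-force oracle and is relabeling-invariant", {
  manual_sse <- function(tab, part) {
    idx <- which(!is.na(tab), arr.ind = TRUE)
    cell <- interaction(part$rows[idx[, 1]], part$cols[idx[, 2]], drop = TRUE)
    sum(unlist(lapply(split(tab[idx], cell), function(v) sum((v - mean(v))^2))))
  }
  set.seed(21)
  for (r in 1:15) {
    tab <- mk_random_table(6, 5, p_missing = 0.3)
    part <- gei_partition(sample(1:2, 6, TRUE), sample(1:2, 5, TRUE), 2, 2)
    expect_equal(sse_bc(tab, part), manual_sse(tab, part), tolerance = 1e-10)
    flip <- gei_partition(3L - part$rows, 3L - part$cols, 2, 2)
    expect_equal(sse_bc(tab, part), sse_bc(tab, flip))
  }
})

test_that("zero-noise planted blocks are recovered exactly", {
  vals <- rbind(
    c(1, 1, 5, 5), c(1, 1, 5, 5),
    c(5, 5, 1, 1), c(5, 5, 1, 1)
  )
  tab <- phenotype_table(vals)
  res <- best_bicluster(tab, 2, 2, trials = 20, base_seed = 3)
  expect_equal(res$sse_bc, 0)
  expect_partition_equal(res$partition,
                         gei_partition(c(1, 1, 2, 2), c(1, 1, 2, 2)))
})

test_that("n = m = 1 gives the total SSE about the global mean, any seed", {
  set.seed(31)
  tab <- mk_random_table(7, 4, p_missing = 0.25)
  y <- tab[!is.na(tab)]
  want <- sum((y - mean(y))^2)
  expect_equal(bicluster(tab, 1, 1, seed = 1)$sse_bc, want)
  expect_equal(bicluster(tab, 1, 1, seed = 99)$sse_bc, want)
})

test_that("a fixed seed reproduces a run bit for bit", {
  set.seed(41)
  tab <- mk_random_table(10, 6, p_missing = 0.2)
  a <- bicluster(tab, 3, 2, seed = 7)
  b <- bicluster(tab, 3, 2, seed = 7)
  expect_identical(a$partition, b$partition)
  expect_identical(a$sse_bc, b$sse_bc)
  expect_identical(a$sse_trace, b$sse_trace)
  expect_equal(a$seed, 7L)
})

test_that("stored sse_bc equals the recomputed objective; clusters nonempty", {
  set.seed(51)
  for (r in 1:10) {
    tab <- mk_random_table(8, 6, p_missing = 0.3)
    res <- bicluster(tab, 3, 2, seed = r)
    expect_equal(res$sse_bc, sse_bc(tab, res$partition), tolerance = 1e-10)
    expect_setequal(unique(res$partition$rows), 1:3)
    expect_setequal(unique(res$partition$cols), 1:2)
    expect_gte(res$iterations, 1L)
  }
})

test_that("the objective never increases across sweeps", {
  set.seed(61)
  for (r in 1:30) {
    tab <- mk_random_table(sample(4:8, 1), sample(3:6, 1), p_missing = 0.25)
    res <- bicluster(tab, 2, 2, seed = r)
    tr <- res$sse_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(tr[-length(tr)], 1e-12)))
  }
})

test_that("best_bicluster returns the smallest SSEbc of its restarts", {
  set.seed(71)
  tab <- mk_random_table(8, 5, p_missing = 0.2)
  singles <- vapply(5:14, function(s) bicluster(tab, 3, 2, seed = s)$sse_bc,
                    numeric(1))
  best <- best_bicluster(tab, 3, 2, trials = 10, base_seed = 5)
  expect_equal(best$sse_bc, min(singles))
  expect_equal(best$seed, (5:14)[which.min(singles)])
  one <- best_bicluster(tab, 3, 2, trials = 1, base_seed = 9)
  expect_identical(one$partition, bicluster(tab, 3, 2, seed = 9)$partition)
})

test_that("exhaustive oracle finds the planted optimum and handles extremes", {
  tab <- phenotype_table(rbind(c(1, 1, 5, 5), c(1, 1, 5, 5), c(5, 5, 1, 1)))
  ex <- exhaustive_bicluster(tab, 2, 2)
  expect_equal(ex$sse_bc, 0)
  expect_partition_equal(ex$partition, gei_partition(c(1, 1, 2), c(1, 1, 2, 2)))
  expect_equal(exhaustive_bicluster(tab, 3, 4)$sse_bc, 0)
  allsame <- phenotype_table(matrix(2, 2, 2))
  for (n in 1:2) for (m in 1:2) {
    expect_equal(exhaustive_bicluster(allsame, n, m)$sse_bc, 0)
  }
  big <- phenotype_table(matrix(rnorm(20 * 20), 20, 20))
  expect_error(exhaustive_bicluster(big, 5, 5), "too large")
})

test_that("restarted search attains the exhaustive optimum on small tables", {
  set.seed(81)
  for (r in 1:10) {
    tab <- mk_random_table(4, 4, p_missing = 0.2)
    ex <- exhaustive_bicluster(tab, 2, 2)
    bo <- best_bicluster(tab, 2, 2, trials = 100, base_seed = 1000 + r)
    expect_equal(bo$sse_bc, ex$sse_bc, tolerance = 1e-9)
  }
})
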