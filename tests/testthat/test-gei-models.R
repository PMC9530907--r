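test_that("additive fit reproduces the 2x2 hand computation", {
  tab <- phenotype_table(matrix(c(1, 3, 2, 5), 2, 2))
  fit <- fit_additive(tab)
  expect_equal(fit$sse, 0.25)
  expect_equal(fit$df, 1L)
  expect_equal(fit$anova$term, c("G", "E", "Error"))
  expect_equal(fit$anova$df, c(1L, 1L, 1L))
  # residuals equal the kind-2 transform on complete data
  expect_equal(fit$residuals, unclass(gei_response(tab, 2)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(fit$g_effects), 0, tolerance = 1e-12)
  expect_equal(sum(fit$e_effects), 0, tolerance = 1e-12)
  expect_error(fit_additive(phenotype_table(matrix(c(1, NA, NA, 4), 2, 2))),
               "disconnected")
})

test_that("sequential decomposition is exact on complete tables", {
  set.seed(13)
  tab <- phenotype_table(matrix(rnorm(9 * 6, 50, 5), 9, 6))
  fit <- fit_additive(tab)
  y <- tab[!is.na(tab)]
  total <- sum((y - mean(y))^2)
  expect_equal(sum(fit$anova$ss), total, tolerance = 1e-8)
  expect_equal(sum(fit$anova$df), length(y) - 1L)
})

test_that("cell-means model moves the additive error into the GEI row", {
  tab <- phenotype_table(matrix(c(1, 3, 2, 5), 2, 2))
  cm <- fit_cell_means(tab)
  expect_equal(cm$term, c("G", "E", "GEI", "Error"))
  expect_equal(cm$ss[3], 0.25)
  expect_equal(cm$df[3], 1L)
  expect_equal(cm$ss[4], 0)
  expect_equal(cm$df[4], 0L)
})

test_that("Finlay-Wilkinson slopes vanish on additive data and explain planted slopes", {
  set.seed(17)
  tab <- mk_additive_table(rnorm(8), rnorm(5))
  fw <- fit_finlay_wilkinson(tab)
  expect_equal(unname(fw$slopes), rep(0, 8), tolerance = 1e-8)
  expect_equal(fw$anova$ss[3], 0, tolerance = 1e-10)

  # plant genotype-specific slopes on the environment effect
  g <- rnorm(10)
  e <- rnorm(6, 0, 2)
  e <- e - mean(e)
  b <- rnorm(10, 0, 0.3)
  b <- b - mean(b) # keeps E the environment main effect
  vals <- 20 + outer(g, e, `+`) + outer(b, e)
  fw2 <- fit_finlay_wilkinson(phenotype_table(vals))
  expect_equal(unname(fw2$slopes), b, tolerance = 1e-6)
  expect_equal(fw2$sse, 0, tolerance = 1e-8)
  expect_equal(fw2$anova$df[3], 9L)
  # FW regression SS + FW error = additive error
  add <- fit_additive(phenotype_table(vals))
  expect_equal(fw2$anova$ss[3] + fw2$sse, add$sse, tolerance = 1e-8)
})

test_that("gollob_df matches g + e - 1 - 2k and rejects out-of-range k", {
  expect_identical(gollob_df(237, 7, 1), 241L)
  expect_identical(gollob_df(237, 7, 2), 239L)
  expect_identical(gollob_df(211, 8, 1:2), c(216L, 214L))
  expect_identical(gollob_df(176, 9, 1:2), c(182L, 180L))
  expect_error(gollob_df(10, 4, 4), "between")
  expect_error(gollob_df(10, 4, 0), "between")
})

test_that("AMMI accounting holds and full rank reconstructs exactly", {
  set.seed(19)
  tab <- phenotype_table(matrix(rnorm(12 * 5, 30, 4), 12, 5))
  add <- fit_additive(tab)
  for (k in c(1, 2, 4)) {
    am <- fit_ammi(tab, k)
    expect_equal(sum(am$term_ss) + am$sse, add$sse, tolerance = 1e-8)
    expect_equal(am$anova$df[3:(2 + k)], gollob_df(12, 5, 1:k))
  }
  am4 <- fit_ammi(tab, 4)
  expect_equal(am4$sse, 0, tolerance = 1e-8)
  # on complete data the term SS are the squared singular values
  expect_equal(am4$term_ss, svd(add$residuals)$d[1:4]^2, tolerance = 1e-8)
  expect_equal(sum(fit_ammi(tab, 2)$anova$df), nrow(tab) * ncol(tab) - 1L)
  expect_error(fit_ammi(tab, 5), "between")
})

test_that("AMMI accounting holds with missing cells too", {
  tab <- mk_masked_table(30, 6, 20, seed = 23)
  add <- fit_additive(tab)
  am <- fit_ammi(tab, 2)
  expect_equal(sum(am$term_ss) + am$sse, add$sse, tolerance = 1e-8)
  expect_gte(am$sse, 0)
})

test_that("error dfs reproduce the published study dimensions", {
  sorghum <- mk_masked_table(237, 7, 49, seed = 1)
  maize <- phenotype_table(matrix(rnorm(211 * 8, 6, 1), 211, 8))
  rice <- mk_masked_table(176, 9, 45, seed = 2)
  expect_equal(fit_additive(sorghum)$df, 1367L)
  expect_equal(fit_additive(maize)$df, 1470L)
  expect_equal(fit_additive(rice)$df, 1355L)
  expect_equal(fit_finlay_wilkinson(sorghum)$df, 1131L)
  expect_equal(fit_finlay_wilkinson(maize)$df, 1260L)
  expect_equal(fit_ammi(sorghum, 2)$df, 887L)
  expect_equal(fit_ammi(maize, 2)$df, 1040L)
  expect_equal(fit_ammi(rice, 2)$df, 993L)
})

test_that("render_anova_report stacks blocks in order, text and JSON", {
  tab <- phenotype_table(matrix(c(1, 3, 2, 5), 2, 2))
  fits <- list(fit_additive(tab), fit_cell_means(tab),
               fit_finlay_wilkinson(tab), fit_ammi(tab, 1))
  txt <- render_anova_report(fits, "text")
  heads <- c("No-interaction model", "All-interaction model",
             "Regression on mean model", "AMMI model")
  pos <- vapply(heads, function(h) regexpr(h, txt, fixed = TRUE)[1], numeric(1))
  expect_true(all(pos > 0) && all(diff(pos) > 0))
  js <- jsonlite::fromJSON(render_anova_report(fits, "json"),
                           simplifyVector = FALSE)
  expect_length(js, 4L)
  expect_equal(js[[1]]$model, "No-interaction model")
  expect_error(render_anova_report(list()), "no ANOVA")
})
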