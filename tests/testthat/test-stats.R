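# regression, chi-square, descriptives

test_that("transforms are base-10 with the count offset", {
  expect_equal(as.numeric(transform_counts(c(0, 9, 99))), c(0, 1, 2))
  expect_equal(as.numeric(transform_lengths(c(1, 100, 1000))), c(0, 2, 3))
  expect_identical(attr(transform_counts(1), "transform"), "log10(x+1)")
  expect_error(transform_counts(-1), "non-negative")
  expect_error(transform_lengths(0), "positive")
})

test_that("regression matches hand and lm-computed values", {
  # frozen oracle: lm(y ~ x) gives slope 0.9, SSR 4.05, SSE 0.70,
  # F(1,2) = 11.5714..., p = 0.076615...
  fit <- ols_f_test(c(1, 2, 3, 4), c(1, 2, 2, 4))
  expect_equal(fit$slope, 0.9, tolerance = 1e-12)
  expect_equal(fit$ss_regression, 4.05, tolerance = 1e-12)
  expect_equal(fit$ss_error, 0.70, tolerance = 1e-12)
  expect_equal(fit$f_statistic, 4.05 / (0.70 / 2), tolerance = 1e-12)
  expect_identical(fit$df2, 2L)

  # random-data agreement with closed form and with lm, 1e-9 relative
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- 0.7 * x + rnorm(n, sd = runif(1, 0.1, 2))
    fit <- ols_f_test(x, y)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    expect_equal(fit$slope, sxy / sxx, tolerance = 1e-9)
    r2 <- fit$r_squared
    expect_equal(fit$f_statistic, r2 * (n - 2) / (1 - r2), tolerance = 1e-9)
    m <- lm(y ~ x)
    expect_equal(fit$slope, unname(coef(m)[2]), tolerance = 1e-9)
    expect_equal(fit$f_statistic, unname(summary(m)$fstatistic[1]),
                 tolerance = 1e-9)
    expect_equal(fit$p_value, anova(m)[["Pr(>F)"]][1], tolerance = 1e-9)
  }
})

test_that("regression degenerate cases follow the contract", {
  # perfect fit
  fit <- ols_f_test(1:5, 2 * (1:5) + 1)
  expect_identical(fit$f_statistic, Inf)
  expect_identical(fit$p_value, 0)
  expect_equal(fit$r_squared, 1)
  # constant response
  fit0 <- ols_f_test(1:5, rep(3, 5))
  expect_identical(fit0$f_statistic, 0)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  # errors
  expect_error(ols_f_test(rep(2, 5), 1:5), "constant")
  expect_error(ols_f_test(1:2, 1:2), "at least 3")
  expect_error(ols_f_test(1:3, 1:4), "equal length")
})

test_that("chi-square matches hand-computed and reference values", {
  # perfectly proportional table: statistic 0
  prop <- matrix(c(10, 5, 20, 10), 2)
  res0 <- chi_square_independence(prop)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # diagonal table: all expected 5, statistic 4 * 25/5 = 20, df 1
  diag2 <- matrix(c(10, 0, 0, 10), 2)
  res <- chi_square_independence(diag2)
  expect_equal(res$statistic, 20)
  expect_identical(res$df, 1L)
  expect_true(all(res$expected == 5))

  # expected margins conserve observed margins
  set.seed(42)
  for (i in 1:10) {
    r <- sample(2:6, 1); c <- sample(2:4, 1)
    tab <- matrix(rpois(r * c, 8) + 1, r, c)
    res <- chi_square_independence(tab)
    expect_equal(rowSums(res$expected), rowSums(tab))
    expect_equal(colSums(res$expected), colSums(tab))
    # agreement with the standard implementation (no correction)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
    expect_identical(res$df, as.integer(ref$parameter))
    # permutation invariance
    res_p <- chi_square_independence(tab[sample(r), sample(c)])
    expect_equal(res_p$statistic, res$statistic, tolerance = 1e-12)
    # linear scaling of the whole table scales the statistic
    res_3 <- chi_square_independence(tab * 3)
    expect_equal(res_3$statistic, 3 * res$statistic, tolerance = 1e-9)
  }

  # Yates on a 2x2 matches the corrected reference
  t22 <- matrix(c(12, 3, 5, 9), 2)
  ry <- chi_square_independence(t22, correction = "yates")
  refy <- chisq.test(t22, correct = TRUE)
  expect_equal(ry$statistic, unname(refy$statistic), tolerance = 1e-12)
  expect_error(chi_square_independence(matrix(1:9, 3), correction = "yates"),
               "2x2")

  # zero margins dropped with warning; degenerate tables error
  withzero <- rbind(c(4, 6), c(0, 0), c(3, 7))
  expect_warning(rz <- chi_square_independence(withzero), "all-zero")
  expect_identical(rz$df, 1L)
  expect_error(
    suppressWarnings(chi_square_independence(rbind(c(4, 0), c(3, 0)))),
    "degenerate")
  expect_error(chi_square_independence(matrix(1:4, 1)), "2x2")

  # low expected counts flagged
  expect_true(chi_square_independence(matrix(c(2, 1, 1, 3),
                                             2))$low_expected_warning)
})

test_that("p-values fall monotonically as the statistic grows", {
  f <- vapply(c(0.5, 1, 2, 5, 20), function(s) pf(s, 1, 30,
                                                  lower.tail = FALSE), 0)
  expect_true(all(diff(f) < 0))
  # the same holds through the chi-square result objects at fixed df
  tabs <- lapply(c(1, 3, 8), function(d)
    matrix(c(10 + d, 10 - d, 10 - d, 10 + d), 2))
  ps <- vapply(tabs, function(t) chi_square_independence(t)$p_value, 0)
  stats <- vapply(tabs, function(t) chi_square_independence(t)$statistic, 0)
  expect_true(all(diff(stats) > 0))
  expect_true(all(diff(ps) < 0))
})

test_that("mean_se follows the n-1 sample convention", {
  m <- mean_se(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$standard_error, 1 / sqrt(3))   # sd = 1
  m1 <- mean_se(5)
  expect_equal(m1$mean, 5)
  expect_true(is.na(m1$standard_error))
  expect_equal(mean_se(rep(4, 6))$standard_error, 0)
  expect_error(mean_se(numeric(0)), "empty")
  # shift and permutation invariance
  set.seed(43)
  x <- rnorm(20)
  expect_equal(mean_se(x + 2)$mean, mean_se(x)$mean + 2)
  expect_equal(mean_se(x + 2)$standard_error, mean_se(x)$standard_error)
  expect_equal(mean_se(sample(x))$standard_error, mean_se(x)$standard_error)
})

test_that("hits_per_100nt is the raw-scale slope times 100", {
  lens <- seq(100, 2000, by = 100)
  s <- data.frame(rna_id = paste0("ds", seq_along(lens)),
                  molecule_class = "dsRNA", length_nt = lens,
                  n_offtarget_genes = 0.06 * lens,
                  has_nontarget_binding = FALSE, target_taxon = "t",
                  target_category = "other", stringsAsFactors = FALSE)
  r <- hits_per_100nt(s)
  expect_equal(r$rate_per_100nt, 6, tolerance = 1e-9)
  s0 <- s; s0$n_offtarget_genes <- 7
  expect_equal(hits_per_100nt(s0)$rate_per_100nt, 0, tolerance = 1e-12)
  expect_error(hits_per_100nt(s[1:2, ]), "at least 3")
})

test_that("database-level statistics compose the stats layer correctly", {
  set.seed(44)
  lens <- round(exp(runif(60, log(100), log(2500))))
  per_rna <- data.frame(
    rna_id = sprintf("ds%02d", 1:60), molecule_class = "dsRNA",
    length_nt = lens, n_offtarget_genes = rpois(60, 0.06 * lens),
    has_nontarget_binding = runif(60) < 0.3,
    target_taxon = rep(c("Acari", "Coleoptera", "Diptera", "Lepidoptera"),
                       15),
    target_category = "other", stringsAsFactors = FALSE)
  res <- database_stats(per_rna)
  # the regression is exactly ols_f_test on the transformed columns
  direct <- ols_f_test(transform_lengths(per_rna$length_nt),
                       transform_counts(per_rna$n_offtarget_genes))
  expect_equal(res$length_regression$f_statistic, direct$f_statistic)
  expect_identical(res$length_regression$transform_x, "log10(x)")
  expect_identical(res$length_regression$transform_y, "log10(x+1)")
  expect_equal(res$offtarget_per_dsrna$mean, mean(per_rna$n_offtarget_genes))
  expect_identical(res$n_dsrna, 60L)
  expect_identical(res$taxon_test$df, 3L)
  # per-gene length series
  series <- list(lac2 = data.frame(length_nt = c(60, 150, 300, 600, 1000,
                                                 1500, 2000),
                                   n_offtarget_genes = c(2, 6, 15, 33, 61,
                                                         88, 120)))
  res2 <- database_stats(per_rna, length_series = series)
  expect_identical(res2$per_gene_regressions$lac2$df2, 5L)
  expect_lt(res2$per_gene_regressions$lac2$p_value, 0.001)
})
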