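# Statistical layer: log-transformed least-squares regression of off-target
# counts on dsRNA length with F test, Pearson chi-square tests of
# independence, and descriptive summaries. Transforms use base 10 (the
# slope of a log-log fit is base-invariant; the intercept is not, and the
# base used is recorded in every result).

#' Log-transform off-target counts
#'
#' Counts include zeros (an RNA may match nothing), so the variance-
#' stabilising transform is `log10(x + 1)`; a zero count maps to 0.
#'
#' @param x non-negative numeric counts.
#' @return transformed values, with a `"transform"` attribute.
#' @export
transform_counts <- function(x) {
  if (!is.numeric(x)) .stopf("counts must be numeric")
  if (any(is.na(x)) || any(x < 0)) .stopf("counts must be non-negative")
  structure(log10(x + 1), transform = "log10(x+1)")
}

#' Log-transform dsRNA lengths
#'
#' @param x positive numeric lengths (nt).
#' @return `log10(x)`, with a `"transform"` attribute.
#' @export
transform_lengths <- function(x) {
  if (!is.numeric(x)) .stopf("lengths must be numeric")
  if (any(is.na(x)) || any(x <= 0)) .stopf("lengths must be positive")
  structure(log10(x), transform = "log10(x)")
}

#' Simple least-squares regression with F test
#'
#' Two-variable ordinary least squares computed in closed form
#' (slope = Sxy/Sxx), with the one-way F test of the regression:
#' `F = (SSR/1) / (SSE/(n-2))` on (1, n-2) degrees of freedom, upper-tail
#' p-value. A numerically perfect fit reports `F = Inf`, `p = 0`; a constant
#' response reports slope as computed, `F = 0`, `r^2 = 0`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`; `x` must not be
#'   constant. Apply [transform_counts()] / [transform_lengths()] first for
#'   the transformed analysis; the transform attributes are carried into the
#'   result.
#' @return object of class `rnai_ols`: `n`, `slope`, `intercept`,
#'   `slope_se`, `ss_regression`, `ss_error`, `ss_total`, `df1`, `df2`,
#'   `f_statistic`, `p_value`, `r_squared`, `transform_x`, `transform_y`.
#' @export
#' @examples
#' ols_f_test(c(1, 2, 3, 4), c(1, 2, 2, 4))
ols_f_test <- function(x, y) {
  if (length(x) != length(y))
    .stopf("x and y must have equal length (%d vs %d)", length(x), length(y))
  n <- length(x)
  if (n < 3) .stopf("need at least 3 observations (have %d)", n)
  if (any(is.na(x)) || any(is.na(y))) .stopf("missing values not allowed")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) .stopf("x is constant: regression undefined")
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  sst <- sum((y - my)^2)
  ssr <- slope * sxy
  sse <- max(sst - ssr, 0)
  df2 <- n - 2L
  if (sst == 0) {
    f <- 0; p <- 1; r2 <- 0; se <- 0
  } else if (sse <= 1e-12 * sst) {
    f <- Inf; p <- 0; r2 <- 1; se <- 0; sse <- 0
  } else {
    f <- ssr / (sse / df2)
    p <- pf(f, 1, df2, lower.tail = FALSE)
    r2 <- ssr / sst
    se <- sqrt(sse / df2 / sxx)
  }
  structure(list(n = n, slope = slope, intercept = intercept, slope_se = se,
                 ss_regression = ssr, ss_error = sse, ss_total = sst,
                 df1 = 1L, df2 = df2, f_statistic = f, p_value = p,
                 r_squared = r2,
                 transform_x = attr(x, "transform") %||% "identity",
                 transform_y = attr(y, "transform") %||% "identity"),
            class = "rnai_ols")
}

#' @export
print.rnai_ols <- function(x, ...) {
  cat(sprintf("Least-squares regression (n = %d)\n", x$n))
  cat(sprintf("  y [%s] ~ x [%s]\n", x$transform_y, x$transform_x))
  cat(sprintf("  slope = %.4g (SE %.4g), intercept = %.4g\n",
              x$slope, x$slope_se, x$intercept))
  cat(sprintf("  F(%d, %d) = %.4g, p = %.3g, r^2 = %.3f\n",
              x$df1, x$df2, x$f_statistic, x$p_value, x$r_squared))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Expected counts `E[i,j] = rowsum_i * colsum_j / N`; statistic
#' `sum((O - E)^2 / E)` on `(r-1)(c-1)` degrees of freedom, upper-tail
#' p-value. All-zero rows/columns are dropped with a warning before testing
#' (their expected counts are undefined); the test errors if fewer than two
#' rows or columns remain. No continuity correction by default; Yates'
#' correction is available for 2x2 tables.
#'
#' @param table numeric matrix of non-negative counts (r x c, r,c >= 2),
#'   e.g. from [taxon_table()] or [gene_group_table()].
#' @param correction `"none"` (default) or `"yates"` (2x2 only).
#' @return object of class `rnai_chisq`: `statistic`, `df`, `p_value`,
#'   `n` (total count), `observed`, `expected`, `low_expected_warning`
#'   (any expected cell < 5), `correction`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(10, 0, 0, 10), 2))
chi_square_independence <- function(table, correction = c("none", "yates")) {
  correction <- match.arg(correction)
  tab <- as.matrix(table)
  if (!is.numeric(tab) || any(is.na(tab)) || any(tab < 0))
    .stopf("table must be a matrix of non-negative counts")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    .stopf("table must be at least 2x2")
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    .warnf("dropping %d all-zero row(s) and %d all-zero column(s)",
           sum(zr), sum(zc))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    .stopf("table degenerate after dropping empty margins")
  N <- sum(tab)
  if (N <= 0) .stopf("table has zero total count")
  expected <- outer(rowSums(tab), colSums(tab)) / N
  if (correction == "yates" && !(nrow(tab) == 2 && ncol(tab) == 2))
    .stopf("Yates' correction is defined for 2x2 tables only")
  dev <- abs(tab - expected)
  if (correction == "yates") dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 n = N, observed = tab, expected = expected,
                 low_expected_warning = any(expected < 5),
                 correction = correction),
            class = "rnai_chisq")
}

#' @export
print.rnai_chisq <- function(x, ...) {
  cat(sprintf("Pearson chi-square test of independence (%dx%d, N = %g)\n",
              nrow(x$observed), ncol(x$observed), x$n))
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.3g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$correction == "yates") " (Yates)" else ""))
  if (x$low_expected_warning)
    cat("  note: some expected counts < 5\n")
  invisible(x)
}

#' Mean with standard error
#'
#' Arithmetic mean and its standard error (sample standard deviation with
#' n-1 denominator over sqrt(n)); the SE is reported as `NA` for a single
#' observation.
#'
#' @param values non-empty numeric vector.
#' @return object of class `rnai_meanse`: `n`, `mean`, `standard_error`,
#'   `min`, `max`.
#' @export
#' @examples
#' mean_se(c(1, 2, 3))
mean_se <- function(values) {
  if (length(values) == 0) .stopf("empty input")
  if (any(is.na(values))) .stopf("missing values not allowed")
  structure(list(n = length(values), mean = mean(values),
                 standard_error = if (length(values) > 1)
                   sd(values) / sqrt(length(values)) else NA_real_,
                 min = min(values), max = max(values)),
            class = "rnai_meanse")
}

#' @export
print.rnai_meanse <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.4g SE (n = %d, range %g-%g)\n",
              x$mean, x$standard_error, x$n, x$min, x$max))
  invisible(x)
}

#' Off-target hits gained per 100 nt of dsRNA
#'
#' Raw-scale companion to the log-log regression: the slope of an
#' untransformed least-squares fit of off-target count on length, scaled to
#' hits per 100 nt, with its 95% confidence interval. The log-log fit tests
#' the relationship; this auxiliary fit expresses it in interpretable units
#' (a log-log model has no single raw-scale slope).
#'
#' @param summaries per-RNA summaries from [summarize_per_rna()].
#' @param molecule_class restrict to one class (default `"dsRNA"`; `NULL`
#'   keeps all).
#' @return object of class `rnai_rate`: `rate_per_100nt`, `ci95` (length-2),
#'   `n`, and the underlying `regression` (`rnai_ols`).
#' @export
hits_per_100nt <- function(summaries, molecule_class = "dsRNA") {
  stopifnot(is.data.frame(summaries))
  s <- summaries
  if (!is.null(molecule_class))
    s <- s[s$molecule_class %in% molecule_class, , drop = FALSE]
  if (nrow(s) < 3)
    .stopf("need at least 3 RNAs for the rate estimate (have %d)", nrow(s))
  if (any(s$length_nt <= 0)) .stopf("lengths must be positive")
  fit <- ols_f_test(as.numeric(s$length_nt), as.numeric(s$n_offtarget_genes))
  tcrit <- qt(0.975, fit$df2)
  structure(list(rate_per_100nt = fit$slope * 100,
                 ci95 = (fit$slope + c(-1, 1) * tcrit * fit$slope_se) * 100,
                 n = fit$n, regression = fit),
            class = "rnai_rate")
}

#' @export
print.rnai_rate <- function(x, ...) {
  cat(sprintf(
    "%.3g additional off-target hits per 100 nt (95%% CI %.3g-%.3g, n = %d)\n",
    x$rate_per_100nt, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

#' @noRd
.report_ols <- function(fit, name) {
  list(name = name, statistic = fit$f_statistic,
       df = c(fit$df1, fit$df2), p = fit$p_value, n = fit$n,
       slope = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared,
       transform_x = fit$transform_x, transform_y = fit$transform_y)
}

#' @noRd
.report_chisq <- function(test, name) {
  list(name = name, statistic = test$statistic, df = test$df,
       p = test$p_value, n = test$n,
       observed = unname(test$observed), expected = unname(test$expected),
       row_labels = rownames(test$observed),
       col_labels = colnames(test$observed),
       low_expected_warning = test$low_expected_warning)
}

#' Reproduce the database-level statistics from a per-RNA table
#'
#' Runs the whole statistical layer from a collated per-RNA database table
#' (one row per pesticidal RNA with its length, off-target tally count,
#' non-target binding flag, taxon and target category) without re-running
#' the sequence scan: the log-log length regression with F test, the raw
#' hits-per-100-nt rate, the descriptive mean of off-target homologies per
#' dsRNA, the taxon chi-square, optional per-gene length regressions, and
#' optional gene-group chi-square from a precomputed contingency table.
#'
#' @param per_rna data frame in the summaries schema (see
#'   [summarize_per_rna()] / [read_summaries()]).
#' @param gene_group_counts optional contingency matrix (gene group x target
#'   category) for the gene-group test.
#' @param length_series optional named list of data frames with columns
#'   `length_nt` and `n_offtarget_genes`, one per gene, for per-gene
#'   length regressions.
#' @param regression_molecules molecule classes entering the length
#'   regression (`NULL` = all RNAs).
#' @param taxon_molecules molecule classes entering the taxon test.
#' @return named list of results (`rnai_ols`, `rnai_chisq`, `rnai_meanse`,
#'   `rnai_rate` objects plus counts).
#' @export
database_stats <- function(per_rna, gene_group_counts = NULL,
                           length_series = NULL,
                           regression_molecules = NULL,
                           taxon_molecules = "dsRNA") {
  stopifnot(is.data.frame(per_rna))
  reg <- per_rna
  if (!is.null(regression_molecules))
    reg <- reg[reg$molecule_class %in% regression_molecules, , drop = FALSE]
  fit <- ols_f_test(transform_lengths(as.numeric(reg$length_nt)),
                    transform_counts(as.numeric(reg$n_offtarget_genes)))
  ds <- per_rna[per_rna$molecule_class == "dsRNA", , drop = FALSE]
  si <- per_rna[per_rna$molecule_class == "siRNA", , drop = FALSE]
  out <- list(
    length_regression = fit,
    rate = hits_per_100nt(per_rna,
                          molecule_class = regression_molecules %||% "dsRNA"),
    offtarget_per_dsrna = mean_se(as.numeric(ds$n_offtarget_genes)),
    taxon_test = chi_square_independence(
      taxon_table(per_rna, molecule_class = taxon_molecules)),
    n_dsrna_with_offtarget = sum(ds$n_offtarget_genes > 0),
    n_dsrna = nrow(ds),
    n_sirna_with_offtarget = sum(si$n_offtarget_genes > 0),
    n_sirna = nrow(si))
  if (!is.null(gene_group_counts))
    out$gene_group_test <- chi_square_independence(gene_group_counts)
  if (!is.null(length_series))
    out$per_gene_regressions <- lapply(length_series, function(d)
      ols_f_test(transform_lengths(as.numeric(d$length_nt)),
                 transform_counts(as.numeric(d$n_offtarget_genes))))
  out
}
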