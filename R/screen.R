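# The full screening pipeline: scan -> tally -> classify -> summarize ->
# statistics, returned as one classed object with print/summary/plot
# methods.

#' Screen a pesticidal-RNA registry against a non-target gene set
#'
#' Runs the complete off-target screen: every RNA is decomposed into 21-nt
#' windows (both orientations) and matched against every eligible gene
#' sequence at up to `max_mismatches` substitutions; hits are collapsed to
#' one tally per (RNA, gene), labelled off-target or non-target, summarized
#' per RNA, and analysed with the statistical layer (log-log length
#' regression with F test, raw hits-per-100-nt rate, descriptive mean,
#' taxon and gene-group chi-square tests, developmental-gene fractions).
#'
#' @param registry a `pesticidal_registry` (see [read_registry()]).
#' @param genes a [gene_set()] (see [read_gene_set()]).
#' @param max_mismatches,k,ambiguity_policy,exclude_flags passed to
#'   [scan_gene_set()].
#' @param min_identity_class tallies require at least this identity class.
#' @param regression_molecules molecule classes entering the length
#'   regression and rate estimate (default dsRNA only; `NULL` for all RNAs).
#' @param taxon_molecules molecule classes entering the taxon test.
#' @param grouping,categories passed to [gene_group_table()].
#' @return object of class `offtarget_screen` with elements `hits`,
#'   `tallies`, `summaries`, `descriptive` (off-target homologies per
#'   dsRNA), `regression` (log-log, `rnai_ols`), `rate` (`rnai_rate`),
#'   `taxon_test`, `gene_group_test` (`rnai_chisq` or `NULL` when
#'   untestable), `dev_fractions`, `counts` and `params`.
#' @export
#' @examples
#' sim <- generate_synthetic(synthetic_config(seed = 1, n_genes = 25,
#'   gene_length_range = c(300, 600), n_dsrna = 8,
#'   dsrna_length_range = c(100, 350), n_sirna = 2, n_target_genes = 8))
#' scr <- screen_offtargets(sim$registry, sim$genes)
#' scr
screen_offtargets <- function(registry, genes, max_mismatches = 2L, k = 21L,
                              min_identity_class = 19L,
                              regression_molecules = "dsRNA",
                              taxon_molecules = "dsRNA",
                              ambiguity_policy = c("strict", "iupac"),
                              exclude_flags = DEFAULT_EXCLUDE_FLAGS,
                              grouping = default_gene_grouping(),
                              categories = c("vATPase", "other")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(is.data.frame(registry), inherits(genes, "gene_set"))
  hits <- scan_registry(registry, genes, max_mismatches = max_mismatches,
                        k = k, ambiguity_policy = ambiguity_policy,
                        exclude_flags = exclude_flags)
  tallies <- tally_per_gene(hits, min_identity_class = min_identity_class)
  tallies <- classify_binding(tallies, registry, genes)
  summaries <- summarize_per_rna(tallies, registry)

  ds <- summaries[summaries$molecule_class == "dsRNA", , drop = FALSE]
  si <- summaries[summaries$molecule_class == "siRNA", , drop = FALSE]
  reg <- if (is.null(regression_molecules)) summaries else
    summaries[summaries$molecule_class %in% regression_molecules, ,
              drop = FALSE]
  regression <- if (nrow(reg) >= 3 && length(unique(reg$length_nt)) > 1)
    ols_f_test(transform_lengths(as.numeric(reg$length_nt)),
               transform_counts(as.numeric(reg$n_offtarget_genes)))
  else NULL
  rate <- if (!is.null(regression))
    hits_per_100nt(summaries, molecule_class = regression_molecules)
  else NULL
  taxon_test <- tryCatch(
    chi_square_independence(taxon_table(summaries,
                                        molecule_class = taxon_molecules)),
    error = function(e) NULL)
  ggt <- gene_group_table(tallies, genes, registry, grouping = grouping,
                          categories = categories)
  gene_group_test <- if (isTRUE(attr(ggt, "untestable"))) NULL else
    tryCatch(chi_square_independence(ggt), error = function(e) NULL)

  ## fraction of dsRNAs with off-target similarity to developmental genes,
  ## and of those, the fraction also hitting homeobox genes
  coarse <- coarse_group(genes$genes$functional_group, genes$group_hierarchy)
  dev_genes <- genes$genes$gene_id[coarse == "developmental"]
  hb_genes <- genes$genes$gene_id[genes$genes$functional_group == "homeobox"]
  t_off <- tallies[tallies$binding_type == "off_target", , drop = FALSE]
  ds_ids <- ds$rna_id
  hits_dev <- unique(t_off$rna_id[t_off$gene_id %in% dev_genes])
  hits_hb <- unique(t_off$rna_id[t_off$gene_id %in% hb_genes])
  n_dev <- sum(ds_ids %in% hits_dev)
  dev_fractions <- list(
    pct_dsrna_developmental = if (length(ds_ids) > 0)
      100 * n_dev / length(ds_ids) else NA_real_,
    pct_developmental_homeobox = if (n_dev > 0)
      100 * sum(ds_ids %in% hits_dev & ds_ids %in% hits_hb) / n_dev
    else NA_real_)

  structure(list(
    hits = hits, tallies = tallies, summaries = summaries,
    descriptive = if (nrow(ds) > 0)
      mean_se(as.numeric(ds$n_offtarget_genes)) else NULL,
    regression = regression, rate = rate, taxon_test = taxon_test,
    gene_group_table = ggt, gene_group_test = gene_group_test,
    dev_fractions = dev_fractions,
    counts = list(
      n_dsrna = nrow(ds), n_sirna = nrow(si),
      n_dsrna_with_offtarget = sum(ds$n_offtarget_genes > 0),
      n_sirna_with_offtarget = sum(si$n_offtarget_genes > 0),
      n_sirna_with_any_tally = length(unique(
        tallies$rna_id[tallies$rna_id %in% si$rna_id])),
      n_tallies = nrow(tallies)),
    params = list(max_mismatches = max_mismatches, k = k,
                  min_identity_class = min_identity_class,
                  regression_molecules = regression_molecules,
                  taxon_molecules = taxon_molecules,
                  ambiguity_policy = ambiguity_policy,
                  exclude_flags = exclude_flags),
    call = match.call()),
    class = "offtarget_screen")
}

#' @export
print.offtarget_screen <- function(x, ...) {
  cat("In silico RNAi off-target screen\n")
  cat(sprintf("  %d dsRNAs, %d siRNAs scanned; %d hits, %d per-(RNA, gene) tallies\n",
              x$counts$n_dsrna, x$counts$n_sirna, nrow(x$hits),
              x$counts$n_tallies))
  cat(sprintf("  dsRNAs with >= 1 off-target similarity: %d of %d; siRNAs: %d of %d\n",
              x$counts$n_dsrna_with_offtarget, x$counts$n_dsrna,
              x$counts$n_sirna_with_offtarget, x$counts$n_sirna))
  if (!is.null(x$descriptive))
    cat(sprintf("  off-target homologies per dsRNA: %.1f +/- %.2f SE\n",
                x$descriptive$mean, x$descriptive$standard_error))
  if (!is.null(x$regression))
    cat(sprintf("  length regression (log-log): F(%d, %d) = %.3g, p = %.3g\n",
                x$regression$df1, x$regression$df2,
                x$regression$f_statistic, x$regression$p_value))
  if (!is.null(x$rate))
    cat(sprintf("  raw-scale rate: %.2f hits per 100 nt (95%% CI %.2f-%.2f)\n",
                x$rate$rate_per_100nt, x$rate$ci95[1], x$rate$ci95[2]))
  if (!is.null(x$taxon_test))
    cat(sprintf("  taxon x non-target binding: X-squared = %.3g, df = %d, p = %.3g\n",
                x$taxon_test$statistic, x$taxon_test$df,
                x$taxon_test$p_value))
  if (!is.null(x$gene_group_test))
    cat(sprintf("  gene group x target category: X-squared = %.3g, df = %d, p = %.3g\n",
                x$gene_group_test$statistic, x$gene_group_test$df,
                x$gene_group_test$p_value))
  invisible(x)
}

#' @export
summary.offtarget_screen <- function(object, ...) {
  print(object)
  cat("\nDevelopmental-gene exposure:\n")
  cat(sprintf("  %.1f%% of dsRNAs share off-target similarity with developmental genes\n",
              object$dev_fractions$pct_dsrna_developmental))
  if (!is.na(object$dev_fractions$pct_developmental_homeobox))
    cat(sprintf("  of those, %.1f%% also hit homeobox genes\n",
                object$dev_fractions$pct_developmental_homeobox))
  if (!is.null(object$taxon_test)) {
    cat("\nTaxon table (observed):\n")
    print(object$taxon_test$observed)
  }
  if (!is.null(object$gene_group_test)) {
    cat("\nGene-group table (observed):\n")
    print(object$gene_group_test$observed)
  }
  invisible(object)
}

#' Plot the length-response of an off-target screen
#'
#' Scatter of per-RNA off-target tally counts against molecule length on the
#' transformed (log-log) scale, with the fitted regression line.
#'
#' @param x an `offtarget_screen`.
#' @param ... passed to `plot()`.
#' @export
plot.offtarget_screen <- function(x, ...) {
  s <- x$summaries
  mol <- x$params$regression_molecules
  if (!is.null(mol)) s <- s[s$molecule_class %in% mol, , drop = FALSE]
  plot(log10(s$length_nt), log10(s$n_offtarget_genes + 1),
       xlab = "log10 RNA length (nt)",
       ylab = "log10(off-target tallies + 1)",
       main = "dsRNA length vs off-target similarity", ...)
  if (!is.null(x$regression))
    abline(x$regression$intercept, x$regression$slope, lty = 2)
  invisible(x)
}

#' Build the structured statistics report of a screen
#'
#' Nested, JSON-ready records for every test the screen ran (name,
#' statistic, df, p, n, transforms, warnings); write with
#' [write_stats_report()].
#'
#' @param screen an `offtarget_screen`.
#' @return named list.
#' @export
stats_report <- function(screen) {
  stopifnot(inherits(screen, "offtarget_screen"))
  rep_ <- list()
  if (!is.null(screen$descriptive))
    rep_$offtarget_per_dsrna <- c(list(name = "off-target homologies per dsRNA"),
                                  unclass(screen$descriptive))
  if (!is.null(screen$regression))
    rep_$length_regression <- .report_ols(screen$regression,
                                          "log-log length regression")
  if (!is.null(screen$rate))
    rep_$rate_per_100nt <- list(name = "off-target hits per 100 nt",
                                value = screen$rate$rate_per_100nt,
                                ci95 = screen$rate$ci95, n = screen$rate$n)
  if (!is.null(screen$taxon_test))
    rep_$taxon_test <- .report_chisq(screen$taxon_test,
                                     "target taxon x non-target binding")
  if (!is.null(screen$gene_group_test))
    rep_$gene_group_test <- .report_chisq(
      screen$gene_group_test, "gene group x pesticidal target category")
  rep_$dev_fractions <- screen$dev_fractions
  rep_$counts <- screen$counts
  rep_$params <- screen$params[c("max_mismatches", "k",
                                 "min_identity_class", "ambiguity_policy")]
  rep_
}
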