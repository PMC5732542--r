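# Synthetic gene sets, pesticidal RNAs and planted homologies with known
# ground truth, emulating the statistical structure of a collated
# pesticidal-RNA database: ~74 dsRNAs spanning 19-2500 nt and ~21 siRNAs of
# 19-23 nt, off-target homology counts whose expectation grows linearly with
# dsRNA length (Poisson planting at a configurable rate per 100 nt), eight
# target-taxon groups, and gene functional groups including a
# developmental/homeobox class. Background sequence is i.i.d. uniform ACGT.

#' Configuration for the synthetic data generator
#'
#' Defaults are the study conditions the generator emulates: 74 dsRNAs over
#' 19-2500 nt (log-uniform lengths, so the median molecule is a few hundred
#' nt), 21 siRNAs of 19-23 nt, 6 expected planted off-target homologies per
#' 100 nt of dsRNA, eight target taxa with a flat (null) non-target binding
#' probability, and a five-group gene functional annotation with a
#' developmental/homeobox class.
#'
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical outputs.
#' @param n_genes,gene_length_range size of the background gene set (nt).
#' @param group_proportions named fractions over functional groups (sum 1).
#' @param n_dsrna,dsrna_length_range,dsrna_length_dist dsRNA count, length
#'   range (nt) and length distribution (`"loguniform"` or `"uniform"`).
#' @param n_sirna,sirna_length_range siRNA count and length range (nt).
#' @param planted_rate_per_100nt expected planted off-target homologies per
#'   100 nt of dsRNA (Poisson); each homology lands on a distinct gene.
#' @param mismatch_mix named probabilities over planted substitution counts
#'   (names `"0"`, `"1"`, `"2"`; sum 1).
#' @param taxa target-taxon labels.
#' @param nontarget_binding_prob_by_taxon named per-taxon probability that a
#'   dsRNA gets a planted homology in its target's non-target ortholog;
#'   `NULL` means 0.3 for every taxon (a null taxon effect).
#' @param frac_low_quality_genes,frac_unknown_function_genes fractions of
#'   genes flagged `low_quality` / `unknown_function` (excluded at scan
#'   time; never planted into).
#' @param ortholog_fraction fraction of genes declared non-target orthologs
#'   of target genes (assigned to distinct targets first).
#' @param n_target_genes number of distinct pesticidal target genes.
#' @param vatpase_fraction fraction of target genes in the `vATPase`
#'   pesticidal category (the rest are `other`).
#' @param k window/plant length (nt).
#' @return validated object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 200L,
                             gene_length_range = c(500L, 3000L),
                             group_proportions = c(homeobox = 0.05,
                                                   other_developmental = 0.15,
                                                   housekeeping = 0.25,
                                                   neural_muscular = 0.15,
                                                   other = 0.40),
                             n_dsrna = 74L,
                             dsrna_length_range = c(19L, 2500L),
                             dsrna_length_dist = c("loguniform", "uniform"),
                             n_sirna = 21L,
                             sirna_length_range = c(19L, 23L),
                             planted_rate_per_100nt = 6,
                             mismatch_mix = c("0" = 0.25, "1" = 0.35,
                                              "2" = 0.40),
                             taxa = c("Acari", "Hymenoptera", "Coleoptera",
                                      "Lepidoptera", "Diptera", "Hemiptera",
                                      "Blattodea", "Nematoda"),
                             nontarget_binding_prob_by_taxon = NULL,
                             frac_low_quality_genes = 0.08,
                             frac_unknown_function_genes = 0.05,
                             ortholog_fraction = 0.15,
                             n_target_genes = 57L,
                             vatpase_fraction = 0.3,
                             k = 21L) {
  dsrna_length_dist <- match.arg(dsrna_length_dist)
  if (is.null(nontarget_binding_prob_by_taxon))
    nontarget_binding_prob_by_taxon <- setNames(rep(0.3, length(taxa)), taxa)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              group_proportions = group_proportions,
              n_dsrna = as.integer(n_dsrna),
              dsrna_length_range = as.integer(dsrna_length_range),
              dsrna_length_dist = dsrna_length_dist,
              n_sirna = as.integer(n_sirna),
              sirna_length_range = as.integer(sirna_length_range),
              planted_rate_per_100nt = planted_rate_per_100nt,
              mismatch_mix = mismatch_mix, taxa = taxa,
              nontarget_binding_prob_by_taxon =
                nontarget_binding_prob_by_taxon,
              frac_low_quality_genes = frac_low_quality_genes,
              frac_unknown_function_genes = frac_unknown_function_genes,
              ortholog_fraction = ortholog_fraction,
              n_target_genes = as.integer(n_target_genes),
              vatpase_fraction = vatpase_fraction, k = as.integer(k))
  .validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @noRd
.validate_synthetic_config <- function(cfg) {
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] < 1)
      .stopf("%s must be an ordered positive range", nm)
  }
  chk_range(cfg$gene_length_range, "gene_length_range")
  chk_range(cfg$dsrna_length_range, "dsrna_length_range")
  chk_range(cfg$sirna_length_range, "sirna_length_range")
  if (cfg$n_genes < 1 || cfg$n_dsrna < 0 || cfg$n_sirna < 0 ||
      cfg$n_target_genes < 1)
    .stopf("counts must be non-negative (n_genes, n_target_genes >= 1)")
  if (abs(sum(cfg$group_proportions) - 1) > 1e-8)
    .stopf("group_proportions must sum to 1")
  if (abs(sum(cfg$mismatch_mix) - 1) > 1e-8)
    .stopf("mismatch_mix must sum to 1")
  if (is.null(names(cfg$mismatch_mix)) ||
      anyNA(suppressWarnings(as.integer(names(cfg$mismatch_mix)))))
    .stopf("mismatch_mix must be named by substitution counts")
  if (!all(cfg$taxa %in% names(cfg$nontarget_binding_prob_by_taxon)))
    .stopf("nontarget_binding_prob_by_taxon must cover every taxon")
  if (cfg$planted_rate_per_100nt < 0)
    .stopf("planted_rate_per_100nt must be >= 0")
  if (cfg$frac_low_quality_genes + cfg$frac_unknown_function_genes >= 1)
    .stopf("excluded-gene fractions must leave some normal genes")
  invisible(cfg)
}

#' Generate a synthetic screening dataset with ground truth
#'
#' Draws a random gene set and pesticidal-RNA registry, then plants
#' homologies with known location, orientation and substitution count.
#' The number of off-target homologies planted for a dsRNA of length L is
#' Poisson(L/100 x `planted_rate_per_100nt`), each on a distinct normal-
#' quality gene (so deduplicated tallies recover the planted count exactly);
#' plants copy a window of the dsRNA - or its reverse complement, with
#' probability 0.5 each - into a free stretch of the gene, then apply
#' exactly the drawn number of substitutions, so the realized mismatch count
#' is the drawn one by construction. Non-target homologies are planted into
#' the ortholog of the RNA's target gene with a per-taxon probability.
#' siRNAs and dsRNAs shorter than the window receive no plants. Identical
#' seed and config give byte-identical output files.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir if non-`NULL`, write `genes.fasta`, `annotation.tsv`,
#'   `registry.tsv` and `truth.json` there.
#' @return list with `registry` (a `pesticidal_registry`), `genes` (a
#'   [gene_set()]), `truth` (list: `planted_hits` data frame with 0-based
#'   coordinates, `per_rna` expected tallies, `per_taxon` non-target counts,
#'   `group_category_counts` planted off-target counts by gene group x
#'   target category) and, when written, `paths`.
#' @export
generate_synthetic <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  bases <- c("A", "C", "G", "T")
  rand_dna <- function(n)
    paste(sample(bases, n, replace = TRUE), collapse = "")

  ## pesticidal target genes, species, taxa, categories
  ntg <- cfg$n_target_genes
  tg <- sprintf("target_%02d", seq_len(ntg))
  tg_taxon <- cfg$taxa[((seq_len(ntg) - 1L) %% length(cfg$taxa)) + 1L]
  tg_species <- sprintf("species_%02d", seq_len(ntg))
  tg_cat <- rep("other", ntg)
  n_vat <- round(cfg$vatpase_fraction * ntg)
  if (n_vat > 0) tg_cat[sample.int(ntg, n_vat)] <- "vATPase"

  ## background gene set
  ng <- cfg$n_genes
  gid <- sprintf("g%04d", seq_len(ng))
  fg <- sample(names(cfg$group_proportions), ng, replace = TRUE,
               prob = cfg$group_proportions)
  qual <- rep("normal", ng)
  n_lq <- round(cfg$frac_low_quality_genes * ng)
  n_uf <- round(cfg$frac_unknown_function_genes * ng)
  if (n_lq + n_uf > 0) {
    flagged <- sample.int(ng, n_lq + n_uf)
    if (n_lq > 0) qual[flagged[seq_len(n_lq)]] <- "low_quality"
    if (n_uf > 0) qual[flagged[n_lq + seq_len(n_uf)]] <- "unknown_function"
  }
  orth <- rep("", ng)
  normal_idx <- which(qual == "normal")
  n_orth <- min(round(cfg$ortholog_fraction * ng), length(normal_idx))
  if (n_orth > 0) {
    orth_idx <- sample(normal_idx, n_orth)
    orth[orth_idx] <- sample(tg, n_orth, replace = n_orth > ntg)
  }
  glen <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 ng, replace = TRUE)
  gseq <- vapply(glen, rand_dna, "")
  occupied <- lapply(glen, logical)

  ## registry
  draw_ds_len <- function(n) {
    a <- cfg$dsrna_length_range[1]; b <- cfg$dsrna_length_range[2]
    if (a == b) return(rep(a, n))
    if (cfg$dsrna_length_dist == "loguniform")
      pmin(pmax(round(exp(runif(n, log(a), log(b)))), a), b)
    else sample(seq(a, b), n, replace = TRUE)
  }
  n_ds <- cfg$n_dsrna; n_si <- cfg$n_sirna
  rna_id <- c(sprintf("dsRNA_%03d", seq_len(n_ds)),
              sprintf("siRNA_%02d", seq_len(n_si)))
  rna_class <- rep(c("dsRNA", "siRNA"), c(n_ds, n_si))
  rna_len <- c(draw_ds_len(n_ds),
               sample(seq(cfg$sirna_length_range[1],
                          cfg$sirna_length_range[2]),
                      n_si, replace = TRUE))
  rna_tgt <- sample.int(ntg, n_ds + n_si, replace = TRUE)
  rna_seq <- vapply(rna_len, rand_dna, "")

  ## planting machinery
  place_in_gene <- function(g, seg) {
    L <- nchar(seg); n <- glen[g]
    if (n < L) return(NA_integer_)
    cs0 <- c(0, cumsum(!occupied[[g]]))
    upto <- n - L + 1
    starts <- which((cs0[seq_len(upto) + L] - cs0[seq_len(upto)]) == L)
    if (length(starts) == 0) return(NA_integer_)
    s <- if (length(starts) == 1) starts else sample(starts, 1)
    substr(gseq[g], s, s + L - 1) <<- seg
    occupied[[g]][s:(s + L - 1)] <<- TRUE
    s
  }
  mutate_m <- function(seg, m) {
    if (m == 0) return(seg)
    v <- strsplit(seg, "", fixed = TRUE)[[1]]
    for (p in sample.int(length(v), m))
      v[p] <- sample(setdiff(bases, v[p]), 1)
    paste(v, collapse = "")
  }
  mm_values <- as.integer(names(cfg$mismatch_mix))
  plant_one <- function(i, g, kind) {
    L <- rna_len[i]
    s_rna <- if (L == k) 1L else sample.int(L - k + 1, 1)
    wb <- substr(rna_seq[i], s_rna, s_rna + k - 1)
    ori <- sample(c("+", "-"), 1)
    if (ori == "-") wb <- revcomp(wb)
    m <- if (length(mm_values) == 1) mm_values else
      sample(mm_values, 1, prob = cfg$mismatch_mix)
    gp <- place_in_gene(g, mutate_m(wb, m))
    if (is.na(gp)) return(NULL)
    list(rna_id = rna_id[i], gene_id = gid[g], rna_offset = s_rna - 1L,
         gene_position = gp - 1L, strand = ori, mismatches = m, kind = kind)
  }

  ## planted counts saturate when the longest dsRNA expects more
  ## distinct-gene homologies than there are plantable genes
  max_expected <- cfg$dsrna_length_range[2] / 100 * cfg$planted_rate_per_100nt
  if (max_expected > length(normal_idx))
    .warnf(paste("n_genes may be too small for the planted rate:",
                 "the longest dsRNA expects %.0f homologies but only %d",
                 "normal-quality genes exist; planted counts will saturate"),
           max_expected, length(normal_idx))

  hits <- list()
  orth_gene_of <- setNames(rep(NA_integer_, ntg), tg)
  for (g in which(nzchar(orth)))
    if (is.na(orth_gene_of[[orth[g]]])) orth_gene_of[[orth[g]]] <- g

  for (i in seq_len(n_ds)) {
    L <- rna_len[i]
    if (L < k) next
    ## off-target homologies on distinct genes; if a drawn gene has no free
    ## stretch left, try the next one so the Poisson draw is realized
    n_p <- rpois(1, L / 100 * cfg$planted_rate_per_100nt)
    elig <- normal_idx[orth[normal_idx] != tg[rna_tgt[i]]]
    if (n_p > 0 && length(elig) > 0) {
      placed <- 0L
      for (g in sample(elig, length(elig))) {
        h <- plant_one(i, g, "off_target")
        if (!is.null(h)) {
          hits[[length(hits) + 1]] <- h
          placed <- placed + 1L
          if (placed >= n_p) break
        }
      }
    }
    ## non-target homology in the target's ortholog, per-taxon probability
    og <- orth_gene_of[[tg[rna_tgt[i]]]]
    p_nt <- cfg$nontarget_binding_prob_by_taxon[[tg_taxon[rna_tgt[i]]]]
    if (!is.na(og) && runif(1) < p_nt) {
      h <- plant_one(i, og, "non_target")
      if (!is.null(h)) hits[[length(hits) + 1]] <- h
    }
  }

  planted <- if (length(hits) == 0) {
    data.frame(rna_id = character(0), gene_id = character(0),
               rna_offset = integer(0), gene_position = integer(0),
               strand = character(0), mismatches = integer(0),
               kind = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(hits, as.data.frame, stringsAsFactors = FALSE))
  }

  registry <- as_registry(data.frame(
    rna_id = rna_id, sequence = rna_seq, molecule_class = rna_class,
    target_gene_name = tg[rna_tgt], target_species = tg_species[rna_tgt],
    target_taxon = tg_taxon[rna_tgt], target_category = tg_cat[rna_tgt],
    source_study = sprintf("synthetic_study_%02d",
                           ((rna_tgt - 1L) %% 24L) + 1L),
    stringsAsFactors = FALSE))
  genes <- gene_set(
    data.frame(gene_id = gid, gene_name = gid, functional_group = fg,
               quality_flag = qual, ortholog_of = orth,
               stringsAsFactors = FALSE),
    setNames(as.list(gseq), gid))

  n_off <- table(planted$rna_id[planted$kind == "off_target"])
  nt_ids <- unique(planted$rna_id[planted$kind == "non_target"])
  per_rna <- data.frame(
    rna_id = rna_id, molecule_class = rna_class, length_nt = rna_len,
    n_offtarget = as.integer(ifelse(is.na(n_off[rna_id]), 0L,
                                    n_off[rna_id])),
    has_nontarget = rna_id %in% nt_ids,
    target_taxon = tg_taxon[rna_tgt], target_category = tg_cat[rna_tgt],
    stringsAsFactors = FALSE)
  ds <- per_rna$molecule_class == "dsRNA"
  per_taxon <- data.frame(
    taxon = cfg$taxa,
    n_dsrna = vapply(cfg$taxa, function(t)
      sum(ds & per_rna$target_taxon == t), integer(1)),
    n_with_nontarget = vapply(cfg$taxa, function(t)
      sum(ds & per_rna$target_taxon == t & per_rna$has_nontarget),
      integer(1)),
    stringsAsFactors = FALSE)
  off <- planted[planted$kind == "off_target", , drop = FALSE]
  group_category <- table(
    factor(setNames(fg, gid)[off$gene_id],
           levels = names(cfg$group_proportions)),
    factor(setNames(tg_cat[rna_tgt], rna_id)[off$rna_id],
           levels = c("vATPase", "other")))
  truth <- list(planted_hits = planted, per_rna = per_rna,
                per_taxon = per_taxon,
                group_category_counts = as.matrix(unclass(group_category)))

  out <- list(registry = registry, genes = genes, truth = truth,
              config = cfg)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      .stopf("cannot create output directory: %s", out_dir)
    paths <- c(fasta = file.path(out_dir, "genes.fasta"),
               annotation = file.path(out_dir, "annotation.tsv"),
               registry = file.path(out_dir, "registry.tsv"),
               truth = file.path(out_dir, "truth.json"))
    write_gene_set(genes, paths[["fasta"]], paths[["annotation"]])
    write_registry(registry, paths[["registry"]])
    truth_json <- truth
    truth_json$group_category_counts <-
      list(counts = unname(truth$group_category_counts),
           row_labels = rownames(truth$group_category_counts),
           col_labels = colnames(truth$group_category_counts))
    jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' Expected chance matches between random windows and random background
#'
#' Analytic estimate of the expected number of spurious matches at or above
#' the minimum identity class between the configuration's RNA windows and
#' its i.i.d. uniform-ACGT background:
#' `n_windows x background_positions x 2 strands x P(Hamming <= max_mm)`,
#' where `P = sum_m C(k,m) 3^m / 4^k`. Used to pick configurations whose
#' scans recover planted truth exactly (rate well below 1) versus
#' study-scale configurations where a few chance 19/21 matches are expected,
#' as they are against a real genome.
#'
#' @param cfg a [synthetic_config()].
#' @param max_mismatches mismatch threshold of the scan.
#' @return expected spurious match count (numeric).
#' @export
expected_spurious_rate <- function(cfg, max_mismatches = 2L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  k <- cfg$k
  m <- 0:max_mismatches
  p_chance <- sum(choose(k, m) * 3^m) / 4^k
  a <- cfg$dsrna_length_range[1]; b <- cfg$dsrna_length_range[2]
  mean_ds <- if (a == b) a else if (cfg$dsrna_length_dist == "loguniform")
    (b - a) / (log(b) - log(a)) else (a + b) / 2
  n_windows <- cfg$n_dsrna * max(mean_ds - k + 1, 1) + cfg$n_sirna * 1
  positions <- cfg$n_genes * max(mean(cfg$gene_length_range) - k + 1, 0)
  n_windows * positions * 2 * p_chance
}
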