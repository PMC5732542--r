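# Collapse hits to per-(RNA, gene) tallies, label non-target vs off-target
# binding, and build the contingency tables for the independence tests.
# Deduplication rule: each gene is tallied once per RNA, however many windows
# of that RNA match it.

#' Collapse hits to one tally per (RNA, gene) pair
#'
#' Each gene is counted once per RNA regardless of how many locations along
#' the gene are matched. `best_identity_class` is the maximum identity class
#' over the pair's hits, `n_windows_matching` the number of distinct
#' (window start, orientation) combinations with at least one hit on the
#' gene, and `any_seed_perfect` whether any hit had a perfect seed region.
#'
#' @param hits hit data frame from [scan_gene_set()] / [scan_registry()].
#' @param min_identity_class drop hits below this identity class before
#'   tallying (default 19, i.e. all three classes count as high similarity).
#' @return data frame with one row per (rna_id, gene_id): columns `rna_id`,
#'   `gene_id`, `best_identity_class`, `n_windows_matching`,
#'   `any_seed_perfect`.
#' @export
tally_per_gene <- function(hits, min_identity_class = 19L) {
  stopifnot(is.data.frame(hits))
  empty <- data.frame(rna_id = character(0), gene_id = character(0),
                      best_identity_class = integer(0),
                      n_windows_matching = integer(0),
                      any_seed_perfect = logical(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0) return(empty)
  hits <- hits[hits$identity_class >= min_identity_class, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  key <- paste(hits$rna_id, hits$gene_id, sep = "\r")
  win <- paste(hits$rna_window_start, hits$strand, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    rna_id = hits$rna_id[first],
    gene_id = hits$gene_id[first],
    best_identity_class = as.integer(
      tapply(hits$identity_class, key, max)[key[first]]),
    n_windows_matching = as.integer(
      tapply(win, key, function(w) length(unique(w)))[key[first]]),
    any_seed_perfect = as.logical(
      tapply(hits$seed_perfect, key, any)[key[first]]),
    stringsAsFactors = FALSE)
  out <- out[order(out$rna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label tallies as off-target or non-target binding
#'
#' Within the non-target organism, similarity to the homolog of the RNA's
#' own target gene is *non-target* binding (the intended gene in the
#' unintended organism); similarity to any other gene is *off-target*
#' binding. A tally is non-target iff the gene's `ortholog_of` set contains
#' the RNA's `target_gene_name`.
#'
#' @param tallies tally data frame from [tally_per_gene()].
#' @param registry the `pesticidal_registry` the hits came from.
#' @param genes the [gene_set()] that was scanned.
#' @return `tallies` with a `binding_type` column (`off_target` /
#'   `non_target`). Emits a warning when no gene in the set declares any
#'   ortholog (all tallies are then off-target), and a message listing RNAs
#'   whose target gene has no annotated homolog in the set.
#' @export
classify_binding <- function(tallies, registry, genes) {
  stopifnot(is.data.frame(tallies), is.data.frame(registry),
            inherits(genes, "gene_set"))
  orth <- lapply(genes$genes$ortholog_of, .split_orthologs)
  names(orth) <- genes$genes$gene_id
  if (nrow(tallies) > 0 && all(lengths(orth) == 0))
    .warnf("no gene declares an ortholog: all tallies classified off_target")
  target_of <- setNames(registry$target_gene_name, registry$rna_id)
  unknown <- setdiff(unique(tallies$rna_id), names(target_of))
  if (length(unknown) > 0)
    .stopf("tallies reference rna_id(s) absent from the registry: %s",
           paste(unknown, collapse = ", "))
  all_declared <- unique(unlist(orth, use.names = FALSE))
  no_homolog <- setdiff(unique(registry$target_gene_name), all_declared)
  if (length(no_homolog) > 0)
    message("target gene(s) without an annotated non-target homolog ",
            "(their RNAs can only tally off_target): ",
            paste(no_homolog, collapse = ", "))
  if (nrow(tallies) == 0) {
    tallies$binding_type <- character(0)
    return(tallies)
  }
  is_nt <- mapply(function(g, r) target_of[[r]] %in% orth[[g]],
                  tallies$gene_id, tallies$rna_id, USE.NAMES = FALSE)
  tallies$binding_type <- ifelse(is_nt, "non_target", "off_target")
  tallies
}

#' Summarize tallies per RNA
#'
#' One summary row per registry RNA, including RNAs with zero tallies.
#' `n_offtarget_genes` counts off-target tallies only (a non-target homolog
#' is by definition not a different gene); `has_nontarget_binding` flags any
#' non-target tally.
#'
#' @param tallies classified tallies (with `binding_type`).
#' @param registry the `pesticidal_registry`.
#' @return data frame with columns `rna_id`, `molecule_class`, `length_nt`,
#'   `n_offtarget_genes`, `has_nontarget_binding`, `target_taxon`,
#'   `target_category`, one row per registry RNA.
#' @export
summarize_per_rna <- function(tallies, registry) {
  stopifnot(is.data.frame(tallies), is.data.frame(registry))
  unknown <- setdiff(unique(tallies$rna_id), registry$rna_id)
  if (length(unknown) > 0)
    .stopf("tallies reference rna_id(s) absent from the registry: %s",
           paste(unknown, collapse = ", "))
  if (nrow(tallies) > 0 && !"binding_type" %in% names(tallies))
    .stopf("tallies must be classified first (see classify_binding)")
  n_off <- table(tallies$rna_id[tallies$binding_type == "off_target"])
  has_nt <- unique(tallies$rna_id[tallies$binding_type == "non_target"])
  out <- data.frame(
    rna_id = registry$rna_id,
    molecule_class = registry$molecule_class,
    length_nt = registry$length_nt,
    n_offtarget_genes = as.integer(ifelse(is.na(n_off[registry$rna_id]), 0L,
                                          n_off[registry$rna_id])),
    has_nontarget_binding = registry$rna_id %in% has_nt,
    target_taxon = registry$target_taxon,
    target_category = registry$target_category,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Taxon-by-outcome contingency table
#'
#' Cross-tabulates target taxa against the presence/absence of non-target
#' binding, one count per RNA, for the chi-square test of whether taxonomic
#' relatedness of the target affects non-target binding incidence.
#'
#' @param summaries per-RNA summaries from [summarize_per_rna()].
#' @param molecule_class restrict to one molecule class (default `"dsRNA"`;
#'   `NULL` keeps all RNAs).
#' @return integer matrix, rows = taxa, columns
#'   `c("nontarget_present", "nontarget_absent")`.
#' @export
taxon_table <- function(summaries, molecule_class = "dsRNA") {
  stopifnot(is.data.frame(summaries))
  s <- summaries
  if (!is.null(molecule_class))
    s <- s[s$molecule_class %in% molecule_class, , drop = FALSE]
  taxa <- sort(unique(s$target_taxon))
  if (length(taxa) < 2)
    .stopf("need at least 2 taxa for a contingency table (have %d)",
           length(taxa))
  tab <- cbind(
    nontarget_present = vapply(taxa, function(t)
      sum(s$target_taxon == t & s$has_nontarget_binding), integer(1)),
    nontarget_absent = vapply(taxa, function(t)
      sum(s$target_taxon == t & !s$has_nontarget_binding), integer(1)))
  rownames(tab) <- taxa
  tab
}

#' Default off-target gene grouping for the gene-group test
#'
#' Maps annotated functional groups onto the five row categories used by the
#' gene-group chi-square test. Functional groups not named in the map fall
#' into `other`.
#'
#' @return named character vector, functional group -> row category.
#' @export
default_gene_grouping <- function() {
  c(homeobox = "homeobox", other_developmental = "other_developmental",
    housekeeping = "housekeeping", neural_muscular = "neural_muscular",
    other = "other")
}

#' Gene-group by target-category contingency table
#'
#' Cross-tabulates the functional group of the off-target gene against the
#' pesticidal target category of the RNA, one count per off-target tally,
#' for the chi-square test of whether certain gene groups attract off-target
#' similarity disproportionately for certain pesticidal targets (e.g.
#' vATPase subunits).
#'
#' @param tallies classified tallies.
#' @param genes the [gene_set()].
#' @param registry the `pesticidal_registry`.
#' @param grouping named map of functional groups to row categories, as from
#'   [default_gene_grouping()]; groups absent from the map fall into the
#'   `"other"` row, which must therefore be among the map's values.
#' @param categories column categories; RNAs whose `target_category` is not
#'   listed fall into the last one (the catch-all).
#' @return integer matrix (rows = gene groups, columns = target categories).
#'   An all-zero table carries the attribute `untestable = TRUE` and a
#'   warning.
#' @export
gene_group_table <- function(tallies, genes, registry,
                             grouping = default_gene_grouping(),
                             categories = c("vATPase", "other")) {
  stopifnot(is.data.frame(tallies), inherits(genes, "gene_set"),
            is.data.frame(registry))
  if (is.null(names(grouping)) || any(!nzchar(grouping)) ||
      anyNA(grouping))
    .stopf("grouping must be a named map of functional groups to row labels")
  rows <- unique(unname(grouping))
  gene_group <- setNames(genes$genes$functional_group, genes$genes$gene_id)
  rna_cat <- setNames(registry$target_category, registry$rna_id)
  tab <- matrix(0L, nrow = length(rows), ncol = length(categories),
                dimnames = list(rows, categories))
  t_off <- tallies[!is.na(tallies$binding_type) &
                     tallies$binding_type == "off_target", , drop = FALSE]
  if (nrow(t_off) > 0) {
    fg <- unname(gene_group[t_off$gene_id])
    mapped <- unname(grouping[fg])
    if (anyNA(mapped)) {
      if (!"other" %in% rows)
        .stopf("functional group(s) %s not in grouping and no 'other' row configured",
               paste(unique(fg[is.na(mapped)]), collapse = ", "))
      mapped[is.na(mapped)] <- "other"
    }
    cat_ <- unname(rna_cat[t_off$rna_id])
    cat_[!cat_ %in% categories] <- categories[length(categories)]
    for (i in seq_along(mapped))
      tab[mapped[i], cat_[i]] <- tab[mapped[i], cat_[i]] + 1L
  }
  if (sum(tab) == 0) {
    attr(tab, "untestable") <- TRUE
    .warnf("gene-group table is all zero: untestable")
  }
  tab
}
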