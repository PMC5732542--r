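# Readers and writers for the pesticidal-RNA registry, the non-target gene
# set (FASTA + annotation) and all result tables. File dialect: TSV with a
# header row, UTF-8, '#' comment lines allowed. All genomic coordinates in
# output files are 0-based half-open.

REGISTRY_COLUMNS <- c("rna_id", "sequence", "molecule_class",
                      "target_gene_name", "target_species", "target_taxon",
                      "target_category")
ANNOTATION_COLUMNS <- c("gene_id", "functional_group", "quality_flag",
                        "ortholog_of")
QUALITY_FLAGS <- c("normal", "low_quality", "unknown_function", "unannotated")
HITS_COLUMNS <- c("rna_id", "gene_id", "rna_window_start", "gene_seq_index",
                  "gene_position", "strand", "mismatches", "identity_class",
                  "seed_perfect")
TALLY_COLUMNS <- c("rna_id", "gene_id", "binding_type", "best_identity_class",
                   "n_windows_matching")
SUMMARY_COLUMNS <- c("rna_id", "molecule_class", "length_nt",
                     "n_offtarget_genes", "has_nontarget_binding",
                     "target_taxon", "target_category")

#' @noRd
.read_tsv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             colClasses = "character", quote = "", check.names = TRUE,
             stringsAsFactors = FALSE)
}

#' @noRd
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read a pesticidal-RNA registry
#'
#' Reads the curated registry of published pesticidal ds/siRNAs: one row per
#' RNA with its sequence, molecule class and target metadata. Sequences are
#' uppercased and the RNA alphabet is normalized to DNA (`U` to `T`) so that
#' matching is alphabet-uniform against gene sequences. Every row is
#' validated; the reader never silently drops rows.
#'
#' @param path path to a tab-separated registry with header columns
#'   `rna_id`, `sequence`, `molecule_class` (`dsRNA` or `siRNA`),
#'   `target_gene_name`, `target_species`, `target_taxon`, `target_category`
#'   and optionally `source_study`. Lines starting with `#` are comments.
#' @param fmt registry dialect; only `"tsv_with_header"` is defined.
#' @return a `data.frame` of class `pesticidal_registry`, one row per RNA,
#'   with a derived `length_nt` column (sequence length in nucleotides).
#' @export
read_registry <- function(path, fmt = "tsv_with_header") {
  fmt <- match.arg(fmt, "tsv_with_header")
  df <- .read_tsv(path)
  missing <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing) > 0)
    .stopf("registry is missing required column(s): %s",
           paste(missing, collapse = ", "))
  if (!"source_study" %in% names(df)) df$source_study <- ""
  as_registry(df)
}

#' Validate a data frame as a pesticidal-RNA registry
#'
#' Applies the registry invariants (IUPAC alphabet, U->T normalization,
#' unique `rna_id`, siRNA length between 19 and 25 nt) to an in-memory table.
#'
#' @param df data frame with the registry columns (see [read_registry()]).
#' @return a validated `pesticidal_registry` data frame with `length_nt`.
#' @export
as_registry <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing) > 0)
    .stopf("registry is missing required column(s): %s",
           paste(missing, collapse = ", "))
  df$sequence <- .normalize_seq(df$sequence)
  bad <- which(!nzchar(df$sequence) | !.is_iupac(df$sequence))
  if (length(bad) > 0)
    .stopf("registry row(s) %s: sequence empty or containing non-IUPAC characters",
           paste(bad, collapse = ", "))
  badclass <- which(!df$molecule_class %in% c("dsRNA", "siRNA"))
  if (length(badclass) > 0)
    .stopf("registry row(s) %s: molecule_class must be 'dsRNA' or 'siRNA'",
           paste(badclass, collapse = ", "))
  dup <- unique(df$rna_id[duplicated(df$rna_id)])
  if (length(dup) > 0)
    .stopf("duplicate rna_id in registry: %s", paste(dup, collapse = ", "))
  df$length_nt <- nchar(df$sequence)
  shortlong <- which(df$molecule_class == "siRNA" &
                       (df$length_nt < 19 | df$length_nt > 25))
  if (length(shortlong) > 0)
    .stopf("registry row(s) %s: siRNA length must be 19-25 nt",
           paste(shortlong, collapse = ", "))
  if (!"source_study" %in% names(df)) df$source_study <- ""
  df <- df[c(REGISTRY_COLUMNS, "source_study", "length_nt")]
  rownames(df) <- NULL
  class(df) <- c("pesticidal_registry", "data.frame")
  df
}

#' Write a pesticidal-RNA registry
#'
#' @param registry a `pesticidal_registry` data frame.
#' @param path output TSV path.
#' @return invisibly, the path written.
#' @export
write_registry <- function(registry, path) {
  stopifnot(is.data.frame(registry))
  cols <- c(REGISTRY_COLUMNS, "source_study")
  .write_tsv(as.data.frame(registry)[cols], path)
  invisible(path)
}

#' Default fine-to-coarse gene group hierarchy
#'
#' Maps fine functional groups onto coarse groups; by default the homeobox
#' genes and the remaining developmental genes both roll up into a coarse
#' `developmental` group, matching the convention that homeobox membership
#' implies developmental membership. Groups absent from the map are their own
#' coarse group.
#'
#' @return named character vector, fine group -> coarse group.
#' @export
default_group_hierarchy <- function() {
  c(homeobox = "developmental", other_developmental = "developmental")
}

#' Map fine functional groups to coarse groups
#'
#' @param group character vector of fine functional groups.
#' @param hierarchy named map as from [default_group_hierarchy()].
#' @return character vector of coarse groups.
#' @export
coarse_group <- function(group, hierarchy = default_group_hierarchy()) {
  out <- unname(hierarchy[group])
  ifelse(is.na(out), group, out)
}

#' Construct a non-target gene set
#'
#' Container for the searchable non-target gene space: one record per gene
#' (annotation plus zero or more nucleotide sequences attributed to it) and a
#' configurable fine-to-coarse functional group hierarchy.
#'
#' @param genes data frame with columns `gene_id` (unique), `gene_name`,
#'   `functional_group`, `quality_flag` (one of `normal`, `low_quality`,
#'   `unknown_function`, `unannotated`) and `ortholog_of` (semicolon-separated
#'   list of target gene names this gene is the non-target homolog of; may be
#'   empty).
#' @param sequences named list, `gene_id` -> character vector of DNA
#'   sequences; genes may hold several sequences (e.g. several transcript or
#'   genomic regions) or none.
#' @param group_hierarchy named character vector mapping fine groups to
#'   coarse groups.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(genes, sequences,
                     group_hierarchy = default_group_hierarchy()) {
  stopifnot(is.data.frame(genes), is.list(sequences))
  need <- setdiff(c("gene_id", "functional_group", "quality_flag",
                    "ortholog_of"), names(genes))
  if (length(need) > 0)
    .stopf("gene annotation is missing column(s): %s",
           paste(need, collapse = ", "))
  if (!"gene_name" %in% names(genes)) genes$gene_name <- genes$gene_id
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0)
    .stopf("duplicate gene_id in gene set: %s", paste(dup, collapse = ", "))
  bad <- which(!genes$quality_flag %in% QUALITY_FLAGS)
  if (length(bad) > 0)
    .stopf("gene(s) %s: quality_flag must be one of %s",
           paste(genes$gene_id[bad], collapse = ", "),
           paste(QUALITY_FLAGS, collapse = ", "))
  stray <- setdiff(names(sequences), genes$gene_id)
  if (length(stray) > 0)
    .stopf("sequences supplied for unknown gene_id(s): %s",
           paste(stray, collapse = ", "))
  sequences <- lapply(sequences, .normalize_seq)
  for (id in names(sequences)) {
    s <- sequences[[id]]
    if (length(s) > 0 && any(!nzchar(s) | !.is_iupac(s)))
      .stopf("gene %s: empty or non-IUPAC sequence", id)
  }
  full <- setNames(vector("list", nrow(genes)), genes$gene_id)
  for (id in genes$gene_id)
    full[[id]] <- as.character(sequences[[id]] %||% character(0))
  if (any(genes$functional_group == "homeobox") &&
      !"homeobox" %in% names(group_hierarchy))
    .warnf("group hierarchy does not place 'homeobox' in a coarse group")
  genes <- genes[c("gene_id", "gene_name", "functional_group",
                   "quality_flag", "ortholog_of")]
  rownames(genes) <- NULL
  structure(list(genes = genes, sequences = full,
                 group_hierarchy = group_hierarchy),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  nseq <- vapply(x$sequences, length, integer(1))
  cat(sprintf("<gene_set> %d genes (%d with sequence, %d sequences total)\n",
              nrow(x$genes), sum(nseq > 0), sum(nseq)))
  cat("  functional groups:",
      paste(sprintf("%s=%d", names(table(x$genes$functional_group)),
                    table(x$genes$functional_group)), collapse = ", "), "\n")
  cat("  quality flags:",
      paste(sprintf("%s=%d", names(table(x$genes$quality_flag)),
                    table(x$genes$quality_flag)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) nrow(x$genes)

#' Read a non-target gene set from FASTA plus annotation
#'
#' FASTA record ids (the first whitespace-delimited token of each header) are
#' gene ids; multiple records sharing an id are attached to one gene record.
#' Genes present in the FASTA but absent from the annotation are retained
#' with `quality_flag = "unannotated"` (and are excluded at scan time by
#' default); annotation rows without any FASTA record are retained with zero
#' sequences and a warning, and are skipped when scanning.
#'
#' @param fasta_path multi-record FASTA of gene-attributed nucleotide
#'   sequences (wrapped or unwrapped).
#' @param annotation_path TSV with columns `gene_id`, `functional_group`,
#'   `quality_flag`, `ortholog_of` and optionally `gene_name`.
#' @param group_hierarchy fine-to-coarse group map.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(fasta_path, annotation_path,
                          group_hierarchy = default_group_hierarchy()) {
  if (!file.exists(fasta_path)) .stopf("file not found: %s", fasta_path)
  recs <- tryCatch(Biostrings::readDNAStringSet(fasta_path),
                   error = function(e)
                     .stopf("FASTA parse failure in %s: %s", fasta_path,
                            conditionMessage(e)))
  if (length(recs) == 0) .warnf("empty FASTA: %s", fasta_path)
  ids <- sub("\\s.*$", "", names(recs))
  ann <- .read_tsv(annotation_path)
  missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing) > 0)
    .stopf("annotation is missing required column(s): %s",
           paste(missing, collapse = ", "))
  dup <- unique(ann$gene_id[duplicated(ann$gene_id)])
  if (length(dup) > 0)
    .stopf("duplicate gene_id in annotation: %s", paste(dup, collapse = ", "))
  if (!"gene_name" %in% names(ann)) ann$gene_name <- ann$gene_id

  unannotated <- setdiff(unique(ids), ann$gene_id)
  if (length(unannotated) > 0)
    ann <- rbind(ann[c("gene_id", "gene_name", "functional_group",
                       "quality_flag", "ortholog_of")],
                 data.frame(gene_id = unannotated, gene_name = unannotated,
                            functional_group = "unknown",
                            quality_flag = "unannotated", ortholog_of = "",
                            stringsAsFactors = FALSE))
  no_seq <- setdiff(ann$gene_id, unique(ids))
  if (length(no_seq) > 0)
    .warnf("annotation row(s) without any FASTA record (retained with zero sequences): %s",
           paste(no_seq, collapse = ", "))
  seqs <- split(as.character(recs), ids)
  # preserve FASTA record order within each gene
  gene_set(ann, seqs, group_hierarchy = group_hierarchy)
}

#' Write a gene set as FASTA plus annotation
#'
#' @param genes a [gene_set()].
#' @param fasta_path,annotation_path output paths.
#' @param width FASTA line width.
#' @return invisibly, the two paths.
#' @export
write_gene_set <- function(genes, fasta_path, annotation_path, width = 70L) {
  stopifnot(inherits(genes, "gene_set"))
  ids <- rep(names(genes$sequences),
             vapply(genes$sequences, length, integer(1)))
  seqs <- unlist(genes$sequences, use.names = FALSE)
  dss <- Biostrings::DNAStringSet(if (is.null(seqs)) character(0) else seqs)
  names(dss) <- ids
  Biostrings::writeXStringSet(dss, fasta_path, width = width)
  .write_tsv(genes$genes, annotation_path)
  invisible(c(fasta_path, annotation_path))
}

#' @noRd
.order_hits <- function(hits) {
  hits[order(hits$rna_id, hits$gene_id, hits$gene_seq_index,
             hits$gene_position, hits$rna_window_start, hits$strand), ,
       drop = FALSE]
}

#' Write / read match hits
#'
#' Hits are written in a deterministic order (rna_id, gene_id, sequence
#' index, gene position, window start). Coordinates are 0-based; strand is
#' `+` for sense windows and `-` for antisense windows; `seed_perfect` is
#' encoded 0/1.
#'
#' @param hits hit data frame as returned by [scan_gene_set()].
#' @param path TSV path.
#' @return `write_hits()` the path, invisibly; `read_hits()` the data frame.
#' @export
write_hits <- function(hits, path) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0) {
    hits <- as.data.frame(setNames(rep(list(character(0)),
                                       length(HITS_COLUMNS)), HITS_COLUMNS))
  } else {
    hits <- .order_hits(hits)
    hits$seed_perfect <- as.integer(hits$seed_perfect)
  }
  .write_tsv(hits[HITS_COLUMNS], path)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  df <- .read_tsv(path)
  missing <- setdiff(HITS_COLUMNS, names(df))
  if (length(missing) > 0)
    .stopf("hits table is missing column(s): %s",
           paste(missing, collapse = ", "))
  for (col in c("rna_window_start", "gene_seq_index", "gene_position",
                "mismatches", "identity_class"))
    df[[col]] <- as.integer(df[[col]])
  df$seed_perfect <- as.integer(df$seed_perfect) == 1L
  df
}

#' Write / read per-(RNA, gene) tallies
#'
#' @param tallies tally data frame as returned by [tally_per_gene()] /
#'   [classify_binding()].
#' @param path TSV path.
#' @export
write_tallies <- function(tallies, path) {
  stopifnot(is.data.frame(tallies))
  if (!"binding_type" %in% names(tallies)) tallies$binding_type <- NA_character_
  if (nrow(tallies) == 0) {
    tallies <- as.data.frame(setNames(rep(list(character(0)),
                                          length(TALLY_COLUMNS)),
                                      TALLY_COLUMNS))
  } else {
    tallies <- tallies[order(tallies$rna_id, tallies$gene_id), , drop = FALSE]
  }
  .write_tsv(tallies[TALLY_COLUMNS], path)
  invisible(path)
}

#' @rdname write_tallies
#' @export
read_tallies <- function(path) {
  df <- .read_tsv(path)
  missing <- setdiff(TALLY_COLUMNS, names(df))
  if (length(missing) > 0)
    .stopf("tally table is missing column(s): %s",
           paste(missing, collapse = ", "))
  for (col in c("best_identity_class", "n_windows_matching"))
    df[[col]] <- as.integer(df[[col]])
  df
}

#' Write / read per-RNA summaries
#'
#' @param summaries summary data frame as returned by [summarize_per_rna()].
#' @param path TSV path.
#' @export
write_summaries <- function(summaries, path) {
  stopifnot(is.data.frame(summaries))
  s <- as.data.frame(summaries)[SUMMARY_COLUMNS]
  s <- s[order(s$rna_id), , drop = FALSE]
  s$has_nontarget_binding <- as.integer(s$has_nontarget_binding)
  .write_tsv(s, path)
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  df <- .read_tsv(path)
  missing <- setdiff(SUMMARY_COLUMNS, names(df))
  if (length(missing) > 0)
    .stopf("summary table is missing column(s): %s",
           paste(missing, collapse = ", "))
  for (col in c("length_nt", "n_offtarget_genes"))
    df[[col]] <- as.integer(df[[col]])
  df$has_nontarget_binding <- as.integer(df$has_nontarget_binding) == 1L
  df
}

#' Write / read a structured statistics report
#'
#' The report is nested JSON, one record per test (name, statistic, df, p,
#' n, transforms, warnings). Numbers are written at full precision so a
#' write-then-read round trip reproduces the values exactly.
#'
#' @param report a named list, e.g. from [stats_report()].
#' @param path JSON path.
#' @export
write_stats_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_stats_report
#' @export
read_stats_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
}

#' Write all screening results to a directory
#'
#' Writes `hits.tsv`, `tallies.tsv`, `summaries.tsv` (when given) and
#' `stats_report.json` (when given) with deterministic row ordering.
#'
#' @param hits,tallies,summaries result tables (any may be `NULL` to skip).
#' @param stats named list for the JSON report, or `NULL`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(hits = NULL, tallies = NULL, summaries = NULL,
                          stats = NULL, out_dir = ".") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory: %s", out_dir)
  paths <- character(0)
  if (!is.null(hits))
    paths <- c(paths, write_hits(hits, file.path(out_dir, "hits.tsv")))
  if (!is.null(tallies))
    paths <- c(paths, write_tallies(tallies, file.path(out_dir, "tallies.tsv")))
  if (!is.null(summaries))
    paths <- c(paths, write_summaries(summaries,
                                      file.path(out_dir, "summaries.tsv")))
  if (!is.null(stats))
    paths <- c(paths, write_stats_report(stats,
                                         file.path(out_dir,
                                                   "stats_report.json")))
  invisible(paths)
}
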