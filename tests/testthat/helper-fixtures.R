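# fixture builders; everything generated in code, nothing stored on disk

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent reverse complement (no package code)
revcomp_chr <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(v) paste(rev(v), collapse = ""), "")
}

write_tsv_raw <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# hand-rolled FASTA writer so wrap-insensitivity tests do not depend on the
# package's own writer
write_fasta_raw <- function(seqs, path, width = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (width > 0) {
      starts <- seq(1, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
                 con)
    } else {
      writeLines(s, con)
    }
  }
  path
}

# minimal single-sequence-per-gene set
tiny_gene_set <- function(seqs, functional_group = NULL, quality = NULL,
                          ortholog_of = NULL) {
  n <- length(seqs)
  gene_set(data.frame(
    gene_id = names(seqs),
    gene_name = names(seqs),
    functional_group = functional_group %||% rep("other", n),
    quality_flag = quality %||% rep("normal", n),
    ortholog_of = ortholog_of %||% rep("", n),
    stringsAsFactors = FALSE), lapply(seqs, identity))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_registry <- function(seqs, molecule_class = NULL, target_gene = NULL,
                          taxon = NULL, category = NULL) {
  n <- length(seqs)
  as_registry(data.frame(
    rna_id = names(seqs), sequence = unname(unlist(seqs)),
    molecule_class = molecule_class %||% rep("dsRNA", n),
    target_gene_name = target_gene %||% paste0("t", seq_len(n)),
    target_species = paste0("sp", seq_len(n)),
    target_taxon = taxon %||% rep("Coleoptera", n),
    target_category = category %||% rep("other", n),
    source_study = "test", stringsAsFactors = FALSE))
}

# plant a (possibly mutated, possibly reverse-complemented) RNA window into a
# gene sequence; returns the modified gene string plus the truth record
plant_window <- function(gene_seq, rna_seq, rna_start0, gene_pos0,
                         strand = "+", n_sub = 0, k = 21) {
  wb <- substr(rna_seq, rna_start0 + 1, rna_start0 + k)
  if (strand == "-") wb <- revcomp_chr(wb)
  if (n_sub > 0) {
    v <- strsplit(wb, "", fixed = TRUE)[[1]]
    for (p in sample.int(k, n_sub))
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    wb <- paste(v, collapse = "")
  }
  substr(gene_seq, gene_pos0 + 1, gene_pos0 + k) <- wb
  list(gene_seq = gene_seq,
       truth = data.frame(rna_window_start = rna_start0, strand = strand,
                          gene_position = gene_pos0, mismatches = n_sub,
                          stringsAsFactors = FALSE))
}
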