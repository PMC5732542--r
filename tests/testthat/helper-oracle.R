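# independent brute-force matcher: double loop over every window (both
# orientations) and every subject position, strict ambiguity policy; used
# as the oracle the fast scan is compared against

oracle_scan <- function(rna_seq, gene_seqs, k = 21, max_mm = 2) {
  empty <- data.frame(rna_window_start = integer(0), strand = character(0),
                      gene_seq_index = integer(0), gene_position = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  L <- nchar(rna_seq)
  if (L >= k) { starts <- 0:(L - k); wl <- k } else { starts <- 0L; wl <- L }
  sense <- substring(toupper(rna_seq), starts + 1, starts + wl)
  wins <- data.frame(start = rep(starts, 2),
                     strand = rep(c("+", "-"), each = length(starts)),
                     bases = c(sense, revcomp_chr(sense)),
                     stringsAsFactors = FALSE)
  allowed <- if (wl >= k) max_mm else min(max_mm, wl - (k - max_mm))
  if (allowed < 0) return(empty)
  code <- function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    v[!v %in% c("A", "C", "G", "T")] <- NA
    v
  }
  out <- list()
  for (gi in seq_along(gene_seqs)) {
    sv <- code(gene_seqs[gi])
    n <- length(sv)
    if (n < wl) next
    npos <- n - wl + 1
    for (w in seq_len(nrow(wins))) {
      wv <- code(wins$bases[w])
      mm <- integer(npos)
      for (j in seq_len(wl)) {
        cmp <- sv[j:(j + npos - 1)] != wv[j]
        cmp[is.na(cmp)] <- TRUE            # strict: ambiguity = mismatch
        mm <- mm + cmp
      }
      hit <- which(mm <= allowed)
      if (length(hit) > 0)
        out[[length(out) + 1]] <- data.frame(
          rna_window_start = wins$start[w], strand = wins$strand[w],
          gene_seq_index = gi, gene_position = hit - 1L,
          mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

# canonical comparable key set for a hits table (single-sequence genes whose
# ids are gene_ids[gene_seq_index])
hit_keys <- function(df, gene_ids = NULL) {
  ids <- if (!is.null(gene_ids)) gene_ids[df$gene_seq_index] else df$gene_id
  sort(paste(ids, df$rna_window_start, df$strand, df$gene_position,
             df$mismatches, sep = ":"))
}
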