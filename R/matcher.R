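# Window enumeration and the exhaustive mismatch-tolerant scan. The scoring
# unit is a 21-nt window: hits are classed 19/21, 20/21 or 21/21 matched
# nucleotides (identity_class = k - mismatches). Molecules shorter than the
# window are matched full length and scored on the same over-21 scale
# (identity = L - mismatches), so e.g. a perfect 19-nt siRNA match is 19/21.

#' Enumerate siRNA-length windows from a pesticidal RNA
#'
#' Slides a window of `k` nucleotides (default 21, the scoring unit of the
#' identity-class scheme) along the RNA at step 1, modelling the siRNAs that
#' dicing can generate from any register of a dsRNA. Each offset yields a
#' sense window and, by default, an antisense window (the reverse complement
#' of the same stretch), since both strands of a dsRNA can be loaded as
#' guides. Molecules shorter than `k` yield a single full-length window pair
#' flagged `short_molecule`.
#'
#' @param rna a single-row `pesticidal_registry` data frame, or any list with
#'   elements `rna_id` and `sequence`.
#' @param k window length in nucleotides (>= 1).
#' @param include_antisense also enumerate reverse-complement windows.
#' @return data frame with columns `rna_id`, `start` (0-based offset on the
#'   RNA, half-open), `k`, `orientation` (`sense`/`antisense`), `bases`
#'   (window sequence as the guide would read it) and `short_molecule`.
#' @export
#' @examples
#' rna <- list(rna_id = "ds1", sequence = "ACGTACGTACGTACGTACGTACGTA")
#' enumerate_windows(rna)
enumerate_windows <- function(rna, k = 21L, include_antisense = TRUE) {
  if (is.data.frame(rna)) {
    stopifnot(nrow(rna) == 1)
    rna <- as.list(rna)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1) .stopf("k must be a positive integer")
  seq <- .normalize_seq(rna$sequence)
  L <- nchar(seq)
  if (L < 1) .stopf("RNA %s has an empty sequence", rna$rna_id)
  if (L >= k) {
    starts <- 0:(L - k)
    bases <- substring(seq, starts + 1, starts + k)
    short <- FALSE
  } else {
    starts <- 0L
    bases <- seq
    short <- TRUE
  }
  out <- data.frame(rna_id = rna$rna_id, start = starts, k = k,
                    orientation = "sense", bases = bases,
                    short_molecule = short, stringsAsFactors = FALSE)
  if (include_antisense) {
    anti <- out
    anti$orientation <- "antisense"
    anti$bases <- revcomp(out$bases)
    out <- rbind(out, anti)
  }
  rownames(out) <- NULL
  out
}

#' Count mismatches between equal-length base strings
#'
#' Hamming distance under a configurable ambiguity policy. Under `"strict"`
#' (the default, conservative for Ns in assemblies) any position holding a
#' non-ACGT code on either side counts as a mismatch, even `N` against `N`.
#' Under `"iupac"` two bases match when their IUPAC sets intersect (so `N`
#' matches anything). Comparison is case-insensitive.
#'
#' @param a,b equal-length base strings.
#' @param ambiguity_policy `"strict"` or `"iupac"`.
#' @return integer mismatch count.
#' @export
#' @examples
#' count_mismatches("ACGTA", "ACCTA")  # 1
#' count_mismatches("NACGT", "AACGT")  # 1 under strict
count_mismatches <- function(a, b, ambiguity_policy = c("strict", "iupac")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b))
    .stopf("sequences must have equal length (%d vs %d)", nchar(a), nchar(b))
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (ambiguity_policy == "strict") {
    acgt <- c("A", "C", "G", "T")
    sum(ca != cb | !(ca %in% acgt) | !(cb %in% acgt))
  } else {
    sum(bitwAnd(.iupac_bits(ca), .iupac_bits(cb)) == 0L)
  }
}

#' @noRd
.IUPAC_BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
                S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
                V = 7L, N = 15L)

#' @noRd
.iupac_bits <- function(chars) {
  out <- unname(.IUPAC_BIT[chars])
  out[is.na(out)] <- 0L
  out
}

#' Is the seed region of an alignment perfect?
#'
#' The seed region is positions 2-8 of the siRNA guide (1-based, 7 nt),
#' where perfect complementarity matters most for mRNA recognition. Returns
#' `TRUE` iff those positions carry no mismatch between the window and the
#' aligned subject stretch. Windows shorter than 8 nt return `FALSE` with a
#' warning (the seed region is not fully defined).
#'
#' @param window_bases the window sequence (guide orientation).
#' @param subject_bases the equal-length aligned subject stretch.
#' @param ambiguity_policy see [count_mismatches()].
#' @return logical.
#' @export
seed_perfect <- function(window_bases, subject_bases,
                         ambiguity_policy = c("strict", "iupac")) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  if (nchar(window_bases) != nchar(subject_bases))
    .stopf("window and subject must have equal length")
  if (nchar(window_bases) < 8) {
    .warnf("window shorter than 8 nt: seed region undefined, returning FALSE")
    return(FALSE)
  }
  count_mismatches(substr(window_bases, 2, 8), substr(subject_bases, 2, 8),
                   ambiguity_policy) == 0
}

# genes excluded from the searchable space, mirroring the conservative
# filtering of low-quality proteins / unknown-function genes
DEFAULT_EXCLUDE_FLAGS <- c("low_quality", "unknown_function", "unannotated")

#' Scan a gene set for windows of one pesticidal RNA
#'
#' Enumerates all `k`-nt windows of the RNA (both orientations) and reports
#' every position, in every sequence of every eligible gene, that matches
#' with at most `max_mismatches` substitutions (Hamming model; the
#' identity-class scheme has no gap semantics). Genes whose quality flag is
#' in `exclude_flags` are never searched; genes with zero sequences are
#' skipped with a message. Windows from molecules shorter than `k` (length
#' `L`) are scored as `L - mismatches` matched nucleotides over `k`, and
#' reported only when that identity reaches the minimum class
#' (`k - max_mismatches`, i.e. 19/21 at the defaults).
#'
#' The search is exhaustive and exact for its criteria: unlike a seeded
#' heuristic aligner it cannot miss a 19/21 match however the mismatches are
#' spaced.
#'
#' @param rna single-row registry entry (see [enumerate_windows()]).
#' @param genes a [gene_set()].
#' @param max_mismatches maximum substitutions per window (default 2, the
#'   19/21 class).
#' @param k window length (default 21).
#' @param include_antisense enumerate antisense windows too.
#' @param ambiguity_policy see [count_mismatches()].
#' @param exclude_flags quality flags excluded from the searchable space.
#' @return data frame of hits: `rna_id`, `gene_id`, `rna_window_start`
#'   (0-based), `gene_seq_index` (1-based index among the gene's sequences),
#'   `gene_position` (0-based, half-open), `strand` (`+` sense window, `-`
#'   antisense window), `mismatches`, `identity_class` (matched nt over `k`)
#'   and `seed_perfect`; deterministically ordered.
#' @export
scan_gene_set <- function(rna, genes, max_mismatches = 2L, k = 21L,
                          include_antisense = TRUE,
                          ambiguity_policy = c("strict", "iupac"),
                          exclude_flags = DEFAULT_EXCLUDE_FLAGS) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(inherits(genes, "gene_set"))
  k <- as.integer(k)
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0 || max_mismatches > k)
    .stopf("max_mismatches must be in [0, k]")
  if (nrow(genes$genes) == 0) .stopf("gene set is empty")

  keep <- !genes$genes$quality_flag %in% exclude_flags
  gene_ids <- genes$genes$gene_id[keep]
  nseq <- vapply(genes$sequences[gene_ids], length, integer(1))
  if (any(nseq == 0))
    message("skipping gene(s) with zero sequences: ",
            paste(gene_ids[nseq == 0], collapse = ", "))
  gene_ids <- gene_ids[nseq > 0]
  empty <- data.frame(rna_id = character(0), gene_id = character(0),
                      rna_window_start = integer(0),
                      gene_seq_index = integer(0), gene_position = integer(0),
                      strand = character(0), mismatches = integer(0),
                      identity_class = integer(0), seed_perfect = logical(0),
                      stringsAsFactors = FALSE)
  if (length(gene_ids) == 0) return(empty)

  subj <- unlist(genes$sequences[gene_ids], use.names = FALSE)
  subj_gene <- rep(gene_ids, vapply(genes$sequences[gene_ids], length,
                                    integer(1)))
  subj_idx <- unlist(lapply(genes$sequences[gene_ids],
                            function(s) seq_along(s)), use.names = FALSE)

  windows <- enumerate_windows(rna, k = k,
                               include_antisense = include_antisense)
  scan_fun <- if (ambiguity_policy == "strict") scan_windows_strict
              else scan_windows_iupac
  min_identity <- k - max_mismatches
  pieces <- list()
  for (L in unique(nchar(windows$bases))) {
    wsub <- windows[nchar(windows$bases) == L, , drop = FALSE]
    allowed <- if (L >= k) max_mismatches else
      min(max_mismatches, L - min_identity)
    if (allowed < 0) next
    res <- scan_fun(wsub$bases, subj, allowed)
    if (length(res$window) == 0) next
    seed_ok <- res$seed_perfect == 1L
    if (L < 8 && length(seed_ok) > 0) {
      .warnf("window(s) shorter than 8 nt: seed region undefined, seed_perfect = FALSE")
      seed_ok[] <- FALSE
    }
    pieces[[length(pieces) + 1]] <- data.frame(
      rna_id = rna$rna_id %||% wsub$rna_id[1],
      gene_id = subj_gene[res$subject],
      rna_window_start = wsub$start[res$window],
      gene_seq_index = subj_idx[res$subject],
      gene_position = res$position,
      strand = ifelse(wsub$orientation[res$window] == "sense", "+", "-"),
      mismatches = res$mismatches,
      identity_class = L - res$mismatches + (if (L >= k) k - L else 0L),
      seed_perfect = seed_ok,
      stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(empty)
  out <- do.call(rbind, pieces)
  out <- .order_hits(out)
  rownames(out) <- NULL
  out
}

#' Scan a gene set with every RNA of a registry
#'
#' Applies [scan_gene_set()] to each registry row and binds the hits.
#'
#' @param registry a `pesticidal_registry` data frame.
#' @inheritParams scan_gene_set
#' @return combined hit data frame (see [scan_gene_set()]).
#' @export
scan_registry <- function(registry, genes, max_mismatches = 2L, k = 21L,
                          include_antisense = TRUE,
                          ambiguity_policy = c("strict", "iupac"),
                          exclude_flags = DEFAULT_EXCLUDE_FLAGS) {
  ambiguity_policy <- match.arg(ambiguity_policy)
  stopifnot(is.data.frame(registry))
  pieces <- lapply(seq_len(nrow(registry)), function(i)
    scan_gene_set(registry[i, , drop = FALSE], genes,
                  max_mismatches = max_mismatches, k = k,
                  include_antisense = include_antisense,
                  ambiguity_policy = ambiguity_policy,
                  exclude_flags = exclude_flags))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
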