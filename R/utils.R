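# internal helpers shared across modules

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.is_iupac <- function(x) {
  grepl(sprintf("^[%s]+$", IUPAC_CHARS), x)
}

# uppercase, RNA alphabet (U) normalized to DNA (T)
#' @noRd
.normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement of nucleotide strings
#'
#' Full IUPAC-aware reverse complement (vectorised over a character vector).
#'
#' @param x character vector of nucleotide sequences (DNA alphabet).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# split a semicolon-separated ortholog list into a character vector
#' @noRd
.split_orthologs <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}
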