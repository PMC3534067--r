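# Sequence helpers shared across modules. All sequences are handled internally
# as uppercase DNA character vectors (U -> T on ingest, per the database
# convention for sequenced small RNAs).

DNA_BASES <- c("A", "C", "G", "T")

#' Normalize nucleotide input
#'
#' Uppercases and converts U to T. Mixed-case and RNA-alphabet input is
#' accepted everywhere in the package through this single entry point.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over the DNA alphabet.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA strings, vectorized over `n` sequences of length `len`.
random_dna <- function(n, len) {
  if (n == 0) return(character(0))
  vapply(
    seq_len(n),
    function(i) paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
    character(1)
  )
}

# Hamming distance between equal-length strings (vectorized over x).
hamming <- function(x, y) {
  stopifnot(all(nchar(x) == nchar(y)) || length(y) == 1)
  mapply(function(a, b) {
    sum(charToRaw(a) != charToRaw(b))
  }, x, if (length(y) == 1) rep(y, length(x)) else y, USE.NAMES = FALSE)
}

# Check sequences are over the ACGT(U) alphabet.
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTU]", normalize_seq(x))
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGTU characters: %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  invisible(TRUE)
}

# 1-based inclusive locus label in the "Gm02:8609718" reporting dialect.
locus_label <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d(%s)", chrom, start, end, strand)
}

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file.
#' @return A tibble with columns `name` (full header) and `seq`.
#' @export
read_fasta_tbl <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(name = names(x), seq = as.character(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector, or tibble with `name` and `seq`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$name)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
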