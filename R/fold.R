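# RNA secondary-structure folding with a simplified stacking energy model.
# The topology of the optimal structure (which bases pair, where the terminal
# loop sits) is what drives hairpin validation; absolute free energies of
# thermodynamic folders are deliberately not reproduced.

#' Fold an RNA/DNA sequence
#'
#' Deterministic dynamic program maximizing a stacking-weighted pairing score:
#' a pair stacked on an adjacent pair contributes 3 (G-C), 2 (A-U) or 1 (G-U)
#' score units, an unstacked pair contributes 1, and hairpin loops must
#' enclose at least 3 unpaired bases. The reported energy is the negated
#' optimal score (more negative = more stable). Ties are broken toward
#' 5'-most, outermost pairs, so output is reproducible.
#'
#' @param seq A single sequence, 10-400 bases, A/C/G/T/U.
#' @return An object of class `fold_result`: list with `seq`, `structure`
#'   (dot-bracket), `energy` and `pair_map` (1-based partner positions,
#'   `NA` = unpaired).
#' @export
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
fold_rna <- function(seq) {
  stopifnot(length(seq) == 1)
  seq <- normalize_seq(seq)
  assert_dna(seq, "fold input")
  n <- nchar(seq)
  if (n < 10 || n > 400) abort("fold_rna expects sequences of 10-400 bases")
  res <- fold_dp_cpp(seq)
  pm <- res$pairs
  pm[pm == 0] <- NA_integer_
  db <- rep(".", n)
  paired <- which(!is.na(pm))
  db[paired[pm[paired] > paired]] <- "("
  db[paired[pm[paired] < paired]] <- ")"
  structure(
    list(seq = seq, structure = paste(db, collapse = ""),
         energy = -res$score, pair_map = pm),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result> ", nchar(x$seq), " nt, energy ", x$energy, "\n", sep = "")
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' @rdname fold_rna
#' @param x A `fold_result`.
#' @param ... Unused.
#' @method tidy fold_result
#' @export
tidy.fold_result <- function(x, ...) {
  tibble(position = seq_len(nchar(x$seq)),
         base = strsplit(x$seq, "")[[1]],
         partner = x$pair_map,
         paired = !is.na(x$pair_map))
}
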