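# Preprocessing: raw fixed-length reads -> trimmed inserts -> collapsed
# per-library counts -> thresholded non-redundant signature database -> CPM.

DEFAULT_ADAPTER <- "TCGTATGCCGTCTTCTGCTTG"

#' Trim the 3' adapter from fixed-length reads
#'
#' Sequencing reads are a small-RNA insert followed by the ligated 3' adapter
#' and (for short inserts) arbitrary downstream bases, truncated to a fixed
#' read length of 35. The adapter junction is located as the *leftmost*
#' position at which the remainder of the read exactly matches the adapter
#' prefix over their full overlap. Reads that are adapter from base one are
#' empty constructs; inserts shorter than `min_len` are ligation artifacts;
#' reads with no junction are kept untrimmed (35-base inserts are legitimate:
#' the observed insert size range is 15-35 nt).
#'
#' @param reads Character vector of reads, each exactly `read_len` bases.
#' @param adapter 3' adapter sequence; must begin with `TCG`.
#' @param min_len Minimum retained insert length (default 15).
#' @param read_len Fixed read length (default 35).
#' @return A tibble with columns `read`, `insert` (NA when discarded) and
#'   `status` (`ok`, `untrimmed`, `empty`, `artifact`).
#' @export
#' @examples
#' ad <- "TCGTATGCCGTCTTCTGCTTG"
#' r <- paste0("TGAAGCTGCCAGCATGATCTT", substr(ad, 1, 14))
#' trim_adapter(r)
trim_adapter <- function(reads, adapter = DEFAULT_ADAPTER, min_len = 15,
                         read_len = 35) {
  reads <- normalize_seq(reads)
  adapter <- normalize_seq(adapter)
  if (!startsWith(adapter, "TCG")) {
    abort("adapter must start with the junction identifier TCG")
  }
  if (any(nchar(reads) != read_len)) {
    abort(sprintf("all reads must be exactly %d bases", read_len))
  }
  n <- length(reads)
  pos <- rep(NA_integer_, n)  # 0-based junction position == insert length
  alen <- nchar(adapter)
  for (i in 0:(read_len - 1)) {
    ov <- min(read_len - i, alen)
    todo <- is.na(pos)
    if (!any(todo)) break
    hit <- substr(reads[todo], i + 1, i + ov) == substr(adapter, 1, ov)
    pos[todo][hit] <- i
  }
  status <- dplyr::case_when(
    is.na(pos) ~ "untrimmed",
    pos == 0 ~ "empty",
    pos < min_len ~ "artifact",
    TRUE ~ "ok"
  )
  insert <- dplyr::case_when(
    status == "untrimmed" ~ reads,
    status == "ok" ~ substr(reads, 1, pos),
    TRUE ~ NA_character_
  )
  tibble(read = reads, insert = insert, status = status)
}

#' Collapse trimmed inserts into unique-sequence counts
#'
#' @param inserts Either a character vector of retained inserts, or a tibble
#'   with columns `library` and `insert` (NA inserts are dropped).
#' @return A tibble with columns (`library`,) `seq`, `count`.
#' @export
collapse_reads <- function(inserts) {
  if (is.data.frame(inserts)) {
    inserts %>%
      filter(!is.na(.data$insert)) %>%
      count(.data$library, seq = .data$insert, name = "count") %>%
      arrange(.data$library, .data$seq)
  } else {
    inserts <- inserts[!is.na(inserts)]
    if (length(inserts) == 0) return(tibble(seq = character(0), count = integer(0)))
    count(tibble(seq = inserts), .data$seq, name = "count") %>% arrange(.data$seq)
  }
}

#' Abundance threshold as a function of library depth
#'
#' Shallower libraries use a lower unique-read count cutoff: k = 5 up to and
#' including 3 million total reads, k = 16 from 12 million reads, k = 10 in
#' between.
#'
#' @param total_reads Numeric vector of library depths.
#' @return Integer vector of k thresholds.
#' @export
choose_threshold <- function(total_reads) {
  stopifnot(all(total_reads > 0))
  ifelse(total_reads <= 3e6, 5L, ifelse(total_reads >= 12e6, 16L, 10L))
}

#' Counts-per-million normalization
#'
#' @param raw_count Raw read count(s), >= 0.
#' @param total_reads Total raw reads in the library (the pre-filter depth).
#' @return `raw_count * 1e6 / total_reads`.
#' @export
normalize_cpm <- function(raw_count, total_reads) {
  if (any(total_reads == 0)) abort("total_reads must be positive")
  stopifnot(all(raw_count >= 0))
  raw_count * 1e6 / total_reads
}

#' Build the non-redundant thresholded signature database
#'
#' A sequence enters the union database iff at least one library observed it
#' with at least that library's k threshold; for included sequences the counts
#' from *every* library are retained, including sub-threshold ones.
#'
#' @param counts Tibble with columns `library`, `seq`, `count` (from
#'   [collapse_reads()]).
#' @param libraries Tibble with columns `library`, `total_reads` and
#'   optionally `k` (defaults to [choose_threshold()] of `total_reads`).
#' @return A tibble with one row per signature: `signature_id`, `seq`,
#'   `length`, one `n_<lib>` raw-count and one `cpm_<lib>` column per library
#'   (library order as in `libraries`).
#' @export
build_union_db <- function(counts, libraries) {
  if (!"k" %in% names(libraries)) {
    libraries <- mutate(libraries, k = choose_threshold(.data$total_reads))
  }
  counts <- counts %>%
    mutate(seq = normalize_seq(.data$seq)) %>%
    left_join(select(libraries, "library", "k"), by = "library")
  keep <- counts %>%
    group_by(.data$seq) %>%
    summarise(pass = any(.data$count >= .data$k), .groups = "drop") %>%
    filter(.data$pass)
  lib_order <- libraries$library
  wide <- counts %>%
    filter(.data$seq %in% keep$seq) %>%
    select("library", "seq", "count") %>%
    tidyr::pivot_wider(names_from = "library", values_from = "count",
                       values_fill = 0L, names_prefix = "n_")
  # guarantee a raw-count column for every library, in config order
  for (lib in lib_order) {
    cn <- paste0("n_", lib)
    if (!cn %in% names(wide)) wide[[cn]] <- 0L
  }
  wide <- wide[, c("seq", paste0("n_", lib_order))]
  totals <- setNames(libraries$total_reads, libraries$library)
  for (lib in lib_order) {
    wide[[paste0("cpm_", lib)]] <-
      normalize_cpm(wide[[paste0("n_", lib)]], totals[[lib]])
  }
  wide %>%
    arrange(.data$seq) %>%
    mutate(signature_id = sprintf("sig_%05d", row_number()),
           length = nchar(.data$seq)) %>%
    select("signature_id", "seq", "length", dplyr::everything())
}

# Long view of per-library raw counts of a union DB.
signature_counts_long <- function(signatures) {
  signatures %>%
    select("signature_id", "seq", "length", dplyr::starts_with("n_")) %>%
    tidyr::pivot_longer(dplyr::starts_with("n_"), names_to = "library",
                        names_prefix = "n_", values_to = "count")
}

#' Per-library size distribution of unique signatures
#'
#' Counts distinct signatures present (raw count >= 1) per length class and
#' their percentages; percentages sum to 100 over the length range within each
#' library.
#'
#' @param signatures Union DB from [build_union_db()].
#' @param lengths Length classes to tabulate (default 19:25).
#' @return Tibble with `library`, `length`, `n_signatures`, `pct`.
#' @export
size_distribution <- function(signatures, lengths = 19:25) {
  long <- signature_counts_long(signatures) %>%
    filter(.data$count >= 1, .data$length %in% lengths)
  libs <- unique(sub("^n_", "", grep("^n_", names(signatures), value = TRUE)))
  grid <- tidyr::expand_grid(library = libs, length = lengths)
  out <- long %>%
    count(.data$library, .data$length, name = "n_signatures") %>%
    dplyr::right_join(grid, by = c("library", "length")) %>%
    mutate(n_signatures = dplyr::coalesce(.data$n_signatures, 0L)) %>%
    group_by(.data$library) %>%
    mutate(pct = if (sum(.data$n_signatures) > 0)
      100 * .data$n_signatures / sum(.data$n_signatures) else 0) %>%
    ungroup() %>%
    arrange(.data$library, .data$length)
  out
}

#' Write a collapsed count table as a merged FASTA
#'
#' Headers follow the ">id_xCOUNT" dialect (e.g. `>sig_00001_x57`).
#'
#' @param counts Tibble with `seq` and `count`.
#' @param path Output FASTA path.
#' @export
write_collapsed_fasta <- function(counts, path) {
  ids <- sprintf("sig_%05d_x%d", seq_len(nrow(counts)), counts$count)
  write_fasta_tbl(setNames(counts$seq, ids), path)
}
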