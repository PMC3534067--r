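# Repeat / transposable-element profiling: family assignment at 95% identity,
# per-family size-class profiles (distinct signatures vs summed reads), region
# profiles for rDNA-like arrays, and multi-mapping statistics.

#' Read a transposable-element database FASTA
#'
#' The family is parsed from a `family=<name>` token in the header, or from
#' the second `|`-delimited field, falling back to `unknown`.
#'
#' @param path FASTA path.
#' @return Tibble: `name`, `family`, `seq`.
#' @export
read_te_fasta <- function(path) {
  x <- read_fasta_tbl(path)
  fam <- stringr::str_match(x$name, "family=([^ |;]+)")[, 2]
  pipe2 <- stringr::str_split_fixed(x$name, stringr::fixed("|"), 3)[, 2]
  fam <- dplyr::coalesce(fam, dplyr::na_if(pipe2, ""), "unknown")
  tibble(name = sub("\\s.*$", "", x$name), family = fam, seq = x$seq)
}

#' Assign signatures to TE families at bounded identity
#'
#' Each signature is placed ungapped (either strand) against every database
#' record; a hit requires identity of at least `min_identity` over the full
#' signature length (for 21-24-mers, at most one mismatch at the default
#' 0.95). The best hit's family is reported; equally good hits in different
#' families give `ambiguous`.
#'
#' @param seqs Character vector of signature sequences (or tibble with `seq`).
#' @param te_db Tibble from [read_te_fasta()] (columns `name`, `family`,
#'   `seq`), or a path to a TE FASTA.
#' @param min_identity Identity threshold over the signature (default 0.95).
#' @return Tibble: `seq`, `family` (NA if no hit), `identity`, `mismatches`.
#' @export
match_te_db <- function(seqs, te_db, min_identity = 0.95) {
  if (is.character(te_db) && length(te_db) == 1) te_db <- read_te_fasta(te_db)
  if (is.data.frame(seqs)) seqs <- seqs$seq
  seqs <- normalize_seq(seqs)
  te_seqs <- normalize_seq(te_db$seq)
  te_rc <- revcomp(te_seqs)
  rows <- purrr::map(seqs, function(s) {
    L <- nchar(s)
    max_mm <- L - ceiling(min_identity * L)
    best_mm <- Inf; fams <- character(0)
    for (ri in seq_along(te_seqs)) {
      if (nchar(te_seqs[ri]) < L) next
      mm <- min(min(mismatch_profile_cpp(te_seqs[ri], s)),
                min(mismatch_profile_cpp(te_rc[ri], s)))
      if (mm < best_mm) {
        best_mm <- mm; fams <- te_db$family[ri]
      } else if (mm == best_mm) {
        fams <- union(fams, te_db$family[ri])
      }
    }
    if (!is.finite(best_mm) || best_mm > max_mm) {
      tibble(seq = s, family = NA_character_, identity = NA_real_,
             mismatches = NA_integer_)
    } else {
      tibble(seq = s,
             family = if (length(fams) > 1) "ambiguous" else fams,
             identity = (L - best_mm) / L, mismatches = as.integer(best_mm))
    }
  })
  bind_rows(rows)
}

#' Per-family size-class profiles
#'
#' For each family, tabulates distinct signatures and summed reads by length
#' class, plus an aggregate over all assigned signatures. Signatures on the
#' exclusion list (e.g. an extremely abundant validated miRNA that happens to
#' graze a TE record) are dropped from the aggregate.
#'
#' @param assignments From [match_te_db()] (`seq`, `family`).
#' @param signatures Union DB tibble (for per-library read counts), or a
#'   tibble with `seq` and `total_count`.
#' @param lengths Length classes (default 19:25).
#' @param exclude Character vector of signature sequences excluded from the
#'   aggregate profile.
#' @return Tibble: `family` (`"all"` = aggregate), `length`, `n_unique`,
#'   `n_reads`.
#' @export
family_size_profiles <- function(assignments, signatures, lengths = 19:25,
                                 exclude = character(0)) {
  if (!"total_count" %in% names(signatures)) {
    signatures <- signatures %>%
      mutate(total_count = rowSums(dplyr::pick(dplyr::starts_with("n_"))))
  }
  df <- assignments %>%
    filter(!is.na(.data$family)) %>%
    left_join(select(signatures, "seq", "total_count"), by = "seq") %>%
    mutate(length = nchar(.data$seq)) %>%
    filter(.data$length %in% lengths)
  per_family <- df %>%
    group_by(.data$family, .data$length) %>%
    summarise(n_unique = dplyr::n_distinct(.data$seq),
              n_reads = sum(.data$total_count), .groups = "drop")
  aggregate <- df %>%
    filter(!(.data$seq %in% exclude)) %>%
    group_by(.data$length) %>%
    summarise(n_unique = dplyr::n_distinct(.data$seq),
              n_reads = sum(.data$total_count), .groups = "drop") %>%
    mutate(family = "all")
  bind_rows(per_family, aggregate) %>%
    select("family", "length", "n_unique", "n_reads") %>%
    arrange(.data$family, .data$length)
}

#' Size profile of signatures aligned to a genomic region
#'
#' Histograms aligned signatures by length, overall and per library, and
#' reports the fraction of each library's signatures attributable to the
#' region.
#'
#' @param region List/one-row tibble with `chrom`, `start`, `end`.
#' @param alignments Alignment tibble (`signature_id`, `chrom`, `start`,
#'   `end`).
#' @param signatures Union DB tibble (per-library `n_<lib>` columns).
#' @param lengths Length classes (default 19:25).
#' @return List with `overall` (tibble `length`, `n_signatures`),
#'   `per_library` (tibble `library`, `length`, `n_signatures`) and
#'   `library_fraction` (tibble `library`, `fraction` of that library's
#'   present signatures aligning to the region).
#' @export
region_size_profile <- function(region, alignments, signatures,
                                lengths = 19:25) {
  in_region <- alignments %>%
    filter(.data$chrom == region$chrom, .data$end >= region$start,
           .data$start <= region$end) %>%
    distinct(.data$signature_id)
  long <- signature_counts_long(signatures) %>% filter(.data$count >= 1)
  reg_long <- filter(long, .data$signature_id %in% in_region$signature_id)
  overall <- reg_long %>%
    distinct(.data$signature_id, .data$length) %>%
    count(.data$length, name = "n_signatures") %>%
    dplyr::right_join(tibble(length = lengths), by = "length") %>%
    mutate(n_signatures = dplyr::coalesce(.data$n_signatures, 0L)) %>%
    arrange(.data$length)
  per_library <- reg_long %>%
    count(.data$library, .data$length, name = "n_signatures")
  library_fraction <- long %>%
    group_by(.data$library) %>%
    summarise(fraction = mean(.data$signature_id %in%
                                in_region$signature_id), .groups = "drop")
  list(overall = overall, per_library = per_library,
       library_fraction = library_fraction)
}

#' Multi-mapping statistics by location-count band
#'
#' @param location_counts Tibble with `signature_id`, `location_count`
#'   (uncapped, from [apply_multimap_policy()]).
#' @param bands Band upper bounds; defaults reproduce the 1 / 2-10 / 11-103 /
#'   >103 banding.
#' @return Tibble: `band`, `n`, `pct`.
#' @export
multimap_statistics <- function(location_counts,
                                bands = c(1, 10, 103)) {
  lc <- location_counts$location_count
  lc <- lc[lc >= 1]
  labels <- c("1",
              sprintf("%d-%d", head(bands, -1) + 1, bands[-1]),
              sprintf(">%d", bands[length(bands)]))
  band <- cut(lc, breaks = c(0, bands, Inf), labels = labels)
  tibble(band = labels) %>%
    left_join(count(tibble(band = as.character(band)), .data$band),
              by = "band") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n) else 0)
}
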