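# Genome mapping of signatures with bounded substitutions, multi-mapping
# policy, reference-set annotation and gene-model joining.
#
# Coordinates in all tibbles are 1-based inclusive; BED export converts to
# 0-based half-open.

#' Index a genome for signature alignment
#'
#' @param genome Named character vector of chromosome sequences, a
#'   `DNAStringSet`, or a path to a FASTA file.
#' @return A `genome_index` object.
#' @export
index_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      !grepl("^[ACGTUacgtu]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(genome)) {
    if (length(genome) == 0) abort("empty genome")
    if (is.null(names(genome))) names(genome) <- paste0("Chr", seq_along(genome))
    genome <- Biostrings::DNAStringSet(normalize_seq(genome))
  }
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    abort("empty genome")
  }
  # header token up to first whitespace, as aligners do
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(dna = genome, lengths = setNames(Biostrings::width(genome),
                                                  names(genome))),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> ", length(x$dna), " sequence(s), ",
      sum(x$lengths), " bases\n", sep = "")
  invisible(x)
}

#' Align signatures to an indexed genome
#'
#' Reports every ungapped placement on either strand with at most `max_mm`
#' substitutions. The search is complete (no heuristic loss): each signature
#' is matched exhaustively against every chromosome. The default mismatch cap
#' of 4 reflects the practical ceiling observed for genuine small-RNA
#' placements.
#'
#' @param seqs Character vector of signature sequences (15-35 nt), or a tibble
#'   with columns `signature_id` and `seq`.
#' @param index A [index_genome()] object.
#' @param max_mm Maximum substitutions (default 4).
#' @return Tibble: `signature_id`, `seq`, `chrom`, `start`, `end`, `strand`,
#'   `mismatches`.
#' @export
align_signatures <- function(seqs, index, max_mm = 4) {
  stopifnot(inherits(index, "genome_index"))
  if (is.data.frame(seqs)) {
    ids <- seqs$signature_id
    seqs <- seqs$seq
  } else {
    ids <- if (!is.null(names(seqs))) names(seqs) else normalize_seq(seqs)
  }
  seqs <- normalize_seq(seqs)
  if (any(nchar(seqs) < 15 | nchar(seqs) > 35)) {
    abort("signatures must be 15-35 bases")
  }
  uniq <- !duplicated(seqs)
  lookup <- setNames(ids[uniq], seqs[uniq])
  hits <- purrr::map(seqs[uniq], function(s) {
    out <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") s else revcomp(s)
      m <- Biostrings::vmatchPattern(pat, index$dna, max.mismatch = max_mm,
                                     with.indels = FALSE, fixed = TRUE)
      for (ci in seq_along(m)) {
        r <- m[[ci]]
        if (length(r) == 0) next
        chrom <- names(index$dna)[ci]
        st <- IRanges::start(r); en <- IRanges::end(r)
        keep <- st >= 1 & en <= index$lengths[[chrom]]
        if (!any(keep)) next
        st <- st[keep]; en <- en[keep]
        got <- as.character(Biostrings::extractAt(
          index$dna[[ci]], IRanges::IRanges(st, en)))
        mm <- hamming(got, pat)
        out[[length(out) + 1]] <- tibble(
          seq = s, chrom = chrom, start = st, end = en,
          strand = strand, mismatches = as.integer(mm))
      }
    }
    bind_rows(out)
  })
  res <- bind_rows(hits)
  if (nrow(res) == 0) {
    return(tibble(signature_id = character(0), seq = character(0),
                  chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  res %>%
    mutate(signature_id = unname(lookup[.data$seq])) %>%
    select("signature_id", dplyr::everything()) %>%
    arrange(.data$signature_id, .data$chrom, .data$start, .data$strand)
}

# Independent brute-force Hamming scan (test oracle). Pure byte-vector R,
# shares no code with align_signatures.
brute_force_scan <- function(seq, genome, max_mm = 0) {
  seq <- normalize_seq(seq)
  if (is.null(names(genome))) names(genome) <- paste0("Chr", seq_along(genome))
  out <- list()
  for (chrom in names(genome)) {
    g <- charToRaw(normalize_seq(genome[[chrom]]))
    n <- length(g)
    for (strand in c("+", "-")) {
      p <- charToRaw(if (strand == "+") seq else revcomp(seq))
      L <- length(p)
      if (L > n) next
      mm <- integer(n - L + 1)
      for (k in seq_len(L)) {
        mm <- mm + (g[k:(n - L + k)] != p[k])
      }
      st <- which(mm <= max_mm)
      if (length(st)) {
        out[[length(out) + 1]] <- tibble(
          seq = seq, chrom = chrom, start = st, end = st + L - 1L,
          strand = strand, mismatches = as.integer(mm[st]))
      }
    }
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(seq = character(0), chrom = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  mismatches = integer(0)))
  }
  arrange(res, .data$chrom, .data$start, .data$strand)
}

#' Apply the multi-mapping recording policy
#'
#' The total placement count is always retained (it feeds the multi-map
#' statistics), but individual loci are recorded only for signatures mapping
#' to fewer than `record_cap` regions; at or above the cap the locus list is
#' emptied.
#'
#' @param alignments Tibble from [align_signatures()].
#' @param record_cap Strict upper bound for recorded loci (default 10:
#'   "fewer than 10 regions are entered").
#' @return A list with `counts` (tibble `signature_id`, `seq`,
#'   `location_count`) and `recorded` (alignment rows of signatures below the
#'   cap).
#' @export
apply_multimap_policy <- function(alignments, record_cap = 10) {
  counts <- alignments %>%
    group_by(.data$signature_id, .data$seq) %>%
    summarise(location_count = dplyr::n(), .groups = "drop")
  keep <- counts$signature_id[counts$location_count < record_cap]
  list(counts = counts,
       recorded = filter(alignments, .data$signature_id %in% keep))
}

#' Annotate signatures against a reference small-RNA set
#'
#' A reference matches a signature iff their best ungapped full-overlap
#' alignment (overlap = the shorter of the two lengths, slid along the longer)
#' has 0 mismatches when the overlap is 18 bases or less, or at most 1
#' mismatch for longer overlaps. The best annotation has the fewest
#' mismatches; ties break lexicographically on the reference name.
#'
#' @param seqs Character vector of signature sequences or tibble with
#'   `signature_id`, `seq`.
#' @param reference Tibble with `name`, `seq` (15-30 nt reference sequences),
#'   or named character vector.
#' @return Tibble: `signature_id`, `seq`, `annotation` (NA if none),
#'   `ann_mismatches`.
#' @export
annotate_signatures <- function(seqs, reference) {
  if (!is.data.frame(seqs)) {
    seqs <- tibble(signature_id = if (!is.null(names(seqs))) names(seqs)
                   else normalize_seq(seqs),
                   seq = normalize_seq(seqs))
  }
  if (!is.data.frame(reference)) {
    reference <- tibble(name = names(reference), seq = unname(reference))
  }
  reference <- mutate(reference, seq = normalize_seq(.data$seq)) %>%
    arrange(.data$name)
  ann <- purrr::map(normalize_seq(seqs$seq), function(s) {
    best_name <- NA_character_; best_mm <- NA_integer_
    for (ri in seq_len(nrow(reference))) {
      rs <- reference$seq[ri]
      long <- if (nchar(s) >= nchar(rs)) s else rs
      short <- if (nchar(s) >= nchar(rs)) rs else s
      ov <- nchar(short)
      mm <- min(mismatch_profile_cpp(long, short))
      allowed <- if (ov <= 18) 0L else 1L
      if (mm <= allowed && (is.na(best_mm) || mm < best_mm)) {
        best_mm <- as.integer(mm); best_name <- reference$name[ri]
      }
    }
    tibble(annotation = best_name, ann_mismatches = best_mm)
  })
  dplyr::bind_cols(seqs[, c("signature_id", "seq")], bind_rows(ann))
}

#' Parse a GFF3 file, skipping malformed lines with a warning
#'
#' @param path GFF3 file.
#' @return A `GRanges` with the usual `type`, `ID`, `Parent` metadata.
#' @export
parse_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- body & nfield != 9
  if (any(bad)) {
    warn(sprintf("skipping %d malformed GFF3 line(s), e.g.: %s",
                 sum(bad), substr(lines[which(bad)[1]], 1, 60)))
    tmp <- tempfile(fileext = ".gff3")
    writeLines(lines[!bad], tmp)
    on.exit(unlink(tmp))
    path <- tmp
  }
  rtracklayer::import(path, format = "gff3")
}

#' Join recorded loci to overlapping gene models
#'
#' Reports every gene whose span overlaps a locus by at least one base,
#' with the overlapped feature context (exon / intron / UTR; a locus
#' straddling a boundary reports both).
#'
#' @param loci Tibble with `signature_id`, `chrom`, `start`, `end`, `strand`.
#' @param gene_models GFF3 path or `GRanges` (from [parse_gff3()]).
#' @return Tibble: locus columns plus `gene_id` and `features`
#'   (";"-joined); loci with no overlapping gene are absent.
#' @export
join_gene_models <- function(loci, gene_models) {
  if (is.character(gene_models)) gene_models <- parse_gff3(gene_models)
  gr <- gene_models
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0) genes <- gr[type == "mRNA"]
  gene_ids <- as.character(genes$ID)
  exons <- gr[type == "exon"]
  utrs <- gr[type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")]
  if (nrow(loci) == 0 || length(genes) == 0) {
    return(tibble(signature_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  gene_id = character(0), features = character(0)))
  }
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start, loci$end))
  ov <- GenomicRanges::findOverlaps(lgr, genes, ignore.strand = TRUE)
  if (length(ov) == 0) {
    return(tibble(signature_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), strand = character(0),
                  gene_id = character(0), features = character(0)))
  }
  exon_parent <- if (length(exons)) {
    vapply(exons$Parent, function(p) as.character(p)[1], character(1))
  } else character(0)
  # exon Parent may name an mRNA; map via mRNA -> gene when needed
  mrna <- gr[type == "mRNA"]
  mrna_gene <- if (length(mrna)) {
    setNames(vapply(mrna$Parent, function(p)
      if (length(p)) as.character(p)[1] else NA_character_, character(1)),
      as.character(mrna$ID))
  } else character(0)
  resolve_gene <- function(p) {
    if (p %in% gene_ids) p
    else if (p %in% names(mrna_gene) && !is.na(mrna_gene[[p]])) mrna_gene[[p]]
    else p
  }
  exon_gene <- vapply(exon_parent, resolve_gene, character(1))

  rows <- purrr::map(seq_along(ov), function(i) {
    li <- S4Vectors::queryHits(ov)[i]
    gi <- S4Vectors::subjectHits(ov)[i]
    gid <- gene_ids[gi]
    l <- lgr[li]
    feats <- character(0)
    gex <- if (length(exons)) exons[exon_gene == gid] else exons
    introns <- GenomicRanges::setdiff(genes[gi], gex, ignore.strand = TRUE)
    if (length(gex) && length(GenomicRanges::findOverlaps(
      l, gex, ignore.strand = TRUE))) feats <- c(feats, "exon")
    if (length(introns) && length(GenomicRanges::findOverlaps(
      l, introns, ignore.strand = TRUE))) feats <- c(feats, "intron")
    if (length(utrs) && length(GenomicRanges::findOverlaps(
      l, utrs[vapply(utrs$Parent, function(p) resolve_gene(as.character(p)[1]),
                     character(1)) == gid],
      ignore.strand = TRUE))) feats <- c(feats, "UTR")
    if (length(feats) == 0) feats <- "intron"  # gene body with no exon model
    dplyr::bind_cols(loci[li, ], tibble(gene_id = gid,
                                        features = paste(feats, collapse = ";")))
  })
  bind_rows(rows)
}

#' Export recorded loci as BED (0-based half-open)
#'
#' @param loci Tibble with `chrom`, `start`, `end`, `strand` and an id column.
#' @param path Output path.
#' @param score Optional numeric score column name.
#' @export
write_bed <- function(loci, path, score = NULL) {
  id_col <- intersect(c("signature_id", "cluster_id", "name"), names(loci))[1]
  sc <- if (!is.null(score)) loci[[score]] else 0
  bed <- tibble(chrom = loci$chrom, start = loci$start - 1L, end = loci$end,
                name = loci[[id_col]], score = sc,
                strand = if ("strand" %in% names(loci)) loci$strand else "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
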