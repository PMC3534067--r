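# siRNA cluster detection and miRNA/siRNA discrimination: siRNA sources show
# many distinct signatures over a broad region, frequently on both strands;
# miRNA loci show one dominant signature over a ~21-nt footprint with strong
# strand bias and a validating hairpin.

#' Cluster recorded alignments into candidate siRNA regions
#'
#' Single-linkage merge of alignments on the same chromosome within `max_gap`
#' intervening bases, regardless of strand.
#'
#' @param alignments Recorded alignments (tibble with `signature_id`, `seq`,
#'   `chrom`, `start`, `end`, `strand`; a `count` column, if present, feeds
#'   the dominance statistic).
#' @param max_gap Maximum gap between merged alignments (default 200).
#' @return Tibble of clusters sorted by `n_signatures` descending:
#'   `cluster_id`, `chrom`, `start`, `end`, `n_signatures`, `n_alignments`,
#'   `footprint`, `breadth_ratio`, `plus_count`, `minus_count`,
#'   `strand_bias`, `dominant_fraction`, `alignments` (list-column).
#' @export
cluster_alignments <- function(alignments, max_gap = 200) {
  if (nrow(alignments) == 0) {
    return(tibble(cluster_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  n_signatures = integer(0), n_alignments = integer(0),
                  footprint = integer(0), breadth_ratio = numeric(0),
                  plus_count = integer(0), minus_count = integer(0),
                  strand_bias = numeric(0), dominant_fraction = numeric(0),
                  alignments = list()))
  }
  if (!"count" %in% names(alignments)) alignments$count <- 1L
  aln <- arrange(alignments, .data$chrom, .data$start, .data$end,
                 .data$strand, .data$seq)
  aln <- aln %>%
    group_by(.data$chrom) %>%
    mutate(gap = .data$start - cummax(dplyr::lag(.data$end,
                                                 default = dplyr::first(.data$end))) - 1L,
           newc = dplyr::row_number() == 1L | .data$gap > max_gap) %>%
    ungroup() %>%
    mutate(cl = cumsum(.data$newc))
  clusters <- aln %>%
    group_by(.data$cl) %>%
    dplyr::group_map(function(g, key) {
      red <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
      footprint <- sum(IRanges::width(red))
      region_len <- max(g$end) - min(g$start) + 1L
      per_sig <- g %>% group_by(.data$seq) %>%
        summarise(count = max(.data$count), .groups = "drop")
      tot_reads <- sum(per_sig$count)
      tibble(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
             n_signatures = dplyr::n_distinct(g$seq),
             n_alignments = nrow(g),
             footprint = as.integer(footprint),
             breadth_ratio = footprint / region_len,
             plus_count = sum(g$strand == "+"),
             minus_count = sum(g$strand == "-"),
             strand_bias = max(sum(g$strand == "+"),
                               sum(g$strand == "-")) / nrow(g),
             dominant_fraction = max(per_sig$count) / tot_reads,
             alignments = list(select(g, -dplyr::any_of(c("gap", "newc", "cl")))))
    }) %>%
    bind_rows()
  clusters %>%
    arrange(desc(.data$n_signatures), .data$chrom, .data$start) %>%
    mutate(cluster_id = sprintf("cl_%04d", row_number())) %>%
    select("cluster_id", dplyr::everything())
}

#' Classify clusters as miRNA-like, siRNA or ambiguous
#'
#' miRNA-like: footprint at most `mirna_footprint` bases, one dominant
#' sequence carrying at least `dominance` of the reads, strand bias at least
#' `strand_bias`, and an overlapping passing hairpin. siRNA: footprint at
#' least `sirna_footprint` with at least `sirna_min_sigs` distinct signatures.
#' Anything else is ambiguous.
#'
#' @param clusters From [cluster_alignments()].
#' @param hairpins Optional tibble of passing hairpin windows (`chrom`,
#'   `start`, `end`), e.g. accumulated from [validate_mirna_locus()] results.
#' @param mirna_footprint,dominance,strand_bias,sirna_footprint,sirna_min_sigs
#'   Classification thresholds (defaults 30 bases, 0.80, 0.90, 100 bases, 10).
#' @return `clusters` with a `class_label` column.
#' @export
classify_clusters <- function(clusters, hairpins = NULL,
                              mirna_footprint = 30, dominance = 0.80,
                              strand_bias = 0.90, sirna_footprint = 100,
                              sirna_min_sigs = 10) {
  has_hairpin <- rep(FALSE, nrow(clusters))
  if (!is.null(hairpins) && nrow(hairpins) > 0 && nrow(clusters) > 0) {
    cg <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(clusters$start, clusters$end))
    hg <- GenomicRanges::GRanges(hairpins$chrom,
                                 IRanges::IRanges(hairpins$start, hairpins$end))
    has_hairpin <- GenomicRanges::countOverlaps(cg, hg,
                                                ignore.strand = TRUE) > 0
  }
  clusters %>%
    mutate(class_label = dplyr::case_when(
      .data$footprint <= mirna_footprint &
        .data$dominant_fraction >= dominance &
        .data$strand_bias >= strand_bias & has_hairpin ~ "miRNA-like",
      .data$footprint >= sirna_footprint &
        .data$n_signatures >= sirna_min_sigs ~ "siRNA",
      TRUE ~ "ambiguous"))
}

#' Exon-only (spliced mRNA) test for a cluster
#'
#' For a cluster overlapping an intron-containing gene, computes the fraction
#' of aligned bases within the gene span that fall on annotated exons. A
#' fraction of at least `threshold` flags the cluster as processed from
#' spliced mRNA. Genes without introns are not testable (NA flag).
#'
#' @param cluster One cluster row from [cluster_alignments()].
#' @param gene_models GFF3 path or `GRanges`.
#' @param threshold Spliced flag threshold (default 0.98).
#' @return Tibble: `gene_id`, `exon_fraction`, `spliced_flag` (one row per
#'   overlapped gene; zero rows if the cluster overlaps no gene).
#' @export
exon_only_test <- function(cluster, gene_models, threshold = 0.98) {
  if (is.character(gene_models)) gene_models <- parse_gff3(gene_models)
  gr <- gene_models
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  aln <- cluster$alignments[[1]]
  agr <- GenomicRanges::GRanges(aln$chrom, IRanges::IRanges(aln$start, aln$end))
  cgr <- GenomicRanges::GRanges(cluster$chrom,
                                IRanges::IRanges(cluster$start, cluster$end))
  ov <- GenomicRanges::findOverlaps(cgr, genes, ignore.strand = TRUE)
  rows <- purrr::map(unique(S4Vectors::subjectHits(ov)), function(gi) {
    gid <- as.character(genes$ID[gi])
    gex <- exons[GenomicRanges::countOverlaps(exons, genes[gi],
                                              ignore.strand = TRUE) > 0]
    gex <- gex[vapply(gex$Parent, function(p) {
      any(grepl(gid, as.character(p), fixed = TRUE)) || length(p) == 0
    }, logical(1)) | rep(length(gex$Parent) == 0, length(gex))]
    introns <- GenomicRanges::setdiff(genes[gi], gex, ignore.strand = TRUE)
    ovg <- GenomicRanges::findOverlaps(agr, genes[gi], ignore.strand = TRUE)
    inside <- GenomicRanges::restrict(
      agr[S4Vectors::queryHits(ovg)],
      start = GenomicRanges::start(genes[gi]),
      end = GenomicRanges::end(genes[gi]))
    total <- sum(IRanges::width(inside))
    if (total == 0) {
      return(tibble(gene_id = gid, exon_fraction = NA_real_,
                    spliced_flag = NA))
    }
    ove <- GenomicRanges::findOverlaps(inside, gex, ignore.strand = TRUE)
    on_exon <- sum(IRanges::width(GenomicRanges::pintersect(
      inside[S4Vectors::queryHits(ove)],
      gex[S4Vectors::subjectHits(ove)], ignore.strand = TRUE)))
    frac <- on_exon / total
    flag <- if (length(introns) == 0) NA else frac >= threshold
    tibble(gene_id = gid, exon_fraction = frac, spliced_flag = flag)
  })
  bind_rows(rows)
}

#' Find inverted-repeat sources near a cluster
#'
#' Searches a region (cluster span plus `flank`) for arm pairs where one arm
#' matches the reverse complement of the other: seeded self-comparison with
#' exact k-mer seeds grouped by anti-diagonal, merged and scored for identity.
#'
#' @param region List/one-row tibble with `chrom`, `start`, `end`.
#' @param genome Genome (any form accepted by [index_genome()]).
#' @param flank Bases added on both sides (default 10000).
#' @param min_arm Minimum arm length (default 100).
#' @param min_identity Minimum arm identity (default 0.90).
#' @param max_spacer Maximum spacer between arms (default 5000).
#' @param k Seed length (default 12).
#' @param signatures Optional character vector of cluster signature
#'   sequences; those matching either arm (either strand, exact substring)
#'   are listed per repeat in a `matched_signatures` list-column.
#' @return Tibble: `chrom`, `arm1_start`, `arm1_end`, `arm2_start`,
#'   `arm2_end`, `arm_len`, `spacer`, `identity` (genomic coordinates).
#' @export
find_inverted_repeats <- function(region, genome, flank = 10000,
                                  min_arm = 100, min_identity = 0.90,
                                  max_spacer = 5000, k = 12,
                                  signatures = NULL) {
  idx <- if (inherits(genome, "genome_index")) genome else index_genome(genome)
  chrom <- region$chrom
  rs <- max(1L, region$start - as.integer(flank))
  re <- min(idx$lengths[[chrom]], region$end + as.integer(flank))
  s <- as.character(Biostrings::subseq(idx$dna[[chrom]], rs, re))
  n <- nchar(s)
  if (n < 2 * min_arm) return(empty_ir_tbl())
  r <- revcomp(s)
  ks <- substring(s, 1:(n - k + 1), k:n)
  kr <- substring(r, 1:(n - k + 1), k:n)
  hit <- match(kr, ks)  # first occurrence is enough for seeding
  seeds <- tibble(i = which(!is.na(hit)), j = hit[!is.na(hit)])
  if (nrow(seeds) == 0) return(empty_ir_tbl())
  # seed at (j in s, i in r) pairs s[j..] with s[(n-i-k+2)..(n-i+1)];
  # the offset d = j - i is invariant along an exact inverted-repeat stretch
  seeds <- seeds %>%
    mutate(d = .data$j - .data$i,
           arm1 = .data$j, arm2_end = n - .data$i + 1L) %>%
    filter(.data$arm1 + k - 1L < .data$arm2_end - k + 1L)  # arm1 left of arm2
  if (nrow(seeds) == 0) return(empty_ir_tbl())
  out <- seeds %>%
    group_by(.data$d) %>%
    dplyr::group_map(function(g, key) {
      a1 <- range(g$arm1)
      arm1_start <- a1[1]; arm1_end <- a1[2] + k - 1L
      arm_len <- arm1_end - arm1_start + 1L
      arm2_end <- max(g$arm2_end); arm2_start <- arm2_end - arm_len + 1L
      if (arm_len < min_arm) return(NULL)
      spacer <- arm2_start - arm1_end - 1L
      if (spacer < 0 || spacer > max_spacer) return(NULL)
      arm1 <- substr(s, arm1_start, arm1_end)
      arm2 <- substr(s, arm2_start, arm2_end)
      ident <- 1 - sum(charToRaw(arm1) != charToRaw(revcomp(arm2))) / arm_len
      if (ident < min_identity) return(NULL)
      tibble(chrom = chrom,
             arm1_start = rs + arm1_start - 1L, arm1_end = rs + arm1_end - 1L,
             arm2_start = rs + arm2_start - 1L, arm2_end = rs + arm2_end - 1L,
             arm_len = arm_len, spacer = spacer, identity = ident)
    }) %>%
    bind_rows()
  if (nrow(out) == 0) return(empty_ir_tbl())
  out <- arrange(out, desc(.data$arm_len))
  if (!is.null(signatures)) {
    signatures <- normalize_seq(signatures)
    out$matched_signatures <- purrr::map(seq_len(nrow(out)), function(i) {
      arms <- paste0(substr(s, out$arm1_start[i] - rs + 1L,
                            out$arm1_end[i] - rs + 1L),
                     "N",
                     substr(s, out$arm2_start[i] - rs + 1L,
                            out$arm2_end[i] - rs + 1L))
      hit <- vapply(signatures, function(sg) {
        grepl(sg, arms, fixed = TRUE) || grepl(revcomp(sg), arms, fixed = TRUE)
      }, logical(1))
      signatures[hit]
    })
  }
  out
}

empty_ir_tbl <- function() {
  tibble(chrom = character(0), arm1_start = integer(0), arm1_end = integer(0),
         arm2_start = integer(0), arm2_end = integer(0), arm_len = integer(0),
         spacer = integer(0), identity = numeric(0))
}
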