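# Pipeline orchestration and reporting: run all stages on a simulated (or
# user-supplied) study, build the unified expanded signature table, and
# recompute the cross-stage summary statistics. A report-only mode reproduces
# the arithmetic of a published eight-library soybean study design from its
# printed per-library and per-miRNA tables, without any raw data.

#' Eight-library soybean study summary (printed values)
#'
#' The per-library design this package's simulator emulates: library codes,
#' sequencing depth (raw reads), distinct trimmed signatures, reference-set
#' matches and genome-match percentage, as printed in the study summary
#' table. Used by the report-only consistency checks.
#'
#' @return A tibble with `library`, `tissue`, `total_reads`, `n_unique`,
#'   `n_mirbase`, `pct_genome`.
#' @export
ref_library_summary <- function() {
  tibble(
    library = c("WS", "SCR", "SCM", "SCW", "Cot", "GCot", "ST", "LE"),
    tissue = c("whole seed", "seed coat", "seed coat", "seed coat",
               "cotyledon", "germinating cotyledon", "stem", "leaf"),
    total_reads = c(3.0, 2.9, 6.1, 2.9, 3.0, 12.5, 4.2, 6.1) * 1e6,
    n_unique = c(38749L, 32846L, 35413L, 27343L, 27288L, 38961L, 37539L,
                 6855L),
    n_mirbase = c(393L, 475L, 263L, 525L, 390L, 876L, 486L, 273L),
    pct_genome = c(84, 85, 92, 87, 85, 80, 59, 70))
}

#' Selected miRNA expression rows (printed values)
#'
#' A subset of the printed normalized-count (reads per million) table for
#' well-characterized soybean miRNAs, used to check counts-per-million
#' arithmetic and major/star asymmetry.
#'
#' @return Tibble with `row`, `seq`, `length`, `name` and one cpm column per
#'   library.
#' @export
ref_mirna_table <- function() {
  tibble(
    row = c(1L, 4L, 7L, 8L, 10L, 11L, 12L),
    seq = c("TGAAGCTGCCAGCATGATCTT", "TAACTGAACATTCTTAGAGCAT",
            "TTGACAGAAGATAGAGAGCAC", "TTGACAGAAGAGAGAGAGCAC",
            "TCGGACCAGGCTTCATTCCCC", "GGAATGTTGTCTGGCTCGAGG",
            "TGAGACCAAATGAGCAGCTGA"),
    length = c(21L, 22L, 21L, 21L, 21L, 21L, 21L),
    name = c("gma-miR167e/f", "gma-miR1512c", "gma-miR156c/d/e/g",
             "gma-miR156b/f", "gma-miR166a-3p", "gma-miR166a-5p",
             "gma-miR3522"),
    cpm_WS = c(48472, 94395, 290, 214, 4471, 10, 3987),
    cpm_SCR = c(54106, 36802, 4381, 1631, 11557, 154, 1849),
    cpm_SCM = c(9009, 44554, 2889, 3171, 16665, 500, 4478),
    cpm_SCW = c(72015, 64171, 2053, 2018, 29735, 252, 2524),
    cpm_Cot = c(1540, 72, 25, 98674, 12361, 230, 112139),
    cpm_GCot = c(8512, 227, 14252, 42110, 5812, 45, 43366),
    cpm_ST = c(5, 5, 13237, 9, 24375, 23, 1478),
    cpm_LE = c(224, 0, 5014, 51, 5460, 182, 646995))
}

#' Transposable-element family signature counts (printed values)
#'
#' @return Tibble `family`, `n_signatures`.
#' @export
ref_te_family_counts <- function() {
  tibble(
    family = c("Gypsy", "Mutator", "Copia", "PIF-Harbinger", "L1", "CACTA",
               "unknown", "Helitron", "hAT", "Tc1-Mariner", "PONG"),
    n_signatures = c(27731L, 11397L, 11165L, 1384L, 1377L, 553L, 311L,
                     170L, 76L, 75L, 42L))
}

#' Report-only consistency checks on the printed study tables
#'
#' Recomputes, from printed numbers alone, the arithmetic a full pipeline run
#' would produce: the cross-library sum of unique signatures, total raw
#' reads, the depth-dependent abundance thresholds, raw counts back-derived
#' from printed counts-per-million, the TE-family total, and the printed
#' percentage ratios.
#'
#' @return A named list of recomputed quantities.
#' @export
report_table_consistency <- function() {
  libs <- ref_library_summary()
  mirna <- ref_mirna_table()
  te <- ref_te_family_counts()
  mir3522_le_raw <- mirna$cpm_LE[mirna$name == "gma-miR3522"] *
    libs$total_reads[libs$library == "LE"] / 1e6
  list(
    uniques_sum = sum(libs$n_unique),
    total_reads = sum(libs$total_reads),
    k_thresholds = setNames(choose_threshold(libs$total_reads), libs$library),
    mir3522_leaf_raw_reads = mir3522_le_raw,
    mir166a_major_arm = c("3p", "5p")[which.max(
      c(mirna$cpm_SCW[mirna$row == 10], mirna$cpm_SCW[mirna$row == 11]))],
    te_family_total = sum(te$n_signatures),
    pct_24nt_te_matched = 100 * 5187 / 41377,
    pct_multimapped = 100 * 41897 / 107279)
}

#' Run the full small RNA pipeline on a simulated study
#'
#' Stages: simulate -> trim/collapse -> threshold/union -> map -> annotate ->
#' size distribution -> clusters -> hairpin validation -> classification ->
#' exon tests -> phasing -> TE/repeat profiles -> summary.
#'
#' @param config A [sim_config()].
#' @param sim Optional pre-built [generate_genome()] result.
#' @param libraries Optional pre-built [simulate_libraries()] result.
#' @param max_mm,record_cap,max_gap Stage parameters (defaults 4, 10, 200).
#' @return An `srna_pipeline` list with every stage output and a `summary`
#'   list; see the vignette for a walk-through.
#' @export
run_pipeline <- function(config = sim_config(), sim = NULL, libraries = NULL,
                         max_mm = 4, record_cap = 10, max_gap = 200) {
  if (is.null(sim)) sim <- generate_genome(config)
  if (is.null(libraries)) libraries <- simulate_libraries(sim, config)

  # preprocess
  trimmed <- purrr::imap(libraries$reads, function(r, lib) {
    tr <- trim_adapter(r, config$adapter)
    tibble(library = lib, insert = tr$insert)
  }) %>% bind_rows()
  counts <- collapse_reads(trimmed)
  lib_spec <- tibble(library = config$libraries$library,
                     total_reads = config$libraries$depth) %>%
    mutate(k = choose_threshold(.data$total_reads))
  signatures <- build_union_db(counts, lib_spec)
  signatures <- mutate(signatures,
                       total_count = rowSums(dplyr::pick(dplyr::starts_with("n_"))))
  sizedist <- size_distribution(signatures)

  # mapping + annotation
  index <- index_genome(sim$genome)
  aln <- align_signatures(select(signatures, "signature_id", "seq"), index,
                          max_mm = max_mm)
  policy <- apply_multimap_policy(aln, record_cap = record_cap)
  reference <- mirna_reference(sim)
  annotations <- annotate_signatures(
    select(signatures, "signature_id", "seq"),
    tibble(name = names(reference), seq = unname(reference)))
  signatures <- signatures %>%
    left_join(select(annotations, "signature_id", "annotation",
                     "ann_mismatches"), by = "signature_id") %>%
    left_join(select(policy$counts, "signature_id", "location_count"),
              by = "signature_id") %>%
    mutate(location_count = dplyr::coalesce(.data$location_count, 0L))

  # clusters
  recorded <- policy$recorded %>%
    left_join(select(signatures, "signature_id", "total_count"),
              by = "signature_id") %>%
    rename(count = "total_count")
  clusters <- cluster_alignments(recorded, max_gap = max_gap)

  # hairpin validation of miRNA-like cluster dominants
  hp_cand <- clusters %>%
    filter(.data$footprint <= 60, .data$dominant_fraction >= 0.5)
  hairpins <- purrr::map(seq_len(nrow(hp_cand)), function(i) {
    a <- hp_cand$alignments[[i]]
    dom <- a %>% group_by(.data$signature_id) %>%
      summarise(count = max(.data$count), .groups = "drop") %>%
      slice(which.max(.data$count))
    locus <- a %>% filter(.data$signature_id == dom$signature_id) %>% slice(1)
    hp <- validate_mirna_locus(locus, index)
    list(cluster_id = hp_cand$cluster_id[i],
         signature_id = dom$signature_id, locus = locus, hairpin = hp)
  })
  hairpin_tbl <- purrr::map(hairpins, function(h) {
    g <- glance(h$hairpin)
    best <- if (h$hairpin$pass) h$hairpin$windows[h$hairpin$best, ] else NULL
    tibble(cluster_id = h$cluster_id, signature_id = h$signature_id,
           seq = h$locus$seq, chrom = h$locus$chrom,
           mature_start = h$locus$start, mature_end = h$locus$end,
           strand = h$locus$strand,
           pass = g$pass, arm = g$arm, energy = g$energy,
           win_start = if (!is.null(best)) best$win_start else NA_integer_,
           win_end = if (!is.null(best)) best$win_end else NA_integer_)
  }) %>% bind_rows()
  pass_windows <- hairpin_tbl %>%
    filter(.data$pass) %>%
    select("chrom", start = "win_start", end = "win_end")
  clusters <- classify_clusters(clusters, pass_windows)

  # gene models + exon tests on siRNA clusters
  gff <- tempfile(fileext = ".gff3")
  writeLines(sim_gff3(sim), gff)
  gene_models <- parse_gff3(gff)
  unlink(gff)
  sirna_cl <- filter(clusters, .data$class_label == "siRNA")
  exon_tests <- purrr::map(seq_len(nrow(sirna_cl)), function(i) {
    res <- exon_only_test(sirna_cl[i, ], gene_models)
    if (nrow(res)) mutate(res, cluster_id = sirna_cl$cluster_id[i]) else NULL
  }) %>% bind_rows()

  # phasing over siRNA clusters with the annotated matures as triggers
  phase_regions <- filter(clusters, .data$class_label == "siRNA",
                          .data$n_signatures >= 8)
  phased <- detect_phased_loci(phase_regions, index, reference, recorded)

  # miRNA family grouping: annotated signatures plus unannotated cluster
  # dominants with a validating hairpin
  fam_input <- signatures %>%
    left_join(hairpin_tbl %>% filter(.data$pass) %>%
                distinct(.data$signature_id) %>%
                mutate(hairpin_pass = TRUE),
              by = "signature_id") %>%
    mutate(hairpin_pass = dplyr::coalesce(.data$hairpin_pass, FALSE)) %>%
    filter(!is.na(.data$annotation) | .data$hairpin_pass) %>%
    select("seq", "annotation", "total_count", "hairpin_pass")
  families <- group_families(fam_input)

  # repeats
  te_feats <- filter(sim$features, .data$kind == "te_copy")
  te_hits <- NULL
  profiles <- NULL
  if (nrow(te_feats) > 0) {
    te_db <- tibble(
      name = te_feats$feature_id,
      family = vapply(te_feats$payload, function(p) p$family, character(1)),
      seq = substring(sim$genome[["Chr01"]], te_feats$start, te_feats$end))
    te_hits <- match_te_db(signatures$seq, te_db)
    exclude <- signatures$seq[!is.na(signatures$annotation) &
                                signatures$seq %in%
                                te_hits$seq[!is.na(te_hits$family)]]
    profiles <- family_size_profiles(te_hits, signatures, exclude = exclude)
  }
  mm_stats <- multimap_statistics(
    filter(policy$counts, .data$location_count >= 1))
  rdna <- filter(sim$features, .data$kind == "rdna_unit")
  rdna_profile <- if (nrow(rdna) > 0) {
    region_size_profile(rdna[1, ], aln, signatures)
  } else NULL

  expanded <- build_expanded_table(signatures, policy, gene_models, lib_spec,
                                   record_cap)

  summary <- list(
    total_raw_reads = sum(config$libraries$depth),
    per_library_uniques = counts %>% count(.data$library, name = "n_unique"),
    uniques_sum = nrow(distinct(counts, .data$library, .data$seq)),
    union_db_size = nrow(signatures),
    genome_matched = sum(signatures$location_count >= 1),
    pct_genome_matched = 100 * mean(signatures$location_count >= 1),
    n_clusters = nrow(clusters),
    cluster_classes = count(clusters, .data$class_label),
    n_hairpins_pass = sum(hairpin_tbl$pass),
    n_families = dplyr::n_distinct(families$family),
    n_phased_loci = sum(phased$p_value < 0.05 / max(1, nrow(phased))),
    seed = config$seed)

  structure(list(config = config, sim = sim, libraries = lib_spec,
                 counts = counts, signatures = signatures,
                 size_distribution = sizedist, alignments = aln,
                 policy = policy, clusters = clusters,
                 hairpins = hairpin_tbl, families = families,
                 exon_tests = exon_tests,
                 phased = phased, te_hits = te_hits,
                 te_profiles = profiles, multimap = mm_stats,
                 rdna_profile = rdna_profile, expanded = expanded,
                 summary = summary),
            class = "srna_pipeline")
}

#' @export
print.srna_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<srna_pipeline>\n",
      " raw reads:        ", s$total_raw_reads, "\n",
      " union signatures: ", s$union_db_size, "\n",
      " genome matched:   ", s$genome_matched,
      sprintf(" (%.1f%%)\n", s$pct_genome_matched),
      " clusters:         ", s$n_clusters, "\n",
      " passing hairpins: ", s$n_hairpins_pass, "\n",
      " phased loci:      ", s$n_phased_loci, "\n", sep = "")
  invisible(x)
}

#' @rdname run_pipeline
#' @param x An `srna_pipeline`.
#' @param ... Unused.
#' @method glance srna_pipeline
#' @export
glance.srna_pipeline <- function(x, ...) {
  s <- x$summary
  tibble(total_raw_reads = s$total_raw_reads,
         union_db_size = s$union_db_size,
         genome_matched = s$genome_matched,
         pct_genome_matched = s$pct_genome_matched,
         n_clusters = s$n_clusters,
         n_hairpins_pass = s$n_hairpins_pass,
         n_phased_loci = s$n_phased_loci)
}

#' Build the unified expanded signature table
#'
#' One row per signature with id, sequence, length, annotation, per-library
#' raw counts, per-library cpm, recorded loci (";"-joined `chrom:start-end
#' (strand)` labels; empty at or above the recording cap), overlapping gene
#' models and the uncapped location count.
#'
#' @param signatures Union DB with annotation and `location_count`.
#' @param policy Output of [apply_multimap_policy()].
#' @param gene_models `GRanges` or GFF3 path (may be NULL).
#' @param lib_spec Tibble `library`, `total_reads`.
#' @param record_cap Recording cap used.
#' @return A tibble.
#' @export
build_expanded_table <- function(signatures, policy, gene_models, lib_spec,
                                 record_cap = 10) {
  loci_str <- policy$recorded %>%
    group_by(.data$signature_id) %>%
    summarise(loci = paste(locus_label(.data$chrom, .data$start, .data$end,
                                       .data$strand), collapse = ";"),
              .groups = "drop")
  gm <- if (!is.null(gene_models)) {
    join_gene_models(policy$recorded, gene_models) %>%
      group_by(.data$signature_id) %>%
      summarise(gene_models = paste(unique(.data$gene_id), collapse = ";"),
                .groups = "drop")
  } else tibble(signature_id = character(0), gene_models = character(0))
  signatures %>%
    left_join(loci_str, by = "signature_id") %>%
    left_join(gm, by = "signature_id") %>%
    mutate(loci = dplyr::coalesce(.data$loci, ""),
           gene_models = dplyr::coalesce(.data$gene_models, ""),
           annotation = dplyr::coalesce(.data$annotation, "")) %>%
    select("signature_id", "seq", "length", "annotation",
           dplyr::starts_with("n_"), dplyr::starts_with("cpm_"),
           "loci", "gene_models", "location_count")
}

#' Write / read the expanded signature table
#'
#' @param expanded Tibble from [build_expanded_table()].
#' @param path TSV path.
#' @export
export_expanded_table <- function(expanded, path) {
  write.table(expanded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_expanded_table
#' @export
parse_expanded_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  out <- as_tibble(df)
  num_cols <- grep("^(n_|cpm_)|^(length|location_count)$", names(out),
                   value = TRUE)
  for (cn in num_cols) {
    out[[cn]] <- if (grepl("^cpm_", cn)) as.numeric(out[[cn]])
    else as.integer(out[[cn]])
  }
  for (cn in c("annotation", "loci", "gene_models")) {
    out[[cn]][is.na(out[[cn]])] <- ""
  }
  out
}
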