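# Synthetic study generator: a genome with planted small-RNA-producing
# features (miRNA hairpins, inverted-repeat siRNA sources, a TAS-like phased
# locus with its trigger, transposon families, an rDNA-like tandem array,
# spliced background genes) and eight tissue libraries of fixed-length
# adapter-bearing reads with machine-readable truth, so every downstream
# stage of the pipeline has a no-download test surface.

#' Default eight-library design
#'
#' Five seed-type libraries (whole seed, seed coats, immature cotyledon) with
#' a 24-nt-modal length profile and three vegetative/germinating libraries
#' (germinating cotyledon, stem, leaf) with a 21-nt-modal profile, mirroring
#' the tissue contrast of multi-organ plant small-RNA studies.
#'
#' @param depth Reads per library (default 1e5).
#' @return Tibble: `library`, `group`, `depth`, `w19`..`w25` (length
#'   sampling weights, each row summing to 1).
#' @export
default_libraries <- function(depth = 1e5) {
  seed_w <- c(0.02, 0.04, 0.14, 0.13, 0.07, 0.45, 0.15)
  veg_w <- c(0.03, 0.06, 0.40, 0.15, 0.07, 0.19, 0.10)
  libs <- tibble(
    library = c("WS", "SCR", "SCM", "SCW", "Cot", "GCot", "ST", "LE"),
    group = c(rep("seed", 5), rep("vegetative", 3)),
    depth = depth)
  w <- rbind(matrix(seed_w, 5, 7, byrow = TRUE),
             matrix(veg_w, 3, 7, byrow = TRUE))
  colnames(w) <- paste0("w", 19:25)
  dplyr::bind_cols(libs, as_tibble(w))
}

#' Default transposable-element family design
#'
#' Copy numbers and per-copy divergence; the Gypsy family is planted as
#' identical copies (a high-copy exact repeat, exercising the multi-mapping
#' band above the recording cap), the others diverge 1% per copy.
#'
#' @export
default_te_families <- function() {
  tibble(family = c("Gypsy", "Copia", "Mutator", "CACTA"),
         copies = c(12L, 8L, 6L, 5L),
         divergence = c(0, 0.01, 0.01, 0.01))
}

#' Simulation configuration
#'
#' @param genome_length Total genome size in bases.
#' @param n_mirna Number of planted miRNA hairpins.
#' @param n_star_expressed How many of the hairpins also express a detectable
#'   star (miRNA*) product (default 3; star strands of the remaining hairpins
#'   are degraded, as is typical).
#' @param n_sirna_sources Number of inverted-repeat siRNA sources.
#' @param te_families Tibble as from [default_te_families()].
#' @param n_background_genes Background gene models (the first one carries a
#'   spliced-mRNA-derived siRNA cluster for the exon-only test).
#' @param libraries Tibble as from [default_libraries()].
#' @param background_fraction Fraction of reads drawn from random genome
#'   positions rather than planted products (default 0.10).
#' @param error_rate Per-base substitution probability on reads (default
#'   0.005; must be <= 0.05).
#' @param adapter 3' adapter ligated to every insert.
#' @param mirna_matures Optional character vector seeding the first mature
#'   sequences (21-mers); remaining matures are random.
#' @param include_tas,include_rdna Plant the TAS-like phased locus (requires
#'   `n_mirna >= 1` for its trigger) / the rDNA-like tandem array.
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_length = 100000, n_mirna = 20,
                       n_star_expressed = 3, n_sirna_sources = 5,
                       te_families = default_te_families(),
                       n_background_genes = 5,
                       libraries = default_libraries(),
                       background_fraction = 0.10, error_rate = 0.002,
                       adapter = DEFAULT_ADAPTER, mirna_matures = NULL,
                       include_tas = TRUE, include_rdna = TRUE, seed = 1) {
  cfg <- list(genome_length = genome_length, n_mirna = n_mirna,
              n_star_expressed = min(n_star_expressed, n_mirna),
              n_sirna_sources = n_sirna_sources, te_families = te_families,
              n_background_genes = n_background_genes, libraries = libraries,
              background_fraction = background_fraction,
              error_rate = error_rate, adapter = normalize_seq(adapter),
              mirna_matures = if (is.null(mirna_matures)) NULL
                              else normalize_seq(mirna_matures),
              include_tas = include_tas && n_mirna >= 1,
              include_rdna = include_rdna, seed = seed)
  w <- as.matrix(libraries[, paste0("w", 19:25)])
  if (any(abs(rowSums(w) - 1) > 1e-9)) {
    abort("per-library length weights must sum to 1")
  }
  if (any(libraries$depth <= 0)) abort("library depths must be positive")
  if (error_rate < 0 || error_rate > 0.05) {
    abort("error_rate must be in [0, 0.05]")
  }
  if (background_fraction < 0 || background_fraction >= 1) {
    abort("background_fraction must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

# A candidate insert is usable only if a read built from it trims back to it
# (no chance full-overlap adapter-prefix junction upstream of the real one):
# the generator guarantees identifiability of every planted product.
insert_trims_ok <- function(seqs, adapter) {
  reads <- substr(paste0(seqs, strrep(adapter, 3)), 1, 35)
  tr <- trim_adapter(reads, adapter)
  tr$status == "ok" & !is.na(tr$insert) & tr$insert == seqs
}

# Draw `n` distinct random inserts of length `len`, trim-identifiable and
# previously unseen (tracked in environment `seen`).
draw_inserts <- function(n, len, adapter, seen) {
  out <- character(0)
  while (length(out) < n) {
    cand <- random_dna(n - length(out) + 4, len)
    ok <- insert_trims_ok(cand, adapter) & !duplicated(cand) &
      !vapply(cand, function(s) !is.null(seen[[s]]), logical(1))
    cand <- cand[ok]
    for (s in cand) seen[[s]] <- TRUE
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

# Take `n` distinct substrings of `feature_seq` as products (random offsets,
# lengths, strands), all trim-identifiable.
substring_products <- function(feature_seq, n, lengths, len_weights, adapter,
                               seen, region = NULL, strands = c("+", "-")) {
  if (is.null(region)) region <- cbind(1, nchar(feature_seq))
  out <- list()
  guard <- 0
  while (length(out) < n && guard < 50 * n) {
    guard <- guard + 1
    L <- if (length(lengths) == 1) lengths
         else sample(lengths, 1, prob = len_weights)
    ri <- sample(nrow(region), 1)
    lo <- region[ri, 1]; hi <- region[ri, 2]
    if (hi - lo + 1 < L) next
    st <- sample(lo:(hi - L + 1), 1)
    strand <- sample(strands, 1)
    s <- substr(feature_seq, st, st + L - 1)
    if (strand == "-") s <- revcomp(s)
    if (!is.null(seen[[s]]) || !insert_trims_ok(s, adapter)) next
    seen[[s]] <- TRUE
    out[[length(out) + 1]] <- tibble(seq = s, local_start = st,
                                     local_end = st + L - 1L, strand = strand)
  }
  bind_rows(out)
}

# Build one hairpin precursor: flank + arm + loop + revcomp(arm) + flank,
# with the mature embedded in the arm ("5p") or its reverse complement
# ("3p"), and the star span offset +2 from the mature's pairing partners
# (the 2-nt 3' overhang of the processing duplex).
build_hairpin <- function(mature, arm_side, adapter, seen,
                          arm_len = 70, flank = 8, loop_len = 8,
                          arm_offset = 20) {
  L <- nchar(mature)
  for (try in 1:50) {
    arm <- random_dna(1, arm_len)
    embedded <- if (arm_side == "5p") mature else revcomp(mature)
    substr(arm, arm_offset + 1, arm_offset + L) <- embedded
    prec <- paste0(random_dna(1, flank), arm, random_dna(1, loop_len),
                   revcomp(arm), random_dna(1, flank))
    hit <- gregexpr(mature, prec, fixed = TRUE)[[1]]
    if (length(hit) != 1 || hit[1] == -1) next
    a <- hit[1]; b <- a + L - 1
    n <- nchar(prec)
    # Soften the duplex: convert several mature:partner pairs to G:U
    # wobbles. The fold still pairs them, but the mature then has > 4
    # substitutions against the reverse complement of its own partner arm,
    # so it does not self-align on the minus strand (perfect-palindrome
    # stems are not what real precursors look like).
    wobble_at <- which(strsplit(mature, "")[[1]] %in% c("G", "T"))
    if (length(wobble_at) < 5) next
    pick <- sort(sample(wobble_at, min(6, length(wobble_at))))
    for (t in pick) {
      x <- a + t - 1          # mature base position in the precursor
      partner <- n + 1 - x    # its pairing partner on the opposite arm
      mb <- substr(prec, x, x)
      substr(prec, partner, partner) <- if (mb == "G") "T" else "G"
    }
    # stem pairing: position x pairs flank + (2*arm_len + loop) ... i.e.
    # partner(x) = flank + 1 + (n - flank) - x  == n + 1 - x  when flanks
    # are equal length; star = partner span shifted +2 (3' overhang)
    star_start <- (n + 1 - b) + 2L
    star_end <- (n + 1 - a) + 2L
    star <- substr(prec, star_start, star_end)
    if (!is.null(seen[[star]]) || star == mature) next
    if (!insert_trims_ok(star, adapter)) next
    seen[[star]] <- TRUE
    return(list(precursor = prec, mature_start = a, mature_end = b,
                star = star, star_start = star_start, star_end = star_end,
                arm = arm_side))
  }
  abort("could not construct an identifiable hairpin for the given mature")
}

# TE family product design: distinct substrings of one copy with a family-
# specific 22/24-nt balance. Gypsy: many abundant distinct 22-mers; Copia /
# Mutator: many distinct low-copy 24-mers; CACTA: 22-biased.
te_product_design <- function(family) {
  switch(family,
    Gypsy = list(n22 = 30, w22 = 20, n24 = 10, w24 = 1),
    Copia = list(n22 = 5, w22 = 8, n24 = 35, w24 = 1),
    Mutator = list(n22 = 5, w22 = 8, n24 = 30, w24 = 1),
    CACTA = list(n22 = 15, w22 = 10, n24 = 8, w24 = 1),
    list(n22 = 5, w22 = 4, n24 = 10, w24 = 2))
}

#' Generate a synthetic genome with planted small-RNA features
#'
#' Features are placed at non-overlapping loci separated by random background
#' gaps; the truth tables are exhaustive (every feature, every expressible
#' product with its genomic coordinates and relative abundance weight, and
#' per-feature tissue multipliers).
#'
#' @param config A [sim_config()].
#' @return An `srna_sim` list: `genome` (named character vector of
#'   chromosomes), `features` (tibble with payload list-column), `products`
#'   (tibble: `product_id`, `feature_id`, `kind`, `family`, `seq`, `length`,
#'   `chrom`, `start`, `end`, `strand`, `weight`), `multipliers` (tibble:
#'   `feature_id`, `library`, `multiplier`), `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  adapter <- config$adapter
  seen <- new.env(parent = emptyenv())
  libs <- config$libraries$library
  seed_libs <- config$libraries$library[config$libraries$group == "seed"]
  veg_libs <- setdiff(libs, seed_libs)

  features <- list()   # each: feature_id, kind, seq, payload, mult (named)
  products <- list()   # local products per feature

  mult_row <- function(seed_m, veg_m, special = NULL) {
    m <- setNames(ifelse(libs %in% seed_libs, seed_m, veg_m), libs)
    if (!is.null(special)) m[names(special)] <- special
    m
  }

  add_feature <- function(id, kind, seq, payload, mult, prods) {
    features[[length(features) + 1]] <<- list(
      feature_id = id, kind = kind, seq = seq, payload = payload, mult = mult)
    if (!is.null(prods) && nrow(prods) > 0) {
      prods$feature_id <- id
      prods$kind <- kind
      products[[length(products) + 1]] <<- prods
    }
  }

  # --- miRNA hairpins -------------------------------------------------
  matures <- character(config$n_mirna)
  if (config$n_mirna > 0) {
    n_given <- length(config$mirna_matures)
    for (i in seq_len(config$n_mirna)) {
      if (i <= n_given) {
        m <- config$mirna_matures[i]
        if (!insert_trims_ok(m, adapter)) {
          abort(sprintf("supplied mature %s is not trim-identifiable", m))
        }
        seen[[m]] <- TRUE
        matures[i] <- m
      } else {
        matures[i] <- draw_inserts(1, 21, adapter, seen)
      }
    }
    for (i in seq_len(config$n_mirna)) {
      arm_side <- if (i %% 2 == 1) "5p" else "3p"
      hp <- build_hairpin(matures[i], arm_side, adapter, seen)
      star_w <- if (i <= config$n_star_expressed) 8 else 0
      # tissue pattern: i %% 3 == 1 constitutive, 2 seed-specific,
      # 0 vegetative-specific (the trigger, i == 1, stays constitutive)
      mult <- switch(as.character(i %% 3),
                     "1" = mult_row(1, 1),
                     "2" = mult_row(1, 0.02),
                     "0" = mult_row(0.02, 1))
      prods <- tibble(
        seq = c(matures[i], hp$star),
        local_start = c(hp$mature_start, hp$star_start),
        local_end = c(hp$mature_end, hp$star_end),
        strand = "+", weight = c(100, star_w),
        role = c("mature", "star"))
      prods <- filter(prods, .data$weight > 0)
      add_feature(sprintf("mir%03d", i), "mirna_hairpin", hp$precursor,
                  list(mature = matures[i], star = hp$star, arm = hp$arm,
                       mature_start = hp$mature_start,
                       mature_end = hp$mature_end,
                       star_expressed = star_w > 0),
                  mult, prods)
    }
  }

  # --- inverted-repeat siRNA sources ---------------------------------
  arm_len <- 350L; spacer_len <- 500L
  for (i in seq_len(config$n_sirna_sources)) {
    arm <- random_dna(1, arm_len)
    seqf <- paste0(arm, random_dna(1, spacer_len), revcomp(arm))
    region <- rbind(c(1, arm_len),
                    c(arm_len + spacer_len + 1, nchar(seqf)))
    prods <- substring_products(
      seqf, 40, c(21, 22, 24), c(8, 10, 22) / 40, adapter, seen, region)
    prods$weight <- if_else(nchar(prods$seq) == 24, 4, 2)
    prods$role <- "sirna"
    # inverted-repeat siRNA sources are seed-coat restricted, like the
    # classic chalcone-synthase siRNAs
    add_feature(sprintf("ir%02d", i), "sirna_inverted_repeat", seqf,
                list(arm_len = arm_len, spacer = spacer_len),
                mult_row(1, 0), prods)
  }

  # --- TAS-like phased locus -----------------------------------------
  if (config$include_tas) {
    trigger <- matures[1]
    L <- nchar(trigger)
    rc <- revcomp(trigger)
    ok <- FALSE
    for (try in 1:50) {
      tx <- random_dna(1, 300)
      site_start <- 40L
      site <- rc
      # three non-wobble mismatches -> 18 exact matches at the site
      for (j in c(3L, 13L, 20L)) {
        e <- substr(site, j, j)
        repl <- switch(e, C = c("A", "G"), A = c("C", "T"),
                       G = c("A", "C", "T"), T = c("A", "C", "G"))
        substr(site, j, j) <- sample(repl, 1)
      }
      substr(tx, site_start, site_start + L - 1) <- site
      cp <- site_start + L - 10L
      d_starts <- cp + 21L * (0:9)
      off_start <- cp + 100L
      as_end <- cp - 2L + 21L * 5L  # antisense partner of phase window D5
      sense_seqs <- substring(tx, c(d_starts, off_start),
                              c(d_starts, off_start) + 20L)
      as_seq <- revcomp(substr(tx, as_end - 20L, as_end))
      cand <- c(sense_seqs, as_seq)
      if (anyDuplicated(cand) || !all(insert_trims_ok(cand, adapter)) ||
          any(vapply(cand, function(s) !is.null(seen[[s]]), logical(1)))) {
        next
      }
      for (s in cand) seen[[s]] <- TRUE
      prods <- tibble(
        seq = cand,
        local_start = c(d_starts, off_start, as_end - 20L),
        local_end = c(d_starts, off_start, as_end - 20L) + 20L,
        strand = c(rep("+", 11), "-"),
        weight = c(12, 12, 60, rep(12, 7), 8, 6),
        role = c(sprintf("D%d", 1:10), "off_register", "antisense_D5"))
      add_feature("tas01", "tas_locus", tx,
                  list(trigger = trigger, trigger_feature = "mir001",
                       site_start = site_start, cleavage_offset = cp,
                       phased_roles = sprintf("D%d", 1:10)),
                  mult_row(1, 1), prods)
      ok <- TRUE
      break
    }
    if (!ok) abort("could not construct an identifiable TAS locus")
  }

  # --- transposable-element families ---------------------------------
  te <- config$te_families
  for (fi in seq_len(nrow(te))) {
    fam <- te$family[fi]
    consensus <- random_dna(1, 500)
    design <- te_product_design(fam)
    copies <- vapply(seq_len(te$copies[fi]), function(ci) {
      if (te$divergence[fi] <= 0) return(consensus)
      s <- strsplit(consensus, "")[[1]]
      nmut <- stats::rbinom(1, length(s), te$divergence[fi])
      if (nmut > 0) {
        pos <- sample(length(s), nmut)
        s[pos] <- vapply(s[pos], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    # products cut from a random copy so every product occurs in the genome
    copy_of <- sample(te$copies[fi],
                      design$n22 + design$n24, replace = TRUE)
    lens <- c(rep(22L, design$n22), rep(24L, design$n24))
    prods_list <- list()
    for (pi in seq_along(lens)) {
      p <- substring_products(copies[copy_of[pi]], 1, lens[pi], 1,
                              adapter, seen)
      if (nrow(p) == 0) next
      p$copy_index <- copy_of[pi]
      p$weight <- if (lens[pi] == 22L) design$w22 else design$w24
      prods_list[[length(prods_list) + 1]] <- p
    }
    prods <- bind_rows(prods_list)
    prods$role <- "te_sirna"
    # one feature per copy; products attach to their source copy
    for (ci in seq_len(te$copies[fi])) {
      cp_prods <- filter(prods, .data$copy_index == ci) %>%
        select(-"copy_index")
      # transposon-derived siRNAs are a developing-seed phenomenon here:
      # repeats are transcriptionally silent in the vegetative libraries
      add_feature(sprintf("te_%s_%02d", fam, ci), "te_copy", copies[ci],
                  list(family = fam, copy_index = ci,
                       divergence = te$divergence[fi]),
                  mult_row(1, 0), cp_prods)
    }
  }

  # --- rDNA-like tandem array ----------------------------------------
  if (config$include_rdna) {
    unit <- random_dna(1, 600)
    array_seq <- strrep(unit, 5)
    prods <- bind_rows(
      substring_products(unit, 14, 21, 1, adapter, seen),
      substring_products(unit, 10, 22, 1, adapter, seen),
      substring_products(unit, 12, 24, 1, adapter, seen))
    prods$weight <- dplyr::case_when(nchar(prods$seq) == 21 ~ 6,
                                     nchar(prods$seq) == 22 ~ 5,
                                     TRUE ~ 1)
    prods$role <- "rdna_sirna"
    add_feature("rdna01", "rdna_unit", array_seq,
                list(unit_len = 600L, copies = 5L),
                mult_row(1, 1, special = c(GCot = 2)), prods)
  }

  # --- background genes ----------------------------------------------
  exon_lens <- c(300L, 250L, 250L); intron_lens <- c(150L, 150L)
  for (i in seq_len(config$n_background_genes)) {
    gene_seq <- random_dna(1, sum(exon_lens) + sum(intron_lens))
    starts <- cumsum(c(1L, head(as.integer(rbind(exon_lens, c(intron_lens, 0))), -1)))
    exon_starts <- starts[c(1, 3, 5)]
    exon_ends <- exon_starts + exon_lens - 1L
    prods <- NULL
    if (i == 1) {  # spliced-mRNA-derived siRNA source: exonic products only
      prods <- substring_products(gene_seq, 30, c(21, 22), c(0.5, 0.5),
                                  adapter, seen,
                                  region = cbind(exon_starts, exon_ends))
      prods$weight <- 3
      prods$role <- "gene_sirna"
    }
    add_feature(sprintf("gene%02d", i), "background_gene", gene_seq,
                list(exon_starts = exon_starts, exon_ends = exon_ends),
                mult_row(1, 1), prods)
  }

  # --- assemble the genome -------------------------------------------
  n_feat <- length(features)
  feat_lens <- vapply(features, function(f) nchar(f$seq), integer(1))
  # gaps wider than the downstream clustering max_gap, so neighbouring
  # features never merge into one alignment cluster
  gaps <- if (n_feat > 0) sample(250:500, n_feat, replace = TRUE) else integer(0)
  needed <- sum(feat_lens) + sum(gaps) + 500
  if (needed > config$genome_length) {
    abort(sprintf(
      "genome_length %d too small for requested features (need >= %d)",
      config$genome_length, needed))
  }
  order_idx <- sample(n_feat)
  pieces <- character(0)
  pos <- 0L
  feat_start <- integer(n_feat)
  for (oi in seq_along(order_idx)) {
    fi <- order_idx[oi]
    pieces <- c(pieces, random_dna(1, gaps[oi]))
    pos <- pos + gaps[oi]
    feat_start[fi] <- pos + 1L
    pieces <- c(pieces, features[[fi]]$seq)
    pos <- pos + feat_lens[fi]
  }
  pieces <- c(pieces, random_dna(1, config$genome_length - pos))
  genome <- c(Chr01 = paste(pieces, collapse = ""))

  feature_tbl <- purrr::imap(features, function(f, i) {
    tibble(feature_id = f$feature_id, kind = f$kind, chrom = "Chr01",
           start = feat_start[i], end = feat_start[i] + nchar(f$seq) - 1L,
           strand = "+", payload = list(f$payload))
  }) %>% bind_rows()

  product_tbl <- bind_rows(products)
  if (nrow(product_tbl) > 0) {
    fs <- setNames(feature_tbl$start, feature_tbl$feature_id)
    product_tbl <- product_tbl %>%
      mutate(chrom = "Chr01",
             start = unname(fs[.data$feature_id]) + .data$local_start - 1L,
             end = unname(fs[.data$feature_id]) + .data$local_end - 1L,
             length = nchar(.data$seq)) %>%
      mutate(product_id = sprintf("p%04d", row_number()))
    fam <- setNames(
      vapply(features, function(f)
        if (f$kind == "te_copy") f$payload$family else NA_character_,
        character(1)),
      vapply(features, function(f) f$feature_id, character(1)))
    product_tbl$family <- unname(fam[product_tbl$feature_id])
    product_tbl <- select(product_tbl, "product_id", "feature_id", "kind",
                          "family", "role", "seq", "length", "chrom",
                          "start", "end", "strand", "weight")
  } else {
    product_tbl <- tibble(product_id = character(0), feature_id = character(0),
                          kind = character(0), family = character(0),
                          role = character(0), seq = character(0),
                          length = integer(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), weight = numeric(0))
  }

  mult_tbl <- purrr::map(features, function(f) {
    tibble(feature_id = f$feature_id, library = libs,
           multiplier = unname(f$mult[libs]))
  }) %>% bind_rows()

  structure(list(genome = genome, features = feature_tbl,
                 products = product_tbl, multipliers = mult_tbl,
                 config = config),
            class = "srna_sim")
}

#' @export
print.srna_sim <- function(x, ...) {
  cat("<srna_sim> genome ", sum(nchar(x$genome)), " bases, ",
      nrow(x$features), " planted features, ", nrow(x$products),
      " products\n", sep = "")
  invisible(x)
}

# Random background inserts (trim-identifiable genome substrings).
background_inserts <- function(n, len, genome, adapter) {
  g <- genome[[1]]
  gl <- nchar(g)
  out <- character(0)
  while (length(out) < n) {
    m <- n - length(out)
    st <- sample.int(gl - len + 1L, m, replace = TRUE)
    s <- substring(g, st, st + len - 1L)
    min_idx <- runif(m) < 0.5
    s[min_idx] <- revcomp(s[min_idx])
    s <- s[insert_trims_ok(s, adapter)]
    out <- c(out, s)
  }
  out[seq_len(n)]
}

apply_read_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  n_err <- stats::rbinom(length(reads), nchar(reads)[1], rate)
  for (i in which(n_err > 0)) {
    r <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(r), n_err[i])
    r[pos] <- vapply(r[pos], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
    reads[i] <- paste(r, collapse = "")
  }
  reads
}

#' Simulate sequencing libraries from a planted genome
#'
#' Each read is a sampled insert (length drawn from the library's 19-25
#' profile; sequence drawn from planted products weighted by
#' `weight x tissue multiplier`, or from random genome background with
#' probability `background_fraction`) followed by the 3' adapter, truncated
#' to exactly 35 bases, with substitution errors applied at `error_rate`.
#'
#' @param sim An `srna_sim` from [generate_genome()].
#' @param config Optional [sim_config()] (defaults to `sim$config`).
#' @return List: `reads` (named list, one character vector of 35-base reads
#'   per library), `truth_counts` (tibble `library`, `product_id`, `seq`,
#'   `count` of error-free planted draws), `background_counts` (tibble
#'   `library`, `seq`, `count`).
#' @export
simulate_libraries <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "srna_sim"))
  withr::local_seed(config$seed + 1L)
  adapter <- config$adapter
  libs <- config$libraries
  prods <- sim$products %>%
    left_join(sim$multipliers, by = "feature_id",
              relationship = "many-to-many")
  reads_out <- list()
  truth <- list()
  bg_out <- list()
  for (li in seq_len(nrow(libs))) {
    lib <- libs$library[li]
    depth <- libs$depth[li]
    w <- as.numeric(libs[li, paste0("w", 19:25)])
    plib <- filter(prods, .data$library == lib) %>%
      mutate(eff_w = .data$weight * .data$multiplier)
    if (config$background_fraction == 0) {
      # without a background pool, only lengths with expressible products
      # can produce reads; renormalize the profile over those
      avail <- vapply(19:25, function(L)
        any(plib$length == L & plib$eff_w > 0), logical(1))
      if (!any(avail & w > 0)) {
        abort("no expressible products for any profiled length")
      }
      w[!avail] <- 0
      w <- w / sum(w)
    }
    len_counts <- as.vector(stats::rmultinom(1, depth, w))
    inserts <- character(0)
    pids <- character(0)
    for (k in seq_along(len_counts)) {
      L <- 18L + k
      nL <- len_counts[k]
      if (nL == 0) next
      pL <- filter(plib, .data$length == L, .data$eff_w > 0)
      n_bg <- stats::rbinom(1, nL, config$background_fraction)
      if (nrow(pL) == 0) n_bg <- nL
      n_feat <- nL - n_bg
      if (n_feat > 0) {
        pick <- sample.int(nrow(pL), n_feat, replace = TRUE, prob = pL$eff_w)
        inserts <- c(inserts, pL$seq[pick])
        pids <- c(pids, pL$product_id[pick])
      }
      if (n_bg > 0) {
        bg <- background_inserts(n_bg, L, sim$genome, adapter)
        inserts <- c(inserts, bg)
        pids <- c(pids, rep(NA_character_, n_bg))
      }
    }
    perm <- sample(length(inserts))
    inserts <- inserts[perm]; pids <- pids[perm]
    reads <- substr(paste0(inserts, strrep(adapter, 3)), 1, 35)
    reads <- apply_read_errors(reads, config$error_rate)
    reads_out[[lib]] <- reads
    is_bg <- is.na(pids)
    if (any(!is_bg)) {
      truth[[lib]] <- tibble(library = lib, product_id = pids[!is_bg],
                             seq = inserts[!is_bg]) %>%
        count(.data$library, .data$product_id, .data$seq, name = "count")
    }
    if (any(is_bg)) {
      bg_out[[lib]] <- tibble(library = lib, seq = inserts[is_bg]) %>%
        count(.data$library, .data$seq, name = "count")
    }
  }
  list(reads = reads_out, truth_counts = bind_rows(truth),
       background_counts = bind_rows(bg_out))
}

#' Write a simulated study to disk
#'
#' Emits the genome FASTA, one FASTQ per library (35-base reads, constant
#' quality `I`), a GFF3 of background gene models, a per-family TE database
#' FASTA (`family=` token in headers), a miRBase-like reference FASTA built
#' from the planted matures, truth TSV tables and a flat `key: value` config
#' summary.
#'
#' @param sim An `srna_sim`.
#' @param libraries Output of [simulate_libraries()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, libraries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta_tbl(sim$genome, file.path(dir, "genome.fa"))
  for (lib in names(libraries$reads)) {
    reads <- libraries$reads[[lib]]
    con <- file(file.path(dir, paste0(lib, ".fastq")), "w")
    writeLines(paste0("@", lib, "_", seq_along(reads), "\n", reads, "\n+\n",
                      strrep("I", 35)), con)
    close(con)
  }
  te <- filter(sim$features, .data$kind == "te_copy")
  if (nrow(te) > 0) {
    fam <- vapply(te$payload, function(p) p$family, character(1))
    seqs <- substring(sim$genome[["Chr01"]], te$start, te$end)
    write_fasta_tbl(setNames(seqs, paste0(te$feature_id, " family=", fam)),
                    file.path(dir, "te_db.fa"))
  }
  write_fasta_tbl(mirna_reference(sim), file.path(dir, "mirna_ref.fa"))
  writeLines(sim_gff3(sim), file.path(dir, "genes.gff3"))
  write.table(select(sim$products, -"seq") %>%
                mutate(seq = sim$products$seq),
              file.path(dir, "truth_products.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(libraries$truth_counts, file.path(dir, "truth_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  writeLines(c(
    paste0("genome_length: ", cfg$genome_length),
    paste0("n_mirna: ", cfg$n_mirna),
    paste0("n_sirna_sources: ", cfg$n_sirna_sources),
    paste0("background_fraction: ", cfg$background_fraction),
    paste0("error_rate: ", cfg$error_rate),
    paste0("adapter: ", cfg$adapter),
    paste0("seed: ", cfg$seed)),
    file.path(dir, "config.txt"))
  invisible(dir)
}

#' Reference annotation set of planted matures
#'
#' Names follow the conventional `miR<family>-<arm>` dialect so downstream
#' family grouping behaves as with a real reference set.
#'
#' @param sim An `srna_sim`.
#' @return Named character vector (name -> mature sequence).
#' @export
mirna_reference <- function(sim) {
  mir <- filter(sim$features, .data$kind == "mirna_hairpin")
  if (nrow(mir) == 0) return(character(0))
  out <- character(0)
  for (i in seq_len(nrow(mir))) {
    p <- mir$payload[[i]]
    num <- as.integer(sub("mir", "", mir$feature_id[i]))
    out[sprintf("syn-miR%03d-%s", num, p$arm)] <- p$mature
    if (isTRUE(p$star_expressed)) {
      out[sprintf("syn-miR%03d-%s", num, setdiff(c("5p", "3p"), p$arm))] <-
        p$star
    }
  }
  out
}

# GFF3 lines for the background gene models (gene/mRNA/exon hierarchy).
sim_gff3 <- function(sim) {
  genes <- filter(sim$features, .data$kind == "background_gene")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    p <- g$payload[[1]]
    gid <- g$feature_id
    lines <- c(lines,
      sprintf("Chr01\tsim\tgene\t%d\t%d\t.\t+\t.\tID=%s", g$start, g$end, gid),
      sprintf("Chr01\tsim\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.1;Parent=%s",
              g$start, g$end, gid, gid))
    for (e in seq_along(p$exon_starts)) {
      lines <- c(lines, sprintf(
        "Chr01\tsim\texon\t%d\t%d\t.\t+\t.\tID=%s.1.exon%d;Parent=%s.1",
        g$start + p$exon_starts[e] - 1L, g$start + p$exon_ends[e] - 1L,
        gid, e, gid))
    }
  }
  lines
}
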