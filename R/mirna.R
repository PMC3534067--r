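# miRNA locus validation: precursor window extraction around a mapped mature
# signature, folding, hairpin criteria, 5p/3p duplex geometry and family
# grouping.

#' Extract candidate precursor windows around a mature locus
#'
#' Precursors are generally on the order of 200 nt, with the mature product
#' excised from either arm; windows are therefore scanned so the mature
#' signature sits at a range of offsets covering both arms. Window sequences
#' are reported in transcription orientation (reverse-complemented for minus
#' strand loci) and clipped at chromosome ends.
#'
#' @param locus One-row tibble/list with `chrom`, `start`, `end`, `strand`.
#' @param genome Named character vector, `DNAStringSet` or [index_genome()].
#' @param window Window width in bases (default 200).
#' @param stride Offset scan stride (default 20).
#' @param margin Minimum distance of the mature span from window edges
#'   (default 10).
#' @return Tibble: `chrom`, `win_start`, `win_end`, `strand`,
#'   `mature_offset` (1-based within the oriented window), `mature_len`,
#'   `seq`.
#' @export
extract_precursor_windows <- function(locus, genome, window = 200,
                                      stride = 20, margin = 10) {
  idx <- if (inherits(genome, "genome_index")) genome else index_genome(genome)
  chrom <- locus$chrom; start <- locus$start; end <- locus$end
  strand <- locus$strand
  L <- end - start + 1
  chrom_len <- idx$lengths[[chrom]]
  offs <- seq(margin, window - L - margin, by = stride)
  rows <- purrr::map(offs, function(o) {
    if (strand == "+") {
      ws <- start - o + 1L
      we <- ws + window - 1L
    } else {
      we <- end + o - 1L
      ws <- we - window + 1L
    }
    ws2 <- max(1L, ws); we2 <- min(chrom_len, we)
    # mature must survive clipping
    if (start < ws2 || end > we2) return(NULL)
    sq <- as.character(Biostrings::subseq(idx$dna[[chrom]], ws2, we2))
    off <- if (strand == "+") start - ws2 + 1L else we2 - end + 1L
    if (strand == "-") sq <- revcomp(sq)
    tibble(chrom = chrom, win_start = ws2, win_end = we2, strand = strand,
           mature_offset = as.integer(off), mature_len = as.integer(L),
           seq = sq)
  })
  bind_rows(rows) %>% distinct(.data$win_start, .data$win_end, .keep_all = TRUE)
}

# Hairpin criteria on a single folded window.
check_hairpin <- function(fold, mature_offset, mature_len, min_paired = 16,
                          energy_per_base = -0.95, max_bulge = 3) {
  span <- mature_offset:(mature_offset + mature_len - 1)
  pm <- fold$pair_map
  partners <- pm[span]
  paired <- which(!is.na(partners))
  reasons <- character(0)
  arm <- NA_character_
  if (length(paired) < min_paired) {
    reasons <- c(reasons, sprintf("only %d mature bases paired", length(paired)))
  }
  if (length(paired) > 0) {
    p <- partners[paired]
    if (all(p > max(span))) arm <- "5p"
    else if (all(p < min(span))) arm <- "3p"
    else reasons <- c(reasons, "mature in loop")
  } else {
    reasons <- c(reasons, "mature in loop")
  }
  width <- nchar(fold$seq)
  if (fold$energy / width > energy_per_base) {
    reasons <- c(reasons, sprintf("energy %.2f/base above %.2f",
                                  fold$energy / width, energy_per_base))
  }
  if (length(paired) >= 2) {
    inner <- span[min(paired):max(paired)]
    bulges <- sum(is.na(pm[inner]))
    if (bulges > max_bulge) {
      reasons <- c(reasons, sprintf("%d bulge bases in mature span", bulges))
    }
  }
  list(pass = length(reasons) == 0, arm = arm, reasons = reasons,
       n_paired = length(paired))
}

#' Evaluate hairpin candidacy of precursor windows
#'
#' Each window is folded and passes iff (a) at least `min_paired` mature bases
#' are paired, (b) every mature-base partner lies on one side of the mature
#' span (mature on one arm, not in the terminal loop), (c) energy per window
#' base is at most `energy_per_base` (the default -0.95 score units/base is
#' calibrated so planted-hairpin-like stems pass while the best windows of
#' random genomic background almost never do), and (d) at most `max_bulge` unpaired
#' bases interrupt the paired part of the mature span. The best candidate is
#' the lowest-energy passing window.
#'
#' @param windows Tibble from [extract_precursor_windows()].
#' @inheritParams check_hairpin
#' @return A `hairpin_candidate`: list with `windows` (per-window verdicts),
#'   `best` (row index of best passing window or NA), `pass`, `arm`,
#'   `fold` (fold of the best window).
#' @export
evaluate_hairpin <- function(windows, min_paired = 16,
                             energy_per_base = -0.95, max_bulge = 3) {
  if (nrow(windows) == 0) {
    return(structure(list(windows = windows, best = NA_integer_, pass = FALSE,
                          arm = NA_character_, fold = NULL),
                     class = "hairpin_candidate"))
  }
  folds <- purrr::map(windows$seq, fold_rna)
  checks <- purrr::map2(folds, seq_len(nrow(windows)), function(f, i) {
    check_hairpin(f, windows$mature_offset[i], windows$mature_len[i],
                  min_paired, energy_per_base, max_bulge)
  })
  res <- windows %>%
    mutate(energy = purrr::map_dbl(folds, "energy"),
           pass = purrr::map_lgl(checks, "pass"),
           arm = purrr::map_chr(checks, "arm"),
           n_paired = purrr::map_int(checks, ~ as.integer(.x$n_paired)),
           reasons = purrr::map_chr(checks, ~ paste(.x$reasons, collapse = "; ")))
  best <- NA_integer_
  if (any(res$pass)) {
    best <- which(res$pass)[which.min(res$energy[res$pass])]
  }
  structure(list(windows = res, best = best, pass = !is.na(best),
                 arm = if (!is.na(best)) res$arm[best] else NA_character_,
                 fold = if (!is.na(best)) folds[[best]] else NULL),
            class = "hairpin_candidate")
}

#' Validate a mature miRNA locus end to end
#'
#' Convenience wrapper: [extract_precursor_windows()] then
#' [evaluate_hairpin()].
#'
#' @inheritParams extract_precursor_windows
#' @inheritParams evaluate_hairpin
#' @export
validate_mirna_locus <- function(locus, genome, window = 200, stride = 20,
                                 margin = 10, min_paired = 16,
                                 energy_per_base = -0.95, max_bulge = 3) {
  w <- extract_precursor_windows(locus, genome, window, stride, margin)
  evaluate_hairpin(w, min_paired, energy_per_base, max_bulge)
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("<hairpin_candidate> ", nrow(x$windows), " window(s); ",
      if (x$pass) sprintf("PASS (arm %s, energy %g)", x$arm,
                          x$windows$energy[x$best]) else "FAIL", "\n", sep = "")
  invisible(x)
}

#' @rdname evaluate_hairpin
#' @param x A `hairpin_candidate`.
#' @param ... Unused.
#' @method tidy hairpin_candidate
#' @export
tidy.hairpin_candidate <- function(x, ...) {
  select(x$windows, -"seq")
}

#' @rdname evaluate_hairpin
#' @method glance hairpin_candidate
#' @export
glance.hairpin_candidate <- function(x, ...) {
  tibble(pass = x$pass, arm = x$arm,
         energy = if (x$pass) x$windows$energy[x$best] else NA_real_,
         n_windows = nrow(x$windows), n_passing = sum(x$windows$pass))
}

#' Pair 5p and 3p products of a validated hairpin
#'
#' Reports the dominant signature on each precursor arm, labels major/star by
#' read count, and tests the 2-nt 3' stagger of the duplex: the partner span
#' of each product should be offset by two bases at both ends relative to the
#' other product.
#'
#' @param hairpin A passing `hairpin_candidate`.
#' @param products Tibble of signatures within the best window: columns
#'   `seq`, `count`, `offset` (1-based 5' start within the oriented window).
#' @return List with `products` (per-arm dominant rows with `arm` and `role`
#'   major/star), `stagger` (logical; NA if an arm is absent) and `major_arm`.
#' @export
pair_5p_3p <- function(hairpin, products) {
  stopifnot(inherits(hairpin, "hairpin_candidate"), hairpin$pass)
  pm <- hairpin$fold$pair_map
  n <- length(pm)
  products <- products %>%
    mutate(start = .data$offset, end = .data$offset + nchar(.data$seq) - 1L) %>%
    filter(.data$start >= 1, .data$end <= n)
  arm_of <- function(s, e) {
    partners <- pm[s:e]
    partners <- partners[!is.na(partners)]
    if (length(partners) == 0) return(NA_character_)
    if (all(partners > e)) "5p" else if (all(partners < s)) "3p"
    else NA_character_
  }
  products <- products %>%
    mutate(arm = purrr::map2_chr(.data$start, .data$end, arm_of)) %>%
    filter(!is.na(.data$arm))
  if (nrow(products) == 0) {
    return(list(products = products, stagger = NA, major_arm = NA_character_))
  }
  dom <- products %>%
    group_by(.data$arm) %>%
    slice(which.max(.data$count)) %>%
    ungroup()
  major_arm <- dom$arm[which.max(dom$count)]
  dom <- mutate(dom, role = if_else(.data$arm == major_arm, "major", "star"))
  stagger <- NA
  if (all(c("5p", "3p") %in% dom$arm)) {
    five <- dom[dom$arm == "5p", ]
    three <- dom[dom$arm == "3p", ]
    a <- five$start; b <- five$end; c0 <- three$start; d0 <- three$end
    stagger <- isTRUE(!is.na(pm[a]) && pm[a] == d0 - 2L &&
                      b - 2L >= a && !is.na(pm[b - 2L]) && pm[b - 2L] == c0)
  }
  list(products = dom, stagger = stagger, major_arm = major_arm)
}

# Linkage used for grouping unannotated signatures into de novo families:
# a terminal shift of at most 2 bases and at most 1 substitution over the
# overlap (the kind of length/sequence micro-variation seen within a family).
family_linked <- function(a, b, max_shift = 2, max_subst = 1) {
  na <- nchar(a); nb <- nchar(b)
  if (abs(na - nb) > max_shift) return(FALSE)
  for (s in -max_shift:max_shift) {
    astart <- max(1, 1 + s); bstart <- max(1, 1 - s)
    ov <- min(na - astart + 1, nb - bstart + 1)
    if (ov < min(na, nb) - max_shift || ov < 10) next
    mm <- sum(charToRaw(substr(a, astart, astart + ov - 1)) !=
                charToRaw(substr(b, bstart, bstart + ov - 1)))
    if (mm <= max_subst) return(TRUE)
  }
  FALSE
}

#' Group miRNA signatures into families
#'
#' Annotated signatures share a family when their annotation shares the base
#' miRNA number (e.g. `gma-miR156b/f` and `gma-miR156c` are both family
#' `miR156`). Unannotated hairpin-validated signatures are grouped de novo by
#' single-linkage clustering at <= 1 substitution and <= 2-base terminal
#' shift. Within each family the most abundant sequence is flagged as the
#' putative authentic mature product.
#'
#' @param sigs Tibble with `seq`, `annotation` (NA allowed), `total_count`,
#'   and logical `hairpin_pass` (used to admit unannotated signatures).
#' @return Tibble: `family`, `seq`, `annotation`, `total_count`,
#'   `putative_mature`.
#' @export
group_families <- function(sigs) {
  sigs <- mutate(sigs, seq = normalize_seq(.data$seq)) %>%
    distinct(.data$seq, .keep_all = TRUE)
  annotated <- filter(sigs, !is.na(.data$annotation))
  fam <- stringr::str_match(annotated$annotation, "[mM][iI][rR]-?([0-9]+)")[, 2]
  annotated <- mutate(annotated, family = if_else(is.na(fam), .data$annotation,
                                                  paste0("miR", fam)))
  novel <- filter(sigs, is.na(.data$annotation), .data$hairpin_pass)
  if (nrow(novel) > 0) {
    n <- nrow(novel)
    edges <- integer(0)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (family_linked(novel$seq[i], novel$seq[j])) {
            edges <- c(edges, i, j)
          }
        }
      }
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comp <- igraph::components(g)$membership
    novel <- mutate(novel, family = sprintf("novel_%02d", comp))
  } else {
    novel <- mutate(novel, family = character(0))
  }
  bind_rows(annotated, novel) %>%
    group_by(.data$family) %>%
    mutate(putative_mature = .data$total_count == max(.data$total_count)) %>%
    ungroup() %>%
    arrange(.data$family, desc(.data$total_count)) %>%
    select("family", "seq", "annotation", "total_count", "putative_mature")
}
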