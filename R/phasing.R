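# Phased (trans-acting) siRNA detection: trigger-miRNA cleavage-site search
# on a candidate transcript, 21-nt register tallies of distinct downstream
# 5' ends, and an exact binomial phasing score.

#' Find trigger-miRNA cleavage sites on a transcript
#'
#' Scans every ungapped placement of the miRNA's reverse complement along the
#' transcript. Wobble (G:U) pairings count toward the match threshold at half
#' weight (rounded down). The predicted cleavage falls between miRNA
#' positions 10 and 11 from its 5' end; the reported `cleavage_pos` is the
#' transcript coordinate of the first base of the downstream (3') fragment,
#' so in-phase products start at `cleavage_pos + 21k`.
#'
#' @param transcript A single transcript sequence.
#' @param mirna The trigger miRNA sequence (15-30 nt).
#' @param min_matches Minimum effective matches (default 17).
#' @return Tibble: `site_start`, `site_end` (target-site coordinates),
#'   `matches` (exact complementary positions), `wobbles`, `mismatches`,
#'   `cleavage_pos`.
#' @export
find_trigger_sites <- function(transcript, mirna, min_matches = 17) {
  transcript <- normalize_seq(transcript)
  mirna <- normalize_seq(mirna)
  L <- nchar(mirna)
  stopifnot(nchar(transcript) >= L)
  rc <- revcomp(mirna)
  n <- nchar(transcript)
  rows <- list()
  tr_raw <- charToRaw(transcript)
  rc_raw <- charToRaw(rc)
  # wobble at target: expected C (miRNA G) observed T, or expected A
  # (miRNA U) observed G
  for (s in 1:(n - L + 1)) {
    win <- tr_raw[s:(s + L - 1)]
    eq <- win == rc_raw
    exact <- sum(eq)
    wob <- sum(!eq & ((rc_raw == charToRaw("C") & win == charToRaw("T")) |
                        (rc_raw == charToRaw("A") & win == charToRaw("G"))))
    eff <- exact + wob %/% 2
    if (eff >= min_matches) {
      rows[[length(rows) + 1]] <- tibble(
        site_start = s, site_end = s + L - 1L,
        matches = as.integer(exact), wobbles = as.integer(wob),
        mismatches = as.integer(L - exact),
        cleavage_pos = s + L - 10L)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(site_start = integer(0), site_end = integer(0),
                  matches = integer(0), wobbles = integer(0),
                  mismatches = integer(0), cleavage_pos = integer(0))
  }
  out
}

#' Score 21-nt phasing downstream of a cleavage site
#'
#' Distinct aligned 5'-end positions at or downstream of the cleavage site
#' are assigned to registers modulo the period; for antisense alignments the
#' 5' end is the alignment end and a +2 offset accounts for the 2-nt 3'
#' overhang of the processing duplex. The score is k/n where k is the modal
#' register count over n distinct positions; the p-value is the exact
#' binomial tail P[Bin(n, 1/period) >= k], Bonferroni-corrected by the
#' period and capped at 1.
#'
#' @param alignments Tibble with transcript-coordinate columns `start`, `end`
#'   and `strand` (`+` = sense).
#' @param cleavage_pos Cleavage coordinate (first base of the downstream
#'   fragment), e.g. from [find_trigger_sites()].
#' @param period Phasing period (default 21).
#' @return A `phasing_result`: list with `register_counts`, `n`, `k`,
#'   `score`, `p_value`, `insufficient`.
#' @export
phase_register <- function(alignments, cleavage_pos, period = 21) {
  pos5 <- if_else(alignments$strand == "+", alignments$start,
                  alignments$end)
  reg_raw <- if_else(alignments$strand == "+",
                     (pos5 - cleavage_pos) %% period,
                     (pos5 - cleavage_pos + 2L) %% period)
  keep <- pos5 >= cleavage_pos
  df <- distinct(tibble(pos5 = pos5[keep], strand = alignments$strand[keep],
                        register = reg_raw[keep]))
  n <- nrow(df)
  counts <- tabulate(df$register + 1L, nbins = period)
  if (n < 3) {
    return(structure(list(register_counts = counts, n = n, k = NA_integer_,
                          score = NA_real_, p_value = NA_real_,
                          insufficient = TRUE, period = period),
                     class = "phasing_result"))
  }
  k <- max(counts)
  p <- min(1, period * pbinom(k - 1, n, 1 / period, lower.tail = FALSE))
  structure(list(register_counts = counts, n = n, k = as.integer(k),
                 score = k / n, p_value = p, insufficient = FALSE,
                 period = period),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  if (x$insufficient) {
    cat("<phasing_result> insufficient positions (n =", x$n, ")\n")
  } else {
    cat(sprintf("<phasing_result> n = %d, modal register k = %d, score %.3f, p = %.3g\n",
                x$n, x$k, x$score, x$p_value))
  }
  invisible(x)
}

#' @rdname phase_register
#' @param x A `phasing_result`.
#' @param ... Unused.
#' @method tidy phasing_result
#' @export
tidy.phasing_result <- function(x, ...) {
  tibble(register = seq_len(x$period) - 1L, n_positions = x$register_counts)
}

#' @rdname phase_register
#' @method glance phasing_result
#' @export
glance.phasing_result <- function(x, ...) {
  tibble(n = x$n, k = x$k, score = x$score, p_value = x$p_value,
         insufficient = x$insufficient)
}

#' Enumerate phased products downstream of a cleavage site
#'
#' Lists each phase window (D1, D2, ...) of `period` bases downstream of the
#' cleavage position, the signatures whose 5' ends open the window, and flags
#' the most abundant product. Windows truncated by the transcript end are
#' excluded.
#'
#' @param transcript Transcript sequence.
#' @param cleavage_pos Cleavage coordinate (first downstream base).
#' @param signatures Tibble with transcript alignments of signatures:
#'   `seq`, `start`, `end`, `strand`, and count/cpm columns.
#' @param period Phase period (default 21).
#' @return Tibble: `phase` ("D1", ...), `win_start`, `win_end`, `window_seq`,
#'   plus the matching signature rows' columns, and `most_abundant`.
#' @export
enumerate_phased_products <- function(transcript, cleavage_pos, signatures,
                                      period = 21) {
  transcript <- normalize_seq(transcript)
  n <- nchar(transcript)
  count_col <- intersect(c("count", "total_count"), names(signatures))[1]
  starts <- seq(cleavage_pos, n, by = period)
  starts <- starts[starts + period - 1 <= n]
  rows <- purrr::imap(starts, function(ws, i) {
    we <- ws + period - 1L
    # an in-register antisense partner of window i has its 5' end (the
    # alignment end) at ws + period - 2 by the 2-nt overhang geometry
    hit <- filter(signatures,
                  if_else(.data$strand == "+", .data$start,
                          .data$end - period + 2L) == ws)
    if (nrow(hit) == 0) return(NULL)
    dplyr::bind_cols(
      tibble(phase = sprintf("D%d", i), win_start = as.integer(ws),
             win_end = as.integer(we),
             window_seq = substr(transcript, ws, we))[rep(1, nrow(hit)), ],
      hit)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  if (!is.na(count_col)) {
    out <- mutate(out, most_abundant =
                    .data[[count_col]] == max(.data[[count_col]]))
  }
  out
}

#' Scan candidate regions for phased siRNA loci
#'
#' For each region, tests every supplied miRNA for a trigger site on either
#' genomic strand of the region and scores downstream phasing from the
#' region's alignments.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (e.g. siRNA clusters).
#' @param genome Genome in any form accepted by [index_genome()].
#' @param mirnas Named character vector (or tibble `name`,`seq`) of candidate
#'   trigger miRNAs.
#' @param alignments Recorded genome alignments tibble.
#' @param min_matches Trigger threshold (default 17).
#' @param period Phase period (default 21).
#' @return Tibble: region columns, `trigger`, `site_start`, `site_end`,
#'   `matches`, `cleavage_pos` (genomic), `n`, `k`, `score`, `p_value`;
#'   one row per detected trigger site, sorted by p-value.
#' @export
detect_phased_loci <- function(regions, genome, mirnas, alignments,
                               min_matches = 17, period = 21) {
  idx <- if (inherits(genome, "genome_index")) genome else index_genome(genome)
  if (is.data.frame(mirnas)) mirnas <- setNames(mirnas$seq, mirnas$name)
  rows <- list()
  for (ri in seq_len(nrow(regions))) {
    chrom <- regions$chrom[ri]
    rs <- regions$start[ri]; re <- regions$end[ri]
    tx <- as.character(Biostrings::subseq(idx$dna[[chrom]], rs, re))
    aln <- alignments %>%
      filter(.data$chrom == regions$chrom[ri], .data$start >= rs,
             .data$end <= re) %>%
      mutate(tstart = .data$start - rs + 1L, tend = .data$end - rs + 1L)
    for (ori in c("+", "-")) {
      txo <- if (ori == "+") tx else revcomp(tx)
      alo <- if (ori == "+") {
        tibble(start = aln$tstart, end = aln$tend, strand = aln$strand)
      } else {
        w <- nchar(tx)
        tibble(start = w - aln$tend + 1L, end = w - aln$tstart + 1L,
               strand = if_else(aln$strand == "+", "-", "+"))
      }
      for (mi in seq_along(mirnas)) {
        sites <- find_trigger_sites(txo, mirnas[[mi]], min_matches)
        for (si in seq_len(nrow(sites))) {
          ph <- phase_register(alo, sites$cleavage_pos[si], period)
          if (ph$insufficient) next
          cp <- sites$cleavage_pos[si]
          rows[[length(rows) + 1]] <- tibble(
            chrom = chrom, start = rs, end = re, tx_strand = ori,
            trigger = names(mirnas)[mi],
            site_start = sites$site_start[si], site_end = sites$site_end[si],
            matches = sites$matches[si],
            cleavage_pos = if (ori == "+") rs + cp - 1L
                           else re - cp + 1L,
            n = ph$n, k = ph$k, score = ph$score, p_value = ph$p_value)
        }
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  tx_strand = character(0), trigger = character(0),
                  site_start = integer(0), site_end = integer(0),
                  matches = integer(0), cleavage_pos = integer(0),
                  n = integer(0), k = integer(0), score = numeric(0),
                  p_value = numeric(0)))
  }
  arrange(out, .data$p_value)
}
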