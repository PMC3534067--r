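fake_alignments <- function(starts, strand = "+", chrom = "Chr01",
                            len = 21L, counts = 1L) {
  tibble::tibble(
    signature_id = sprintf("s%03d", seq_along(starts)),
    seq = sprintf("SEQ%03d", seq_along(starts)),
    chrom = chrom, start = as.integer(starts),
    end = as.integer(starts) + len - 1L,
    strand = strand, mismatches = 0L,
    count = rep(counts, length.out = length(starts)))
}

test_that("clustering merges within the gap and splits beyond it", {
  one <- cluster_alignments(fake_alignments(1000))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_signatures, 1)

  # gap of exactly 200 merges; 201 splits
  merged <- cluster_alignments(fake_alignments(c(1000, 1221)))   # gap 200
  expect_equal(nrow(merged), 1)
  split <- cluster_alignments(fake_alignments(c(1000, 1222)))    # gap 201
  expect_equal(nrow(split), 2)
})

test_that("cluster statistics ignore input order", {
  withr::local_seed(6)
  aln <- fake_alignments(sample(seq(2000, 3000, by = 40)),
                         strand = sample(c("+", "-"), 26, TRUE))
  a <- cluster_alignments(aln)
  b <- cluster_alignments(aln[sample(nrow(aln)), ])
  cols <- c("chrom", "start", "end", "n_signatures", "footprint",
            "plus_count", "minus_count")
  expect_equal(as.data.frame(a[cols]), as.data.frame(b[cols]))
})

test_that("classification separates broad two-strand clusters from point loci", {
  # 115 distinct signatures over ~1.5 kb, both strands -> siRNA
  withr::local_seed(7)
  starts <- sample(10000:11400, 115)
  broad <- cluster_alignments(fake_alignments(
    starts, strand = sample(c("+", "-"), 115, TRUE)))
  expect_equal(nrow(broad), 1)
  expect_gt(broad$plus_count, 0)
  expect_gt(broad$minus_count, 0)
  cl <- classify_clusters(broad)
  expect_equal(cl$class_label, "siRNA")

  # dominant single signature + overlapping hairpin -> miRNA-like
  point <- cluster_alignments(dplyr::mutate(fake_alignments(5000),
                                            count = 1000L))
  hp <- tibble::tibble(chrom = "Chr01", start = 4900L, end = 5100L)
  expect_equal(classify_clusters(point, hp)$class_label, "miRNA-like")
  # same cluster without a hairpin stays ambiguous
  expect_equal(classify_clusters(point)$class_label, "ambiguous")

  # 3 signatures over 60 bases, no hairpin -> ambiguous
  amb <- cluster_alignments(fake_alignments(c(7000, 7020, 7040)))
  expect_equal(classify_clusters(amb)$class_label, "ambiguous")
})

make_gene_gff <- function() {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Chr01\tx\tgene\t1001\t2100\t.\t+\t.\tID=geneA",
    "Chr01\tx\tmRNA\t1001\t2100\t.\t+\t.\tID=geneA.1;Parent=geneA",
    "Chr01\tx\texon\t1001\t1400\t.\t+\t.\tID=eA1;Parent=geneA.1",
    "Chr01\tx\texon\t1801\t2100\t.\t+\t.\tID=eA2;Parent=geneA.1",
    "Chr01\tx\tgene\t9001\t9600\t.\t+\t.\tID=geneB",
    "Chr01\tx\tmRNA\t9001\t9600\t.\t+\t.\tID=geneB.1;Parent=geneB",
    "Chr01\tx\texon\t9001\t9600\t.\t+\t.\tID=eB1;Parent=geneB.1"), gff)
  gff
}

test_that("the exon-only test flags spliced-mRNA-derived clusters", {
  gff <- make_gene_gff()
  gm <- parse_gff3(gff)
  # exonic-only cluster
  ex <- cluster_alignments(fake_alignments(c(1010, 1100, 1200, 1340, 1810,
                                             1900, 2000, 2050)))
  out <- exon_only_test(ex, gm)
  expect_equal(out$exon_fraction, 1.0)
  expect_true(out$spliced_flag)

  # cluster covering the intron: fraction well below 1, flag FALSE
  mid <- cluster_alignments(fake_alignments(seq(1010, 2050, by = 40)))
  out2 <- exon_only_test(mid, gm)
  expect_lt(out2$exon_fraction, 0.9)
  expect_false(out2$spliced_flag)

  # intronless gene: not testable
  b <- cluster_alignments(fake_alignments(c(9100, 9200, 9300)))
  out3 <- exon_only_test(b, gm)
  expect_true(is.na(out3$spliced_flag))
  expect_equal(out3$exon_fraction, 1.0)
  unlink(gff)
})

test_that("exon fraction cannot decrease when an intronic alignment is removed", {
  gff <- make_gene_gff()
  gm <- parse_gff3(gff)
  aln <- fake_alignments(c(1010, 1100, 1500, 1600, 1900))  # 2 intronic
  with_intronic <- exon_only_test(cluster_alignments(aln), gm)
  without <- exon_only_test(cluster_alignments(aln[-3, ]), gm)
  expect_gte(without$exon_fraction, with_intronic$exon_fraction)
  unlink(gff)
})

test_that("inverted repeats are found at the planted geometry", {
  withr::local_seed(19)
  arm <- paste(sample(c("A", "C", "G", "T"), 621, TRUE), collapse = "")
  spacer <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  left <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g <- c(Chr01 = paste0(left, arm, spacer, revcomp(arm), right))
  region <- list(chrom = "Chr01", start = 3500L, end = 4000L)
  ir <- find_inverted_repeats(region, g, flank = 4000)
  expect_gte(nrow(ir), 1)
  expect_equal(ir$arm_len[1], 621L)
  expect_equal(ir$spacer[1], 1000L)
  expect_gte(ir$identity[1], 0.99)
  expect_equal(ir$arm1_start[1], 3001L)

  # signature linking: a product of either arm is attributed to the repeat
  sig <- substr(arm, 100, 121)
  ir2 <- find_inverted_repeats(region, g, flank = 4000,
                               signatures = c(sig, strrep("A", 21)))
  expect_true(sig %in% ir2$matched_signatures[[1]])

  # a self-complement-free region yields nothing
  none <- find_inverted_repeats(list(chrom = "Chr01", start = 100L,
                                     end = 600L), g, flank = 1000)
  expect_equal(nrow(none), 0)
})

test_that("arms below the identity floor are rejected", {
  withr::local_seed(20)
  arm <- paste(sample(c("A", "C", "G", "T"), 621, TRUE), collapse = "")
  arm2 <- strsplit(revcomp(arm), "")[[1]]
  pos <- sample(621, 68)                   # ~11% divergence
  arm2[pos] <- vapply(arm2[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  g <- c(Chr01 = paste0(
    paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = ""),
    arm,
    paste(sample(c("A", "C", "G", "T"), 800, TRUE), collapse = ""),
    paste(arm2, collapse = ""),
    paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")))
  ir <- find_inverted_repeats(list(chrom = "Chr01", start = 2500L,
                                   end = 3000L), g, flank = 3000)
  expect_true(nrow(ir) == 0 || all(ir$arm_len < 300))
})
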