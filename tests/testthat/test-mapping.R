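make_genome <- function(len = 1000, seed = 5) {
  withr::with_seed(seed, {
    c(Chr01 = paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
  })
}

test_that("the index supports exact lookup on both strands", {
  g <- make_genome()
  idx <- index_genome(g)
  q <- substr(g[[1]], 101, 121)
  hits <- align_signatures(q, idx, max_mm = 0)
  plus <- dplyr::filter(hits, strand == "+")
  expect_true(any(plus$start == 101 & plus$end == 121))

  rc_hits <- align_signatures(revcomp(q), idx, max_mm = 0)
  minus <- dplyr::filter(rc_hits, strand == "-")
  expect_true(any(minus$start == 101 & minus$end == 121))

  expect_error(index_genome(character(0)), "empty")
})

test_that("alignment agrees with an independent brute-force scan", {
  g <- make_genome(5000, seed = 9)
  idx <- index_genome(g)
  withr::local_seed(11)
  for (i in 1:10) {
    q <- if (i <= 5) {
      s <- sample(1000:4000, 1)
      substr(g[[1]], s, s + 20)           # planted: guaranteed hits
    } else {
      paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    }
    for (mm in c(0, 2)) {
      got <- align_signatures(q, idx, max_mm = mm) |>
        dplyr::select(chrom, start, end, strand, mismatches) |>
        dplyr::arrange(chrom, start, strand)
      want <- srnapipe:::brute_force_scan(q, g, max_mm = mm) |>
        dplyr::select(chrom, start, end, strand, mismatches) |>
        dplyr::arrange(chrom, start, strand)
      expect_equal(as.data.frame(got), as.data.frame(want), info = q)
    }
  }
})

test_that("aligning the reverse complement swaps strands only", {
  g <- make_genome(3000, seed = 13)
  idx <- index_genome(g)
  q <- substr(g[[1]], 500, 521)
  a <- align_signatures(q, idx, max_mm = 2)
  b <- align_signatures(revcomp(q), idx, max_mm = 2)
  swap <- dplyr::mutate(b, strand = ifelse(strand == "+", "-", "+"))
  cols <- c("chrom", "start", "end", "strand", "mismatches")
  expect_equal(as.data.frame(dplyr::arrange(a[cols], start, strand)),
               as.data.frame(dplyr::arrange(swap[cols], start, strand)))
})

test_that("multi-mapping policy records below the cap, counts always", {
  fake_aln <- function(n) tibble::tibble(
    signature_id = "s1", seq = strrep("A", 21), chrom = "Chr01",
    start = seq_len(n) * 100L, end = seq_len(n) * 100L + 20L,
    strand = "+", mismatches = 0L)
  p1 <- apply_multimap_policy(fake_aln(1))
  expect_equal(p1$counts$location_count, 1L)
  expect_equal(nrow(p1$recorded), 1)
  p9 <- apply_multimap_policy(fake_aln(9))
  expect_equal(nrow(p9$recorded), 9)
  p10 <- apply_multimap_policy(fake_aln(10))
  expect_equal(p10$counts$location_count, 10L)
  expect_equal(nrow(p10$recorded), 0)
  p103 <- apply_multimap_policy(fake_aln(103))
  expect_equal(p103$counts$location_count, 103L)
  expect_equal(nrow(p103$recorded), 0)
})

test_that("reference annotation follows the 18-base exact / 1-mm rule", {
  ref <- tibble::tibble(
    name = c("syn-miR167e", "syn-miR167z"),
    seq = c("TGAAGCTGCCAGCATGATCTT", "TGAAGCTGCCAGCATGATCTA"))
  # identity
  out <- annotate_signatures("TGAAGCTGCCAGCATGATCTT", ref)
  expect_equal(out$annotation, "syn-miR167e")
  expect_equal(out$ann_mismatches, 0L)
  # 21-mer, one substitution: allowed (overlap > 18)
  q1 <- "TGAAGCTGCCAGCATGATGTT"
  expect_equal(annotate_signatures(q1, ref)$annotation, "syn-miR167e")
  # 18-mer with one substitution: exact required at <= 18 -> none
  q2 <- sub("^T", "A", substr("TGAAGCTGCCAGCATGATCTT", 1, 18))
  expect_true(is.na(annotate_signatures(q2, ref)$annotation))
  # 18-mer exact substring: annotated
  q3 <- substr("TGAAGCTGCCAGCATGATCTT", 1, 18)
  expect_equal(annotate_signatures(q3, ref)$annotation, "syn-miR167e")
  # ties break lexicographically on name
  both <- "TGAAGCTGCCAGCATGATCTG"  # 1 mm from both references
  expect_equal(annotate_signatures(both, ref)$annotation, "syn-miR167e")
})

test_that("gene model joining reports overlap features, skipping bad lines", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Chr01\tx\tgene\t1001\t2000\t.\t+\t.\tID=geneA",
    "Chr01\tx\tmRNA\t1001\t2000\t.\t+\t.\tID=geneA.1;Parent=geneA",
    "Chr01\tx\texon\t1001\t1300\t.\t+\t.\tID=e1;Parent=geneA.1",
    "Chr01\tx\texon\t1601\t2000\t.\t+\t.\tID=e2;Parent=geneA.1",
    "this line is malformed"), gff)
  expect_warning(gm <- parse_gff3(gff), "malformed")
  loci <- tibble::tibble(
    signature_id = c("in_exon", "intergenic", "straddle"),
    chrom = "Chr01",
    start = c(1100L, 5000L, 1290L),
    end = c(1120L, 5020L, 1310L),
    strand = "+")
  out <- join_gene_models(loci, gm)
  expect_equal(out$gene_id[out$signature_id == "in_exon"], "geneA")
  expect_equal(out$features[out$signature_id == "in_exon"], "exon")
  expect_false("intergenic" %in% out$signature_id)
  expect_equal(out$features[out$signature_id == "straddle"], "exon;intron")
  unlink(gff)
})
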