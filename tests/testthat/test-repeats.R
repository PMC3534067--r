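fixture_te_db <- function(seed = 12) {
  withr::with_seed(seed, {
    tibble::tibble(
      name = c("gypsy_1", "copia_1"),
      family = c("Gypsy", "Copia"),
      seq = c(paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
              paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")))
  })
}

test_that("TE matching applies the 95% identity rule over the signature", {
  db <- fixture_te_db()
  q24 <- substr(db$seq[1], 101, 124)
  hit <- match_te_db(q24, db)
  expect_equal(hit$family, "Gypsy")
  expect_equal(hit$identity, 1.0)

  # one mismatch in 21 bases: 20/21 = 0.952 >= 0.95 -> hit
  q21 <- substr(db$seq[2], 201, 221)
  substr(q21, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(q21, 5, 5))[1]
  h21 <- match_te_db(q21, db)
  expect_equal(h21$family, "Copia")
  expect_equal(h21$mismatches, 1L)

  # two mismatches in 24 bases: 22/24 = 0.917 < 0.95 -> none
  q24b <- substr(db$seq[1], 301, 324)
  substr(q24b, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(q24b, 3, 3))[1]
  substr(q24b, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(q24b, 20, 20))[1]
  expect_true(is.na(match_te_db(q24b, db)$family))

  # strand symmetry
  expect_equal(match_te_db(revcomp(q24), db)$family, "Gypsy")

  # an exact tie across two families is ambiguous
  shared <- substr(db$seq[1], 1, 22)
  db2 <- dplyr::bind_rows(db, tibble::tibble(
    name = "copia_2", family = "Copia",
    seq = paste0(shared, substr(db$seq[2], 1, 100))))
  expect_equal(match_te_db(shared, db2)$family, "ambiguous")
})

test_that("TE FASTA headers yield families from tokens or pipe fields", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">te1 family=Gypsy", strrep("ACGT", 30),
               ">te2|Mutator|x", strrep("TGCA", 30),
               ">te3", strrep("AACC", 30)), fa)
  db <- read_te_fasta(fa)
  expect_equal(db$family, c("Gypsy", "Mutator", "unknown"))
  unlink(fa)
})

test_that("family profiles count uniques vs reads with exclusions", {
  assignments <- tibble::tibble(
    seq = c(strrep("A", 22), strrep("C", 22), strrep("G", 24),
            strrep("T", 24), strrep("AG", 12)),
    family = c("Gypsy", "Gypsy", "Copia", "Copia", NA))
  signatures <- tibble::tibble(
    seq = assignments$seq,
    total_count = c(100, 50, 5, 7, 3))
  prof <- family_size_profiles(assignments, signatures)
  g22 <- dplyr::filter(prof, family == "Gypsy", length == 22)
  expect_equal(g22$n_unique, 2L)
  expect_equal(g22$n_reads, 150)
  # pigeonhole: reads >= uniques wherever uniques > 0
  expect_true(all(prof$n_reads >= prof$n_unique))
  # aggregate equals the sum of family profiles when nothing is excluded
  all22 <- dplyr::filter(prof, family == "all", length == 22)
  expect_equal(all22$n_reads, 150)
  # exclusion removes from the aggregate only
  prof2 <- family_size_profiles(assignments, signatures,
                                exclude = strrep("A", 22))
  expect_equal(dplyr::filter(prof2, family == "all",
                             length == 22)$n_reads, 50)
  expect_equal(dplyr::filter(prof2, family == "Gypsy",
                             length == 22)$n_reads, 150)
})

test_that("region profiles partition by library and handle empty regions", {
  signatures <- tibble::tibble(
    signature_id = c("s1", "s2", "s3"),
    seq = c(strrep("A", 21), strrep("C", 22), strrep("G", 21)),
    length = c(21L, 22L, 21L),
    n_A = c(5L, 3L, 0L), n_B = c(2L, 0L, 8L))
  aln <- tibble::tibble(
    signature_id = c("s1", "s2", "s3"),
    chrom = "Chr01", start = c(100L, 150L, 9000L),
    end = c(120L, 171L, 9020L), strand = "+")
  prof <- region_size_profile(list(chrom = "Chr01", start = 1L, end = 500L),
                              aln, signatures)
  expect_equal(sum(prof$overall$n_signatures), 2)
  # per-library tallies never exceed the overall per length
  per <- dplyr::group_by(prof$per_library, length) |>
    dplyr::summarise(m = max(n_signatures))
  ov <- dplyr::filter(prof$overall, n_signatures > 0)
  expect_true(all(per$m <= ov$n_signatures[match(per$length, ov$length)]))
  # library A has both region signatures present, B has one of two present
  fa <- prof$library_fraction
  expect_equal(fa$fraction[fa$library == "A"], 1.0)
  expect_equal(fa$fraction[fa$library == "B"], 0.5)

  empty <- region_size_profile(list(chrom = "Chr01", start = 5e4,
                                    end = 6e4), aln, signatures)
  expect_equal(sum(empty$overall$n_signatures), 0)
})

test_that("multi-map banding partitions the genome-matched signatures", {
  lc <- tibble::tibble(signature_id = sprintf("s%d", 1:6),
                       location_count = c(1L, 1L, 5L, 12L, 103L, 200L))
  bands <- multimap_statistics(lc)
  expect_equal(bands$n, c(2L, 1L, 2L, 1L))
  expect_equal(sum(bands$n), 6L)
  expect_equal(sum(bands$pct), 100)
  all_unique <- multimap_statistics(
    tibble::tibble(signature_id = "x", location_count = 1L))
  expect_equal(all_unique$pct[1], 100)
})
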