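fixture_hairpin <- function(mature = "TGAAGCTGCCAGCATGATCTT", arm = "5p",
                            seed = 3) {
  withr::with_seed(seed, {
    srnapipe:::build_hairpin(mature, arm, srnapipe:::DEFAULT_ADAPTER,
                             new.env(parent = emptyenv()))
  })
}

test_that("precursor windows contain the mature and clip at edges", {
  g <- withr::with_seed(2, c(Chr01 = paste(
    sample(c("A", "C", "G", "T"), 100000, TRUE), collapse = "")))
  idx <- index_genome(g)
  w <- extract_precursor_windows(
    list(chrom = "Chr01", start = 5000L, end = 5020L, strand = "+"), idx)
  expect_true(all(w$win_start <= 5000 & w$win_end >= 5020))
  expect_true(all(nchar(w$seq) == 200))
  expect_equal(substr(w$seq[1], w$mature_offset[1], w$mature_offset[1] + 20),
               substr(g[[1]], 5000, 5020))

  # locus close to the chromosome start: windows clipped but still contain it
  w2 <- extract_precursor_windows(
    list(chrom = "Chr01", start = 5L, end = 25L, strand = "-"), idx)
  expect_true(nrow(w2) >= 1)
  expect_true(all(w2$win_start >= 1))
})

test_that("constructed stem-loops pass; matures in the loop fail", {
  hp <- fixture_hairpin()
  prec <- hp$precursor
  w <- tibble::tibble(chrom = "x", win_start = 1L, win_end = nchar(prec),
                      strand = "+", mature_offset = hp$mature_start,
                      mature_len = 21L, seq = prec)
  res <- evaluate_hairpin(w)
  expect_true(res$pass)
  expect_equal(res$arm, "5p")
  expect_gte(glance(res)$n_passing, 1)
  td <- tidy(res)
  expect_gte(td$n_paired[1], 16)

  # a 3p-arm mature is recognized on the other side
  hp3 <- fixture_hairpin(arm = "3p", seed = 8)
  w3 <- tibble::tibble(chrom = "x", win_start = 1L,
                       win_end = nchar(hp3$precursor), strand = "+",
                       mature_offset = hp3$mature_start, mature_len = 21L,
                       seq = hp3$precursor)
  res3 <- evaluate_hairpin(w3)
  expect_true(res3$pass)
  expect_equal(res3$arm, "3p")

  # mature placed across the terminal loop: partners on both sides
  mid <- (nchar(prec) - 21) %/% 2
  wloop <- dplyr::mutate(w, mature_offset = mid)
  resloop <- evaluate_hairpin(wloop)
  expect_false(resloop$pass)
  expect_match(paste(tidy(resloop)$reasons, collapse = " "), "loop")
})

test_that("hairpin pass implies all mature partners on one arm", {
  withr::local_seed(41)
  for (i in 1:5) {
    hp <- fixture_hairpin(seed = 100 + i)
    w <- tibble::tibble(chrom = "x", win_start = 1L,
                        win_end = nchar(hp$precursor), strand = "+",
                        mature_offset = hp$mature_start, mature_len = 21L,
                        seq = hp$precursor)
    res <- evaluate_hairpin(w)
    if (!res$pass) next
    pm <- res$fold$pair_map
    span <- hp$mature_start:(hp$mature_start + 20)
    partners <- pm[span][!is.na(pm[span])]
    expect_true(all(partners > max(span)) || all(partners < min(span)))
  }
})

test_that("5p/3p pairing reports the 2-nt stagger and major/star roles", {
  hp <- fixture_hairpin()
  prec <- hp$precursor
  w <- tibble::tibble(chrom = "x", win_start = 1L, win_end = nchar(prec),
                      strand = "+", mature_offset = hp$mature_start,
                      mature_len = 21L, seq = prec)
  res <- evaluate_hairpin(w)
  products <- tibble::tibble(
    seq = c(substr(prec, hp$mature_start, hp$mature_end), hp$star),
    count = c(29735, 252),
    offset = c(hp$mature_start, hp$star_start))
  duplex <- pair_5p_3p(res, products)
  expect_equal(duplex$major_arm, "5p")
  expect_true(duplex$stagger)
  expect_setequal(duplex$products$role, c("major", "star"))
  # star-side dominance flips the major arm
  duplex2 <- pair_5p_3p(res, dplyr::mutate(products, count = rev(count)))
  expect_equal(duplex2$major_arm, "3p")

  # only one arm observed: no stagger call, single product
  solo <- pair_5p_3p(res, products[1, ])
  expect_true(is.na(solo$stagger))
  expect_equal(nrow(solo$products), 1)
})

test_that("family grouping merges annotation variants and clusters novels", {
  sigs <- tibble::tibble(
    seq = c("TTGACAGAAGATAGAGAGCAC",   # miR156-annotated, 1-nt apart
            "TTGACAGAAGAGAGAGAGCAC",
            "AAACCCGGGTTTAAACCCGGG",   # novel pair, 1 substitution apart
            "AAACCCGGGTTTAAACCCGGC",
            "GGGTTTAAACCCGGGAAATTT"),  # novel, far from everything
    annotation = c("gma-miR156c/d/e/g", "gma-miR156b/f", NA, NA, NA),
    total_count = c(25, 98674, 50, 10, 7),
    hairpin_pass = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  fam <- group_families(sigs)
  m156 <- dplyr::filter(fam, family == "miR156")
  expect_equal(nrow(m156), 2)
  expect_equal(m156$seq[m156$putative_mature], "TTGACAGAAGAGAGAGAGCAC")
  novel <- dplyr::filter(fam, grepl("^novel", family))
  expect_equal(dplyr::n_distinct(novel$family), 2)
  linked <- dplyr::filter(novel, seq %in% c("AAACCCGGGTTTAAACCCGGG",
                                            "AAACCCGGGTTTAAACCCGGC"))
  expect_equal(dplyr::n_distinct(linked$family), 1)

  # identical sequences collapse to one member
  dup <- group_families(dplyr::bind_rows(sigs, sigs[2, ]))
  expect_equal(sum(dup$seq == "TTGACAGAAGAGAGAGAGCAC"), 1)
})
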