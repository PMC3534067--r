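small_config <- function(seed = 5, ...) {
  defaults <- list(
    genome_length = 40000, n_mirna = 3, n_star_expressed = 1,
    n_sirna_sources = 1,
    te_families = tibble::tibble(family = c("Gypsy", "Copia"),
                                 copies = c(3L, 2L),
                                 divergence = c(0, 0.01)),
    n_background_genes = 2,
    libraries = default_libraries(depth = 3000),
    seed = seed)
  extra <- list(...)
  defaults[names(extra)] <- extra
  do.call(sim_config, defaults)
}

test_that("configuration constraints are enforced", {
  bad <- default_libraries()
  bad$w21[1] <- bad$w21[1] + 0.1
  expect_error(sim_config(libraries = bad), "sum to 1")
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  libs0 <- default_libraries(depth = 0)
  expect_error(sim_config(libraries = libs0), "depth")
  expect_error(generate_genome(small_config(genome_length = 5000)),
               "too small")
})

test_that("every planted payload occurs verbatim at its stated locus", {
  sim <- generate_genome(small_config())
  g <- sim$genome[["Chr01"]]
  p <- sim$products
  got <- substring(g, p$start, p$end)
  got[p$strand == "-"] <- revcomp(got[p$strand == "-"])
  expect_equal(got, p$seq)
  # features are non-overlapping
  f <- dplyr::arrange(sim$features, start)
  expect_true(all(f$start[-1] > f$end[-nrow(f)]))
  # matures and stars sit verbatim on the hairpin
  tm <- mirna_truth(sim)
  for (i in seq_len(nrow(tm))) {
    prec <- substring(g, tm$f_start[i], tm$f_end[i])
    expect_true(grepl(tm$mature[i], prec, fixed = TRUE))
  }
})

test_that("TAS phased products start at multiples of 21 from the cleavage", {
  sim <- generate_genome(small_config())
  tas <- dplyr::filter(sim$features, kind == "tas_locus")
  expect_equal(nrow(tas), 1)
  pay <- tas$payload[[1]]
  cp_genomic <- tas$start + pay$cleavage_offset - 1L
  prods <- dplyr::filter(sim$products, feature_id == "tas01",
                         grepl("^D", role))
  expect_equal(sort((prods$start - cp_genomic) %% 21), rep(0, nrow(prods)))
  # trigger complements the planted site with >= 17 effective matches
  tx <- substring(sim$genome[["Chr01"]], tas$start, tas$end)
  sites <- find_trigger_sites(tx, pay$trigger)
  expect_true(pay$site_start %in% sites$site_start)
  expect_equal(sites$matches[sites$site_start == pay$site_start], 18L)
})

test_that("a supplied mature lands on a folding arm", {
  mir167 <- "TGAAGCTGCCAGCATGATCTT"
  cfg <- sim_config(genome_length = 30000, n_mirna = 1,
                    n_star_expressed = 0, n_sirna_sources = 0,
                    te_families = tibble::tibble(family = character(0),
                                                 copies = integer(0),
                                                 divergence = numeric(0)),
                    n_background_genes = 1, include_tas = FALSE,
                    include_rdna = FALSE,
                    libraries = default_libraries(depth = 1000),
                    mirna_matures = mir167, seed = 9)
  sim <- generate_genome(cfg)
  hp <- dplyr::filter(sim$features, kind == "mirna_hairpin")
  prec <- substring(sim$genome[["Chr01"]], hp$start, hp$end)
  at <- regexpr(mir167, prec, fixed = TRUE)
  expect_gte(at, 1)
  fold <- fold_rna(prec)
  span <- at:(at + 20)
  expect_gte(sum(!is.na(fold$pair_map[span])), 16)
})

test_that("an empty feature request produces only background genes", {
  cfg <- sim_config(genome_length = 20000, n_mirna = 0,
                    n_sirna_sources = 0,
                    te_families = tibble::tibble(family = character(0),
                                                 copies = integer(0),
                                                 divergence = numeric(0)),
                    n_background_genes = 2, include_tas = TRUE,
                    include_rdna = FALSE,
                    libraries = default_libraries(depth = 1000), seed = 3)
  sim <- generate_genome(cfg)
  expect_setequal(unique(sim$features$kind), "background_gene")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 77)
  s1 <- generate_genome(cfg); s2 <- generate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$products, s2$products)
  l1 <- simulate_libraries(s1); l2 <- simulate_libraries(s2)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth_counts, l2$truth_counts)
})

test_that("libraries have the configured depth and 35-base reads", {
  cfg <- small_config(seed = 13)
  sim <- generate_genome(cfg)
  libs <- simulate_libraries(sim)
  expect_equal(unname(sapply(libs$reads, length)),
               cfg$libraries$depth)
  expect_true(all(nchar(unlist(libs$reads)) == 35))
})

test_that("a degenerate length profile yields only that insert length", {
  libs <- default_libraries(depth = 2000)[1:2, ]
  libs[, paste0("w", 19:25)] <- 0
  libs$w24 <- 1
  cfg <- small_config(seed = 21, libraries = libs, error_rate = 0)
  sim <- generate_genome(cfg)
  out <- simulate_libraries(sim)
  tr <- trim_adapter(unlist(out$reads))
  expect_true(all(nchar(tr$insert) == 24))
})

test_that("without noise every insert comes from the planted product set", {
  cfg <- small_config(seed = 29, error_rate = 0, background_fraction = 0)
  sim <- generate_genome(cfg)
  out <- simulate_libraries(sim)
  tr <- trim_adapter(out$reads[[1]])
  expect_true(all(tr$insert %in% sim$products$seq))
})
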