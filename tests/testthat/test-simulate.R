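# Ground-truth generators: determinism, planted-parameter arithmetic,
# statistical behaviour at scale.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 42)
  a <- gen_motif_and_variant(cfg)
  b <- gen_motif_and_variant(cfg)
  expect_identical(a, b)
  expect_identical(gen_variant_block(cfg), gen_variant_block(cfg))
  expect_identical(gen_allelic_counts(cfg), gen_allelic_counts(cfg))
  # a different seed changes the data
  expect_false(identical(gen_allelic_counts(cfg),
                         gen_allelic_counts(sim_config(seed = 43))))
})

test_that("planted motif: expected fold, window consistency, control case", {
  cfg <- sim_config(seed = 6, consensus_freq = 0.8, disrupted_freq = 0.1)
  sim <- gen_motif_and_variant(cfg)
  expect_equal(sim$expected_log2_fold, 3)  # log2(8)
  expect_equal(sim$pfm$length, 11)
  expect_true(sim$pfm$is_frequency)
  expect_true(all(sim$pfm$counts > 0))  # strictly positive -> pseudocount 0 valid
  expect_equal(nchar(sim$pair$ref_window), 51)
  # informative position carries the planted frequencies for the two alleles
  ip <- cfg$informative_position
  expect_equal(unname(sim$pfm$counts[sim$pair$variant$ref, ip]), 0.8)
  expect_equal(unname(sim$pfm$counts[sim$pair$variant$alt, ip]), 0.1)

  # near-control: consensus barely above disrupted gives a near-zero fold
  ctrl <- gen_motif_and_variant(sim_config(seed = 6, consensus_freq = 0.4001,
                                           disrupted_freq = 0.4))
  expect_equal(ctrl$expected_log2_fold, log2(0.4001 / 0.4))

  # motif that cannot fit the window errors out
  expect_error(gen_motif_and_variant(sim_config(seed = 1, motif_length = 11,
                                                flank = 4)), "does not fit")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(disrupted_freq = 0.9, consensus_freq = 0.8),
               "disrupted_freq")
  expect_error(sim_config(consensus_freq = 0.7, disrupted_freq = 0.5),
               "exceed 1")
  expect_error(sim_config(n_in_peak = 20, n_variants_in_block = 17), "n_in_peak")
  expect_error(sim_config(depth_mean = 0), "depth_mean")
  expect_error(sim_config(true_ref_fraction = 1), "true_ref_fraction")
})

test_that("variant block: defaults place 17 variants over ~14 kb, 2 in peaks", {
  block <- gen_variant_block(sim_config(seed = 11))
  expect_equal(nrow(block$variants), 17)
  expect_lte(max(block$variants$pos) - min(block$variants$pos), 14000)
  expect_true(all(block$variants$r2_to_lead >= 0.9))
  expect_equal(sum(block$variants$r2_to_lead == 1), 1)  # one lead variant
  expect_equal(length(block$truth_in_peak), 2)
  expect_true(all(diff(block$variants$pos) > 0))

  # edge cases of the planted peak count
  none <- gen_variant_block(sim_config(seed = 11, n_in_peak = 0))
  expect_equal(length(none$truth_in_peak), 0)
  res0 <- prioritize_variants(none$variants, none$peaks, 0.8, quiet = TRUE)
  expect_equal(nrow(res0$prioritized), 0)

  all_in <- gen_variant_block(sim_config(seed = 11, n_in_peak = 17))
  res17 <- prioritize_variants(all_in$variants, all_in$peaks, 0.8, quiet = TRUE)
  expect_setequal(res17$prioritized$id, all_in$variants$id)

  expect_error(gen_variant_block(sim_config(seed = 1, block_span = 40)),
               "too small")
})

test_that("allelic counts follow the configured depth and allele fraction", {
  # law of large numbers at 10,000 donors: pooled fraction within 0.01 of truth
  big <- gen_allelic_counts(sim_config(seed = 123, true_ref_fraction = 0.5),
                            n_donors = 10000)
  pooled <- sum(big$ref_count) / sum(big$ref_count + big$alt_count)
  expect_lt(abs(pooled - 0.5), 0.01)

  # strong fraction at depth 100: every one of 7 donors is ref-biased
  strong <- gen_allelic_counts(sim_config(seed = 7, true_ref_fraction = 0.95,
                                          depth_mean = 100))
  expect_equal(nrow(strong), 7)
  expect_true(all(strong$ref_count > strong$alt_count))
  expect_true(all(strong$ref_count + strong$alt_count >= 1))
})

test_that("fixture directory is complete, readable and self-consistent", {
  dir <- file.path(tempdir(), "fixture-selfcheck")
  fx <- write_fixture(sim_config(seed = 77), dir)
  expect_true(all(file.exists(unlist(fx$paths))))

  variants <- read_variants(fx$paths$tsv, "tsv")
  expect_equal(nrow(variants), 17)
  peaks <- read_bed(fx$paths$peaks)
  counts <- read_counts(fx$paths$counts)
  expect_equal(nrow(counts), 7)
  motif <- read_pfm(fx$paths$motif)
  expect_equal(motif$length, 11)

  # the genome really carries each variant's ref allele
  genome <- Biostrings::readDNAStringSet(fx$paths$genome)
  contig <- as.character(genome[[1]])
  for (i in seq_len(nrow(variants))) {
    expect_equal(substr(contig, variants$pos[i], variants$pos[i]),
                 variants$ref[i])
  }

  truth <- jsonlite::read_json(fx$paths$truth)
  expect_equal(sort(unlist(truth$in_peak_ids)),
               sort(fx$truth$in_peak_ids |> unlist()))
  expect_true(truth$candidate_id %in% variants$id)
})
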