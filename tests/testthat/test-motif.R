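# PWM construction, k-mer scoring, window extraction and allele-aware scans.

uniform_pwm <- function(L) {
  pfm_to_pwm(pfm(matrix(1, 4, L), "uniform"), pseudocount = 0)
}

test_that("pfm_to_pwm normalizes with pseudocount and guards zero counts", {
  # uniform counts, no pseudocount: all log-odds are exactly 0
  expect_equal(unname(uniform_pwm(5)$log_odds), matrix(0, 4, 5))

  one_col <- pfm(matrix(c(1, 0, 0, 0), 4, 1), "zero")
  expect_error(pfm_to_pwm(one_col, pseudocount = 0), "position 1")
  w <- pfm_to_pwm(one_col, pseudocount = 0.25)
  # (1 + 0.25) / (1 + 1) = 0.625 -> log2(0.625 / 0.25)
  expect_equal(unname(w$log_odds["A", 1]), log2(0.625 / 0.25), tolerance = 1e-12)

  # frequency-dialect matrices pass through with only the background division
  fr <- pfm(matrix(c(0.5, 0.3, 0.1, 0.1), 4, 1), "freq")
  w2 <- pfm_to_pwm(fr, pseudocount = 0)
  expect_equal(unname(w2$log_odds[, 1]), log2(c(0.5, 0.3, 0.1, 0.1) / 0.25))

  expect_error(pfm_to_pwm(fr, background = c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
})

test_that("score_kmer is the sum of per-position log2 odds", {
  expect_equal(score_kmer(uniform_pwm(11), strrep("A", 11)), 0)

  # pos1: A/C at 0.5 each; pos2: G certain -> "AG" scores 1 + 2
  m <- matrix(c(0.5, 0.5, 0, 0,
                0, 0, 1, 0), nrow = 4)
  w <- pfm_to_pwm(pfm(m, "toy"), pseudocount = 1e-12)
  expect_equal(score_kmer(w, "AG"), 3, tolerance = 1e-9)

  expect_error(score_kmer(w, "AGG"), "length")
  expect_error(score_kmer(w, "AN"), "ambiguous")
})

test_that("additivity: window score equals sum of per-position contributions", {
  set.seed(11)
  w <- pfm_to_pwm(random_pfm(9), pseudocount = 0.01)
  for (i in 1:10) {
    kmer <- random_window(9)
    idx <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
    expect_equal(score_kmer(w, kmer),
                 sum(w$log_odds[cbind(idx, 1:9)]), tolerance = 1e-12)
  }
})

test_that("extract_windows returns centred allele windows and validates ref", {
  set.seed(42)
  contig <- random_window(101)
  substr(contig, 51, 51) <- "C"
  seqs <- c(chr1 = contig)
  v <- list(chrom = "chr1", pos = 51L, id = "rs_test", ref = "C", alt = "T")
  pair <- extract_windows(seqs, v, flank = 25)
  expect_equal(nchar(pair$ref_window), 51)
  expect_equal(pair$variant_offset, 25)
  expect_equal(substr(pair$ref_window, 26, 26), "C")
  expect_equal(substr(pair$alt_window, 26, 26), "T")
  # windows differ at exactly the variant offset
  diffs <- which(strsplit(pair$ref_window, "")[[1]] != strsplit(pair$alt_window, "")[[1]])
  expect_equal(diffs, 26)

  v_bad <- v; v_bad$ref <- "G"
  expect_error(extract_windows(seqs, v_bad), "reference mismatch")
  v_edge <- v; v_edge$pos <- 10L
  expect_error(extract_windows(seqs, v_edge), "exceeds contig")
  v_chr <- v; v_chr$chrom <- "chrX"
  expect_error(extract_windows(seqs, v_chr), "contig not found")
})

test_that("scan_allele scores all variant-overlapping placements on both strands", {
  w <- pfm_to_pwm(random_pfm(11), pseudocount = 0.01)
  set.seed(3)
  win <- random_window(51)
  hit <- scan_allele(w, win, variant_offset = 25)
  expect_equal(hit$n_placements, 22)  # offsets 15..25, two strands
  expect_equal(hit$efficiency, 2^hit$score, tolerance = 1e-9)
  expect_true(hit$offset >= 15 && hit$offset <= 25)

  # variant at the very first base of an exactly motif-sized window
  hit2 <- scan_allele(w, random_window(11), variant_offset = 0)
  expect_equal(hit2$n_placements, 2)
  expect_equal(hit2$offset, 0)

  expect_error(scan_allele(w, random_window(8), 0), "shorter than motif")
})

test_that("scan best hit is the true maximum over an explicit enumeration", {
  set.seed(8)
  w <- pfm_to_pwm(random_pfm(5), pseudocount = 0.01)
  win <- random_window(21)
  voff <- 10
  best <- -Inf
  for (o in (voff - 4):voff) {
    kmer <- substr(win, o + 1, o + 5)
    best <- max(best, score_kmer(w, kmer), score_kmer(w, rev_comp_str(kmer)))
  }
  expect_equal(scan_allele(w, win, voff)$score, best, tolerance = 1e-12)
})

test_that("strand symmetry: scanning the reverse-complemented window matches", {
  set.seed(21)
  for (i in 1:5) {
    w <- pfm_to_pwm(random_pfm(7), pseudocount = 0.01)
    win <- random_window(31)
    voff <- 15
    h_fwd <- scan_allele(w, win, voff)
    h_rev <- scan_allele(w, rev_comp_str(win), nchar(win) - 1 - voff)
    expect_equal(h_fwd$score, h_rev$score, tolerance = 1e-12)
    # offsets mirror: o' = W - L - o
    if (h_fwd$score != h_rev$score || h_fwd$strand != h_rev$strand) {
      expect_equal(h_rev$offset, nchar(win) - 7 - h_fwd$offset)
    }
  }
})

test_that("palindromic-scoring PWM ties break to the + strand", {
  # log-odds invariant under reverse complement: all-equal matrix
  w <- uniform_pwm(4)
  hit <- scan_allele(w, "ACGTACGT", variant_offset = 3)
  expect_equal(hit$strand, "+")
  expect_equal(hit$offset, 0)  # smallest offset among ties
})

test_that("ambiguous bases: hard error by default, skip mode drops placements", {
  w <- pfm_to_pwm(random_pfm(3), pseudocount = 0.01)
  win <- "ACGTNCG"  # N two bases right of the variant
  expect_error(scan_allele(w, win, 3), "ambiguous")
  hit <- scan_allele(w, win, 3, ambig = "skip")
  expect_equal(hit$n_placements, 2)  # only the N-free placement, both strands
  expect_error(scan_allele(w, "ANN", 1, ambig = "skip"), "all placements")
})

test_that("binding_report: fold change, direction and allele-swap inversion", {
  sim <- gen_motif_and_variant(sim_config(seed = 5))
  w <- pfm_to_pwm(sim$pfm, pseudocount = 0)
  rep <- binding_report(w, sim$pair, pvalues = FALSE)
  # alt allele drops one position from 0.8 to 0.1: 8-fold in favour of ref
  expect_equal(rep$efficiency_fold_change, 0.1 / 0.8, tolerance = 1e-9)
  expect_equal(rep$fold_change_favored, 8, tolerance = 1e-9)
  expect_equal(rep$favored_allele, "ref")
  expect_equal(rep$efficiency_fold_change,
               2^(rep$alt_hit$score - rep$ref_hit$score), tolerance = 1e-9)

  # swapping the alleles inverts the fold change exactly
  swapped <- variant_windows(sim$pair$alt_window, sim$pair$ref_window,
                             variant_offset = sim$pair$variant_offset)
  rep_sw <- binding_report(w, swapped, pvalues = FALSE)
  expect_equal(rep_sw$efficiency_fold_change,
               1 / rep$efficiency_fold_change, tolerance = 1e-9)

  # identical windows: no change
  same <- variant_windows(sim$pair$ref_window, sim$pair$ref_window,
                          variant_offset = sim$pair$variant_offset)
  expect_equal(binding_report(w, same, pvalues = FALSE)$efficiency_fold_change, 1)
})

test_that("aligned-placement identity: log2 fold equals the log-odds difference", {
  sim <- gen_motif_and_variant(sim_config(seed = 9))
  w <- pfm_to_pwm(sim$pfm, pseudocount = 0)
  rep <- binding_report(w, sim$pair, pvalues = FALSE)
  if (rep$ref_hit$offset == rep$alt_hit$offset &&
      rep$ref_hit$strand == rep$alt_hit$strand && rep$ref_hit$strand == "+") {
    j <- sim$pair$variant_offset - rep$ref_hit$offset + 1
    lo_diff <- w$log_odds[sim$pair$variant$alt, j] - w$log_odds[sim$pair$variant$ref, j]
    expect_equal(log2(rep$efficiency_fold_change), unname(lo_diff), tolerance = 1e-9)
  }
})

test_that("binding report flattens to the documented TSV columns", {
  sim <- gen_motif_and_variant(sim_config(seed = 2))
  w <- pfm_to_pwm(sim$pfm, pseudocount = 0)
  rep <- binding_report(w, sim$pair)
  df <- as.data.frame(rep)
  expect_named(df, c("motif_id", "variant_id", "ref_score", "alt_score",
                     "ref_strand", "alt_strand", "ref_offset", "alt_offset",
                     "efficiency_fold_change", "pvalue_ref", "pvalue_alt",
                     "pvalue_fold_change", "favored_allele"))
  f <- tempfile(fileext = ".tsv")
  write_motif_report(rep, f)
  expect_equal(nrow(read.delim(f)), 1)
})
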