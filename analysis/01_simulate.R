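#!/usr/bin/env Rscript
# Generate the synthetic fine-mapping locus used by the downstream analyses:
# an 11 bp GATA-like motif whose informative position a SNV disrupts, a
# 17-variant high-LD block (~14 kb) with 2 variants under accessibility
# peaks, and allelic read counts for 7 heterozygous donors (~60x, true
# reference fraction 0.95). Everything is a pure function of the seed.

library(finemotif)

seed <- 20260930L
dir <- "results/fixture"

cfg <- sim_config(seed = seed)
fx <- write_fixture(cfg, dir)

cat("Synthetic locus written to", dir, "\n")
cat("  candidate variant :", fx$truth$candidate_id, "\n")
cat("  planted in-peak   :", paste(unlist(fx$truth$in_peak_ids), collapse = ", "), "\n")
cat("  planted log2 fold :", fx$truth$expected_log2_fold,
    "(consensus 0.8 vs disrupted 0.1)\n")
cat("  true ref fraction :", fx$truth$true_ref_fraction, "\n")
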