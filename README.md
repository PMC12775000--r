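# finemotif

Functional fine-mapping of non-coding GWAS loci in R: given a block of
associated variants in high linkage disequilibrium (LD), `finemotif`
narrows the block to candidate causal variants and quantifies their
predicted and observed regulatory effects. It is aimed at regulatory
genomicists who have an LD block, an accessibility peak set, a
transcription-factor motif and allelic read counts at a heterozygous
site, and want the three standard evidence lines computed exactly and
reproducibly:

1. **Peak prioritization** — filter the block by r² to the lead variant
   and keep variants inside accessible-chromatin peaks (1-based variant
   vs 0-based half-open BED semantics handled once, at the intersection).
2. **Allele-aware motif analysis** — score both alleles of a SNV against
   a position weight matrix. For a sequence *s* of motif length *n*,

   Score(s) = Σᵢ log₂( M(sᵢ, i) / b(sᵢ) ),

   with background *b* (uniform 0.25 by default); binding efficiency is
   2^Score. Each allele's 51 bp window is scanned over every
   variant-overlapping placement on both strands and the best placement
   kept. Reported contrasts: the binding-efficiency fold change
   2^(Score_alt − Score_ref), and the exact motif p-value fold change
   max(p_ref, p_alt)/min(p_ref, p_alt), where p = P(Score ≥ s) under the
   exact background score distribution computed by dynamic-programming
   convolution (conservative flooring on a 0.001-log₂ grid).
3. **Allelic imbalance** — exact two-sided binomial tests of k reference
   reads out of n against a ploidy-aware null p₀ = ref_copies/total_copies
   (0.5 diploid or balanced tetraploid; 1/3 and 2/3 for triploid
   heterozygotes), per donor and pooled, in log space so extreme
   p-values (≈10⁻⁴⁵ and far below) stay representable, plus a
   sensitivity sweep across nulls.

A synthetic-data generator (`sim_config()`, `write_fixture()`) produces
motif matrices, a variant-bearing genome, LD-annotated variant blocks,
peak sets and per-donor counts with known ground truth, so the whole
pipeline is testable end to end without external data.

## Worked example

The numbered scripts under `analysis/` run the complete workflow on the
default synthetic locus (17-variant/14 kb block, 2 variants in peaks,
11 bp motif with a planted log₂ fold of 3, 7 donors at ~60× with true
reference fraction 0.95):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_prioritize.R
Rscript analysis/03_motif_analysis.R
Rscript analysis/04_allelic_imbalance.R
Rscript analysis/05_evidence_summary.R
```

which prints (abridged):

```
17 of 17 block variants pass r2 >= 0.8; 2 map to peaks: rs_sim008, rs_sim013
rs_sim008: efficiency fold change 8 favoring ref allele; p-value fold change 2 (p_ref 2.38e-07, p_alt 4.77e-07)
7 donors, pooled 364 ref / 381 total (fraction 0.955)
pooled two-sided binomial p = 6.26e-86 (ref-biased); per-donor fraction spread 0.061
ploidy-null sensitivity:
  H0 p = 0.5000 -> p = 6.26e-86 (ref-biased)
  H0 p = 0.3333 -> p = 3.25e-148 (ref-biased)
  H0 p = 0.6667 -> p = 1.66e-43 (ref-biased)
ground-truth checks:
  in-peak set recovered exactly: TRUE
  log2 efficiency fold: recovered 3.000000000 vs planted 3.000000000
```

Reading the numbers: the prioritization recovers exactly the two planted
in-peak variants out of 17; the candidate's alternate allele lowers the
informative motif position's frequency from 0.8 to 0.1, so the reference
allele binds 8-fold (2³) more efficiently, recovered to machine
precision; and the pooled read counts reject every plausible ploidy null
in the reference-biased direction. Per-candidate evidence is written to
`results/evidence/evidence.json`, with TSV reports alongside.

The same steps are available programmatically: `run_pipeline()` executes
prioritize → motif scan → imbalance from a single YAML config and is
byte-reproducible for a fixed config and seed.

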