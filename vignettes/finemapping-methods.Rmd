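---
title: "Methods: motif disruption and allelic imbalance for fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif disruption and allelic imbalance for fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemotif)
```

## The problem

A GWAS association is usually carried by a block of variants in high
linkage disequilibrium (LD): statistically they are interchangeable, so
association evidence alone cannot say which variant is causal. Functional
fine-mapping breaks the tie with orthogonal molecular evidence. This
package implements three such evidence lines for a non-coding SNV and
combines them per candidate:

1. **Chromatin accessibility** — of the high-LD variants, only those lying
   inside accessible-chromatin peaks (ATAC/DNase) are plausible regulatory
   candidates.
2. **Motif disruption** — if the variant changes a transcription-factor
   binding motif, the two alleles should score differently against the
   factor's position weight matrix (PWM).
3. **Allelic imbalance** — in accessibility or ChIP reads from
   heterozygous samples, a functional allele difference shows up as a
   skewed reference/alternate read ratio at the site.

## Allele-aware PWM scoring

A motif of length $L$ is described by a position frequency matrix $M$
(per-position nucleotide frequencies). A sequence $s$ of length $L$ scores

$$\mathrm{Score}(s) \;=\; \sum_{i=1}^{L} \log_2 \frac{M_{s_i,i}}{b_{s_i}},$$

where $b$ is the background composition (uniform $0.25$ by default,
configurable). The predicted relative binding efficiency is
$2^{\mathrm{Score}}$, so the allelic effect is summarized by the
efficiency ratio $2^{\mathrm{Score_{alt}} - \mathrm{Score_{ref}}}$.

For each allele we extract the $2f+1$ bp window centred on the variant
(default $f = 25$, i.e. 51 bp), score *every* motif placement whose span
covers the variant on the forward strand and on the reverse complement
(22 placements for an 11 bp motif and a central variant), and keep the
best-scoring placement. The two alleles are scanned independently, so
their best placements may differ in offset and strand; this is deliberate —
each allele is represented by its own best match. Ties are broken to the
forward strand, then to the smaller offset, so output is deterministic.

Count matrices are converted to frequencies with a pseudocount:
$(c + \kappa)/(\text{column total} + 4\kappa)$, default $\kappa = 0.01$
per cell. The pseudocount matters: published fold-change figures for real
motifs depend on the convention used by the original matrix provider, so
$\kappa$ is an explicit argument rather than a constant. Zero counts with
$\kappa = 0$ are an error (they would produce $-\infty$ log-odds).

## Exact motif p-values

A score is interpretable only relative to chance, so each allele's best
score also gets an exact p-value: the probability that a random
background sequence of motif length scores at least as high. Because the
score is a sum of independent per-position terms, its exact distribution
is computed by dynamic-programming convolution: each position's four
log-odds values are floored onto an integer grid of step
$\varepsilon = 0.001$ log2 units and the per-position mass functions are
convolved. For $L \le 8$ the result is testable against exhaustive
enumeration of all $4^L$ sequences; the suite checks agreement to total
variation $< 10^{-9}$ at matched rounding.

Two numerical choices deserve a note:

* **Floor rounding with query widening.** Flooring each position loses up
  to one grid step per position, so a sequence's gridded score may sit up
  to $L$ steps below its true score. Flooring the query alone would
  therefore *not* guarantee a conservative p-value. We lower the query
  threshold by a further $L - 1$ grid steps; a short argument (any k-mer's
  gridded score exceeds $\mathrm{Score}/\varepsilon - L$) then guarantees
  the reported tail probability is never smaller than the exact one, at
  the cost of at most $L\varepsilon$ (0.011 log2 units for an 11 bp motif)
  of resolution. The property suite verifies conservativeness against
  enumerated exact tails.
* **Grid-point tolerance.** Values sitting on a grid point are protected
  from float error by adding $10^{-9}$ before flooring.

The allelic contrast on this scale is the **p-value fold change**
$\max(p_{ref}, p_{alt}) / \min(p_{ref}, p_{alt}) \ge 1$, flagged with the
favoured allele (the one with the smaller p-value).

## Allelic imbalance

At a heterozygous site with $k$ reference reads out of $n$, we test
$H_0\!: p = p_0$ with an exact two-sided binomial test. The default
two-sided convention is *minlike* — the sum of probabilities of all
outcomes no more likely than the observed one, with a $1+10^{-7}$
relative slack on the point-probability comparison to avoid floating-point
inclusion flips; this matches the convention of `stats::binom.test`,
which serves as an independent cross-check in the tests (never as the
implementation). A *doubled* convention,
$2\min\{P(X \le k), P(X \ge k)\}$ capped at 1, is offered because the two
differ for $p_0 \ne 1/2$ and published analyses rarely say which they
used. Tail sums are accumulated in log space so that extreme imbalances
(p-values of $10^{-45}$ and far below) remain representable.

The null $p_0$ is ploidy-aware: for a site with $t$ total copies of which
$r$ carry the reference allele, $p_0 = r/t$ — $1/2$ for a diploid or
balanced tetraploid heterozygote, $1/3$ or $2/3$ for the two triploid
heterozygous genotypes (we interpret printed "0.33"/"0.66" nulls as exact
thirds, since they are copy-number ratios). Homozygous configurations are
an error: no imbalance test is defined. `null_sensitivity()` re-tests the
same counts under a set of nulls — typically $\{1/2, 1/3, 2/3\}$ — to show
a call is robust to the local copy-number assignment.

Multiple donors are tested per sample and on pooled (summed) counts; the
pooled test is the headline number, per-donor directions and the maximum
pairwise fraction difference are reported but not formally tested
(heterogeneity modelling is out of scope). Zero-depth samples are dropped
with a warning, never silently.

## Prioritization and coordinate conventions

Variants use 1-based positions (VCF convention); intervals are 0-based
half-open (BED convention). The single conversion happens inside the
intersection: a variant at position $p$ is inside peak $[s, e)$ iff
$s \le p - 1 < e$, so a variant on the closed start is inside, one on the
exclusive end is outside. Chromosome names are left untouched by default
("chr1" vs "1" must be consistent across inputs — the pipeline fails
pre-flight otherwise); a `chrom_normalize` switch ("strip"/"add") is
available, opt-in, because silent normalization hides data errors.
Coverage tracks are binned means of per-base depth (500 bp bins for locus
overviews, 50 bp for fine structure), with optional counts-per-million
scaling; raw-mode binning conserves total overlapped bases exactly.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the study conditions: an 11 bp motif with
one informative position (consensus base frequency 0.8, disrupting base
0.1, so the planted effect is $\log_2(0.8/0.1) = 3$), other positions at
0.85 consensus; a 17-variant block spanning 14 kb with $r^2 \ge 0.9$ to
the lead; peaks covering exactly 2 block variants (peak widths up to
300 bp, clipped so no off-target variant is covered, plus a decoy peak in
the widest variant-free gap); 7 heterozygous donors with negative-binomial
depths (mean 60, dispersion 10 — typical DNase/ChIP heterozygous-site
depth; chosen once as a realistic value since depth distributions are
rarely printed) and binomial reference counts at a true reference
fraction of 0.95. Background sequence is uniform in composition, matching
the $b = 0.25$ scoring background.

The generator's PFM frequencies are strictly positive, so it can be
scored with pseudocount 0; the recovery analyses do exactly that, which
is why the planted $\log_2$ fold is recovered to $10^{-9}$ rather than
approximately. (With the pipeline default $\kappa = 0.01$ the recovered
fold would be $\log_2((0.8 + \kappa')/(0.1 + \kappa'))$ for the
column-normalized $\kappa'$ — close, not exact.)

Real data differ in ways the generator does not model, so passing
recovery tests does not certify performance on real reads: no
reference-mapping bias (which inflates apparent reference fractions), no
read-level errors or overdispersion beyond the negative-binomial depth
(a beta-binomial count model is out of scope), LD is an annotation rather
than a haplotype simulation, and background sequence has no GC structure
by default (a GC-skew option exists for the scoring background).

## Problem sizes

The test-suite and acceptance computations use: 25 random motifs of
length 2–8 against $4^L$ enumeration; all $(k, n \le 12)$ binomial
outcomes under three nulls; 10,000 null cohorts of $n = 50$ for
calibration; 100 replicate donor cohorts for detection-rate estimates;
one full 17-variant locus per run. These sizes keep every check exact or
tightly bounded while running in seconds.

## Known limitations

* Published motif fold-change figures for real loci are reproducible only
  up to the original pseudocount convention and motif-database release,
  neither of which is generally printed; the machinery accepts JASPAR and
  HOCOMOCO count matrices, but no third-party matrix is bundled.
* The exact binomial test assumes reads are independent Bernoulli draws;
  PCR duplicates and mapping bias violate this in real libraries and are
  expected to be handled upstream.
* `minlike` p-values are not monotone in $|k/n - p_0|$ *across* tails for
  asymmetric nulls (a known property of the convention, not a defect);
  within each tail they are monotone, which is what the suite asserts.
* The pipeline tests one candidate's count table per run; multi-locus
  scans would need per-locus count inputs.
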