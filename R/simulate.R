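#' Configuration for the synthetic fine-mapping dataset
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the study setting this pipeline targets: an 11 bp GATA-like
#' motif with one strongly constrained position that the alternate allele
#' disrupts, a block of 17 high-LD variants spanning ~14 kb of which
#' exactly 2 fall in accessible-chromatin peaks, and allelic read counts
#' for 7 heterozygous donors at roughly 60x depth with a strong (0.95)
#' true reference-allele fraction.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @param motif_length Motif length in bp (default 11).
#' @param informative_position 1-based motif position carrying the
#'   variant-sensitive base (default 6, the centre of an 11-mer).
#' @param consensus_freq Frequency of the reference (consensus) base at the
#'   informative position (default 0.8).
#' @param disrupted_freq Frequency of the alternate (disrupting) base there
#'   (default 0.1); must satisfy `0 < disrupted_freq < consensus_freq <= 1`.
#' @param other_consensus_freq Consensus-base frequency at the remaining
#'   motif positions (default 0.85, a strongly constrained motif).
#' @param n_variants_in_block Variants in the LD block (default 17).
#' @param n_in_peak How many block variants the peak set covers (default 2).
#' @param n_donors Heterozygous donors with allelic counts (default 7).
#' @param depth_mean,depth_dispersion Mean and negative-binomial dispersion
#'   (size) of per-donor total read depth (defaults 60 and 10).
#' @param true_ref_fraction True probability a read carries the reference
#'   allele (default 0.95, a strong imbalance).
#' @param ploidy,ref_copies Copy-number configuration used for the null
#'   (defaults 2 and 1, i.e. a balanced diploid null of 0.5).
#' @param block_span LD block span in bases (default 14000).
#' @param flank Window flank around the candidate variant (default 25,
#'   giving 51 bp windows).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       motif_length = 11L,
                       informative_position = 6L,
                       consensus_freq = 0.8,
                       disrupted_freq = 0.1,
                       other_consensus_freq = 0.85,
                       n_variants_in_block = 17L,
                       n_in_peak = 2L,
                       n_donors = 7L,
                       depth_mean = 60,
                       depth_dispersion = 10,
                       true_ref_fraction = 0.95,
                       ploidy = 2L,
                       ref_copies = 1L,
                       block_span = 14000L,
                       flank = 25L) {
  cfg <- list(seed = as.integer(seed), motif_length = as.integer(motif_length),
              informative_position = as.integer(informative_position),
              consensus_freq = consensus_freq, disrupted_freq = disrupted_freq,
              other_consensus_freq = other_consensus_freq,
              n_variants_in_block = as.integer(n_variants_in_block),
              n_in_peak = as.integer(n_in_peak), n_donors = as.integer(n_donors),
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              true_ref_fraction = true_ref_fraction, ploidy = as.integer(ploidy),
              ref_copies = as.integer(ref_copies),
              block_span = as.integer(block_span), flank = as.integer(flank))
  with(cfg, {
    if (motif_length < 1) fm_stop("motif_length must be >= 1")
    if (informative_position < 1 || informative_position > motif_length) {
      fm_stop("informative_position outside the motif")
    }
    if (!(disrupted_freq > 0 && disrupted_freq < consensus_freq &&
          consensus_freq <= 1)) {
      fm_stop("need 0 < disrupted_freq < consensus_freq <= 1")
    }
    if (consensus_freq + disrupted_freq > 1) {
      fm_stop("consensus_freq + disrupted_freq must not exceed 1")
    }
    if (n_in_peak < 0 || n_in_peak > n_variants_in_block) {
      fm_stop("n_in_peak must be in [0, n_variants_in_block]")
    }
    if (depth_mean <= 0) fm_stop("depth_mean must be positive")
    if (true_ref_fraction <= 0 || true_ref_fraction >= 1) {
      fm_stop("true_ref_fraction must lie strictly between 0 and 1")
    }
  })
  structure(cfg, class = "sim_config")
}

# run fn with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate a motif with one variant-sensitive position plus allele windows
#'
#' Builds a frequency PFM whose informative position gives the reference
#' base `consensus_freq`, the alternate base `disrupted_freq`, and splits
#' the remainder over the other two bases; other positions put
#' `other_consensus_freq` on a random consensus base. A background window
#' of `2 * flank + 1` bp is generated and the motif's consensus sequence is
#' planted so the variant base lands on the informative position; the
#' alternate window substitutes the disrupting base there.
#'
#' All frequencies are strictly positive, so the PFM can be converted with
#' pseudocount 0, in which case (when both alleles' best placements
#' coincide) the log2 binding-efficiency fold change equals exactly
#' `expected_log2_fold = log2(consensus_freq / disrupted_freq)` in favour
#' of the reference allele.
#'
#' @param config A [sim_config()].
#' @return List with `pfm`, `pair` (a `variant_windows`), and
#'   `expected_log2_fold`.
#' @export
gen_motif_and_variant <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$motif_length
  ip <- config$informative_position
  f <- config$flank
  start0 <- f - (ip - 1)  # 0-based motif start if variant sits at window centre
  if (start0 < 0 || start0 + L > 2 * f + 1) {
    fm_stop("motif (", L, " bp, informative position ", ip,
            ") does not fit in a ", 2 * f + 1, " bp window at the centre")
  }
  with_seed(config$seed, function() {
    cons <- sample(BASES, L, replace = TRUE)
    freq <- matrix((1 - config$other_consensus_freq) / 3, 4, L,
                   dimnames = list(BASES, NULL))
    for (j in seq_len(L)) freq[cons[j], j] <- config$other_consensus_freq

    ref_base <- cons[ip]
    alt_base <- sample(setdiff(BASES, ref_base), 1)
    rest <- setdiff(BASES, c(ref_base, alt_base))
    freq[, ip] <- 0
    freq[ref_base, ip] <- config$consensus_freq
    freq[alt_base, ip] <- config$disrupted_freq
    freq[rest, ip] <- (1 - config$consensus_freq - config$disrupted_freq) / 2
    if (any(freq[, ip] <= 0)) {
      # degenerate split (consensus + disrupted = 1): keep strict positivity
      freq[rest, ip] <- 1e-6
      freq[ref_base, ip] <- config$consensus_freq - 1e-6
      freq[alt_base, ip] <- config$disrupted_freq - 1e-6
    }

    window <- sample(BASES, 2 * f + 1, replace = TRUE)
    window[start0 + seq_len(L)] <- cons
    ref_window <- paste(window, collapse = "")
    alt_chars <- window
    alt_chars[f + 1] <- alt_base
    alt_window <- paste(alt_chars, collapse = "")

    pair <- variant_windows(
      ref_window, alt_window,
      variant = list(chrom = "chrSim", pos = f + 1L, id = "rs_sim_candidate",
                     ref = ref_base, alt = alt_base),
      variant_offset = f
    )
    list(pfm = pfm(freq, motif_id = "SIM_GATA_like"),
         pair = pair,
         expected_log2_fold = log2(config$consensus_freq / config$disrupted_freq))
  })
}

#' Generate an LD block of variants and a peak set covering a known subset
#'
#' Places `n_variants_in_block` variants at distinct positions across
#' `block_span` bases, annotates each with a high r2 to the lead variant
#' (uniform on [0.9, 1]; one variant is the lead with r2 = 1), and builds
#' one peak per planted in-peak variant, sized so it covers that variant
#' and no other. A decoy peak is added in the largest variant-free gap
#' when one is wide enough.
#'
#' @param config A [sim_config()].
#' @param chrom Chromosome name for the synthetic locus.
#' @param origin 0-based coordinate at which the block starts.
#' @return List with `variants` (data.frame incl. `r2_to_lead`), `peaks`
#'   (data.frame with `name`), and `truth_in_peak` (ids of the covered
#'   variants).
#' @export
gen_variant_block <- function(config, chrom = "chrSim", origin = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_variants_in_block
  if (config$block_span < 4 * n) {
    fm_stop("block_span too small to place ", n, " distinct variants")
  }
  with_seed(config$seed + 1L, function() {
    pos <- origin + sort(sample.int(config$block_span, n))
    r2 <- stats::runif(n, 0.9, 1)
    r2[sample.int(n, 1)] <- 1  # the lead variant
    ref <- sample(BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), character(1))
    variants <- data.frame(
      chrom = chrom, pos = pos, id = sprintf("rs_sim%03d", seq_len(n)),
      ref = ref, alt = unname(alt), r2_to_lead = r2,
      stringsAsFactors = FALSE
    )

    targets <- if (config$n_in_peak > 0) sort(sample.int(n, config$n_in_peak))
               else integer(0)
    peaks <- NULL
    for (i in targets) {
      p <- pos[i]
      gap_left <- if (i > 1) p - pos[i - 1] else p - origin
      gap_right <- if (i < n) pos[i + 1] - p else origin + config$block_span + 200 - p
      start0 <- p - 1 - min(149, max(0, gap_left - 1))
      end0 <- p + min(150, max(0, gap_right - 1))
      peaks <- rbind(peaks, data.frame(chrom = chrom, start = start0, end = end0,
                                       name = sprintf("peak_%s", variants$id[i]),
                                       stringsAsFactors = FALSE))
    }
    # decoy peak in the widest variant-free gap, if roomy enough
    gaps <- diff(c(origin, pos, origin + config$block_span))
    gi <- which.max(gaps)
    if (gaps[gi] >= 600) {
      left <- c(origin, pos)[gi]
      centre <- left + gaps[gi] %/% 2
      peaks <- rbind(peaks, data.frame(chrom = chrom, start = centre - 100,
                                       end = centre + 100, name = "peak_decoy",
                                       stringsAsFactors = FALSE))
    }
    if (is.null(peaks)) {
      peaks <- data.frame(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          stringsAsFactors = FALSE)
    }
    list(variants = variants, peaks = peaks,
         truth_in_peak = variants$id[targets])
  })
}

#' Generate per-donor allelic read counts with known truth
#'
#' Each donor's total depth is drawn from a negative binomial with mean
#' `depth_mean` and dispersion `depth_dispersion` (floored at 1 read), and
#' the reference count from `Binomial(depth, true_ref_fraction)`.
#'
#' @param config A [sim_config()].
#' @param n_donors Override the configured number of donors.
#' @return Data.frame with `sample_id`, `ref_count`, `alt_count`;
#'   attribute `true_ref_fraction` carries the ground truth.
#' @export
gen_allelic_counts <- function(config, n_donors = config$n_donors) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth_mean <= 0) fm_stop("depth_mean must be positive")
  with_seed(config$seed + 2L, function() {
    depth <- pmax(1L, stats::rnbinom(n_donors, size = config$depth_dispersion,
                                     mu = config$depth_mean))
    ref <- stats::rbinom(n_donors, depth, config$true_ref_fraction)
    out <- data.frame(sample_id = sprintf("donor%02d", seq_len(n_donors)),
                      ref_count = as.integer(ref),
                      alt_count = as.integer(depth - ref),
                      stringsAsFactors = FALSE)
    attr(out, "true_ref_fraction") <- config$true_ref_fraction
    out
  })
}

#' Write a complete synthetic fixture directory
#'
#' Builds one coherent synthetic locus and writes every input the pipeline
#' reads: `motif.pfm` (JASPAR text), `genome.fa` (a contig carrying the
#' planted motif around the candidate variant), `variants.vcf`,
#' `variants.tsv` (with r2), `peaks.bed`, `counts.tsv`, `truth.json` and a
#' ready-to-run `config.yaml` for [run_pipeline()].
#'
#' The candidate variant is the first planted in-peak variant (when
#' `n_in_peak` is 0, the block's first variant); its alleles and local
#' sequence come from [gen_motif_and_variant()], so the planted
#' log2 efficiency fold change is known. Every other variant's ref allele
#' is made consistent with the written contig.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the paths and the truth record.
#' @export
write_fixture <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  motif <- gen_motif_and_variant(config)
  block <- gen_variant_block(config)
  counts <- gen_allelic_counts(config)

  chrom <- block$variants$chrom[1]
  contig_len <- 1000L + config$block_span + 1000L
  contig <- with_seed(config$seed + 3L, function() {
    sample(BASES, contig_len, replace = TRUE)
  })

  candidate_idx <- if (length(block$truth_in_peak) > 0) {
    match(block$truth_in_peak[1], block$variants$id)
  } else 1L
  cand_pos <- block$variants$pos[candidate_idx]
  f <- config$flank
  # embed the planted ref window so the candidate's motif context is real
  contig[(cand_pos - f):(cand_pos + f)] <- strsplit(motif$pair$ref_window, "")[[1]]

  # make every variant's ref allele agree with the contig
  for (i in seq_len(nrow(block$variants))) {
    b <- contig[block$variants$pos[i]]
    block$variants$ref[i] <- b
    if (block$variants$alt[i] == b) {
      block$variants$alt[i] <- setdiff(BASES, b)[1]
    }
  }
  block$variants$alt[candidate_idx] <- motif$pair$variant$alt
  stopifnot(block$variants$ref[candidate_idx] == motif$pair$variant$ref)

  paths <- list(
    motif = file.path(dir, "motif.pfm"),
    genome = file.path(dir, "genome.fa"),
    vcf = file.path(dir, "variants.vcf"),
    tsv = file.path(dir, "variants.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_pfm(motif$pfm, paths$motif)
  seq <- Biostrings::DNAStringSet(paste(contig, collapse = ""))
  names(seq) <- chrom
  Biostrings::writeXStringSet(seq, paths$genome, width = 70)
  write_variants_vcf(block$variants, paths$vcf)
  utils::write.table(block$variants, paths$tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_bed(block$peaks, paths$peaks)
  write_counts(counts, paths$counts)

  truth <- list(
    seed = config$seed,
    candidate_id = block$variants$id[candidate_idx],
    in_peak_ids = as.list(block$truth_in_peak),
    expected_log2_fold = motif$expected_log2_fold,
    true_ref_fraction = config$true_ref_fraction,
    null_p = config$ref_copies / config$ploidy
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)

  yaml::write_yaml(list(
    inputs = list(variants = "variants.tsv", dialect = "tsv",
                  peaks = "peaks.bed", genome = "genome.fa",
                  pfm = "motif.pfm", counts = "counts.tsv"),
    params = list(r2_min = 0.8, flank = config$flank, pseudocount = 0,
                  grid_step = 0.001, method = "minlike",
                  ploidy = config$ploidy, ref_copies = config$ref_copies,
                  sensitivity_nulls = c(0.5, 1 / 3, 2 / 3),
                  counts_variant = block$variants$id[candidate_idx])
  ), paths$config, precision = 15)

  invisible(list(paths = paths, truth = truth, config = config))
}
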