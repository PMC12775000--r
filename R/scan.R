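#' Extract allele-specific sequence windows around a SNV
#'
#' Pulls the `2 * flank + 1` bp window centred on the variant position from
#' a reference sequence (default flank 25, giving a 51 bp window), checks
#' that the genomic base matches the declared reference allele, and builds
#' the alternate-allele window by substituting the centre base.
#'
#' @param seqs A reference sequence source: a
#'   [Biostrings::DNAStringSet], a named character vector of contigs, or
#'   the path to a FASTA file.
#' @param variant A single variant: a one-row data.frame or list with
#'   `chrom`, `pos` (1-based), `id`, `ref`, `alt`.
#' @param flank Bases either side of the variant; default 25.
#' @return An object of class `variant_windows` with fields `variant`,
#'   `ref_window`, `alt_window`, `flank` and `variant_offset` (0-based index
#'   of the variant base within each window, equal to `flank`).
#' @export
extract_windows <- function(seqs, variant, flank = 25) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    seqs <- Biostrings::readDNAStringSet(seqs)
  }
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs),
                            sub("\\s.*$", "", names(seqs)))
  }
  variant <- as.list(variant)
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  if (!chrom %in% names(seqs)) fm_stop("contig not found in sequence source: ", chrom)
  contig <- toupper(seqs[[chrom]])
  if (pos - flank < 1 || pos + flank > nchar(contig)) {
    fm_stop("window [", pos - flank, ", ", pos + flank,
            "] exceeds contig ", chrom, " (length ", nchar(contig), ")")
  }
  window <- substr(contig, pos - flank, pos + flank)
  check_dna(window, paste0("window around ", chrom, ":", pos))
  found <- substr(window, flank + 1, flank + 1)
  if (found != ref) {
    fm_stop("reference mismatch at ", chrom, ":", pos, ": found '", found,
            "', expected ref allele '", ref, "'")
  }
  alt_window <- window
  substr(alt_window, flank + 1, flank + 1) <- alt
  structure(
    list(variant = variant, ref_window = window, alt_window = alt_window,
         flank = flank, variant_offset = flank),
    class = "variant_windows"
  )
}

#' Build a window pair directly from two sequences
#'
#' For synthetic or pre-extracted windows: validates that the two windows
#' differ only at the variant offset and that the centre bases match the
#' declared alleles.
#'
#' @param ref_window,alt_window Equal-length A/C/G/T strings.
#' @param variant Variant record (list or one-row data.frame); defaults to a
#'   placeholder consistent with the windows.
#' @param variant_offset 0-based offset of the variant base; default centre.
#' @return A `variant_windows` object.
#' @export
variant_windows <- function(ref_window, alt_window, variant = NULL,
                            variant_offset = (nchar(ref_window) - 1L) %/% 2L) {
  ref_window <- toupper(ref_window)
  alt_window <- toupper(alt_window)
  if (nchar(ref_window) != nchar(alt_window)) {
    fm_stop("ref and alt windows differ in length")
  }
  check_dna(c(ref_window, alt_window), "window")
  rb <- strsplit(ref_window, "")[[1]]
  ab <- strsplit(alt_window, "")[[1]]
  diffs <- which(rb != ab)
  if (!identical(diffs, as.integer(variant_offset) + 1L) &&
      !(length(diffs) == 0 && rb[variant_offset + 1] == ab[variant_offset + 1])) {
    if (length(diffs) != 1 || diffs != variant_offset + 1) {
      fm_stop("windows must differ exactly at the variant offset (",
              variant_offset, "); they differ at ",
              paste(diffs - 1, collapse = ", "))
    }
  }
  if (is.null(variant)) {
    variant <- list(chrom = "synthetic", pos = variant_offset + 1L,
                    id = "snv", ref = rb[variant_offset + 1],
                    alt = ab[variant_offset + 1])
  }
  structure(
    list(variant = as.list(variant), ref_window = ref_window,
         alt_window = alt_window,
         flank = as.integer(variant_offset),
         variant_offset = as.integer(variant_offset)),
    class = "variant_windows"
  )
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Scan a window with a PWM and return the best variant-overlapping hit
#'
#' Scores every placement of the motif whose span covers the variant offset,
#' on the forward strand and on the reverse complement (reverse-strand
#' placements are reported in forward-window coordinates), and returns the
#' maximum-score hit. For a 51 bp window, an 11 bp motif and a central
#' variant this scores 11 offsets on each strand (22 placements). Ties are
#' broken to the + strand, then to the smaller offset, so output is
#' deterministic.
#'
#' @param pwm A `pwm` object.
#' @param window A/C/G/T string at least as long as the motif.
#' @param variant_offset 0-based position of the variant within the window.
#' @param ambig `"error"` (default) to reject non-ACGT bases, or `"skip"` to
#'   drop placements containing them.
#' @return An object of class `motif_hit`: `strand` ("+" or "-"), `offset`
#'   (0-based forward-strand start), `score` (log2), `efficiency`
#'   (`2^score`), `pvalue` (NA until filled by [motif_pvalue()]), and
#'   `n_placements` scored.
#' @export
scan_allele <- function(pwm, window, variant_offset, ambig = c("error", "skip")) {
  ambig <- match.arg(ambig)
  stopifnot(inherits(pwm, "pwm"))
  window <- toupper(window)
  L <- pwm$length
  W <- nchar(window)
  if (L > W) fm_stop("window (", W, " bp) shorter than motif (", L, " bp)")
  if (variant_offset < 0 || variant_offset >= W) {
    fm_stop("variant_offset ", variant_offset, " outside window")
  }
  offsets <- seq(max(0L, variant_offset - L + 1L), min(W - L, variant_offset))
  if (length(offsets) == 0) fm_stop("no motif placement covers the variant")

  hits <- list()
  for (o in offsets) {
    kmer <- substr(window, o + 1, o + L)
    if (grepl("[^ACGT]", kmer)) {
      if (ambig == "error") fm_stop("ambiguous base in placement at offset ", o)
      next
    }
    hits[[length(hits) + 1]] <- list(strand = "+", offset = o,
                                     score = score_kmer(pwm, kmer))
    hits[[length(hits) + 1]] <- list(strand = "-", offset = o,
                                     score = score_kmer(pwm, rev_comp(kmer)))
  }
  if (length(hits) == 0) fm_stop("all placements contained ambiguous bases")
  sc <- vapply(hits, `[[`, numeric(1), "score")
  st <- vapply(hits, `[[`, character(1), "strand")
  of <- vapply(hits, `[[`, numeric(1), "offset")
  best <- order(-sc, st != "+", of)[1]
  structure(
    list(strand = st[best], offset = as.integer(of[best]), score = sc[best],
         efficiency = 2^sc[best], pvalue = NA_real_,
         n_placements = length(hits)),
    class = "motif_hit"
  )
}

#' @export
print.motif_hit <- function(x, ...) {
  cat(sprintf("motif hit: strand %s, offset %d, score %.4f (efficiency %.4g)",
              x$strand, x$offset, x$score, x$efficiency))
  if (!is.na(x$pvalue)) cat(sprintf(", p = %.3g", x$pvalue))
  cat("\n")
  invisible(x)
}

#' Allele-aware binding report for a variant window pair
#'
#' Scans the reference-allele and alternate-allele windows independently
#' (their best placements may differ in offset and strand, as each allele's
#' best match is chosen separately), then reports:
#' \itemize{
#'   \item `efficiency_fold_change` = `2^(alt score - ref score)`, the ratio
#'     of predicted binding efficiencies (alt / ref);
#'   \item `favored_allele`, the allele with the higher best score, and
#'     `fold_change_favored`, the same ratio oriented so it is >= 1;
#'   \item when `pvalues = TRUE`, exact motif p-values for each allele's
#'     best score under the background score distribution, and
#'     `pvalue_fold_change` = `max(p_ref, p_alt) / min(p_ref, p_alt)` with
#'     the allele carrying the smaller p-value.
#' }
#'
#' @param pwm A `pwm` object.
#' @param pair A `variant_windows` object.
#' @param pvalues Compute exact score-distribution p-values (default TRUE).
#' @param grid_step Score grid for the exact distribution, log2 units.
#' @param dist Optional precomputed [score_distribution()] for `pwm`.
#' @param ambig Passed to [scan_allele()].
#' @return An object of class `allele_binding_report`; see
#'   [as.data.frame.allele_binding_report()] for the flat table layout.
#' @export
binding_report <- function(pwm, pair, pvalues = TRUE, grid_step = 0.001,
                           dist = NULL, ambig = "error") {
  stopifnot(inherits(pair, "variant_windows"))
  ref_hit <- scan_allele(pwm, pair$ref_window, pair$variant_offset, ambig)
  alt_hit <- scan_allele(pwm, pair$alt_window, pair$variant_offset, ambig)
  eff_fc <- 2^(alt_hit$score - ref_hit$score)
  favored <- if (alt_hit$score > ref_hit$score) "alt"
             else if (ref_hit$score > alt_hit$score) "ref" else "none"

  p_ref <- p_alt <- p_fc <- NA_real_
  p_favored <- NA_character_
  if (pvalues) {
    if (is.null(dist)) dist <- score_distribution(pwm, grid_step)
    p_ref <- motif_pvalue(dist, ref_hit$score)
    p_alt <- motif_pvalue(dist, alt_hit$score)
    ref_hit$pvalue <- p_ref
    alt_hit$pvalue <- p_alt
    p_fc <- max(p_ref, p_alt) / min(p_ref, p_alt)
    p_favored <- if (p_alt < p_ref) "alt" else if (p_ref < p_alt) "ref" else "none"
  }
  structure(
    list(
      motif_id = pwm$motif_id,
      variant_id = as.character(pair$variant$id %||% "snv"),
      ref_hit = ref_hit, alt_hit = alt_hit,
      efficiency_fold_change = eff_fc,
      fold_change_favored = max(eff_fc, 1 / eff_fc),
      favored_allele = favored,
      pvalue_ref = p_ref, pvalue_alt = p_alt,
      pvalue_fold_change = p_fc, pvalue_favored_allele = p_favored
    ),
    class = "allele_binding_report"
  )
}

#' P-value fold change between alleles
#'
#' Convenience wrapper around [binding_report()] returning the ratio of the
#' two alleles' best-hit motif p-values, `max(p_ref, p_alt) / min(...)`
#' (always >= 1), together with the favoured allele (the one with the
#' smaller p-value, i.e. the stronger predicted binding site).
#'
#' @inheritParams binding_report
#' @return List with `ratio`, `favored_allele`, `pvalue_ref`, `pvalue_alt`.
#' @export
pvalue_fold_change <- function(pwm, pair, grid_step = 0.001, dist = NULL) {
  rep <- binding_report(pwm, pair, pvalues = TRUE, grid_step = grid_step,
                        dist = dist)
  list(ratio = rep$pvalue_fold_change,
       favored_allele = rep$pvalue_favored_allele,
       pvalue_ref = rep$pvalue_ref, pvalue_alt = rep$pvalue_alt)
}

#' Flatten a binding report to a one-row data.frame
#'
#' @param x An `allele_binding_report`.
#' @param ... Unused.
#' @return One-row data.frame with columns `motif_id`, `variant_id`,
#'   `ref_score`, `alt_score`, `ref_strand`, `alt_strand`, `ref_offset`,
#'   `alt_offset`, `efficiency_fold_change`, `pvalue_ref`, `pvalue_alt`,
#'   `pvalue_fold_change`, `favored_allele`.
#' @export
as.data.frame.allele_binding_report <- function(x, ...) {
  data.frame(
    motif_id = x$motif_id, variant_id = x$variant_id,
    ref_score = x$ref_hit$score, alt_score = x$alt_hit$score,
    ref_strand = x$ref_hit$strand, alt_strand = x$alt_hit$strand,
    ref_offset = x$ref_hit$offset, alt_offset = x$alt_hit$offset,
    efficiency_fold_change = x$efficiency_fold_change,
    pvalue_ref = x$pvalue_ref, pvalue_alt = x$pvalue_alt,
    pvalue_fold_change = x$pvalue_fold_change,
    favored_allele = x$favored_allele,
    stringsAsFactors = FALSE
  )
}

#' @export
print.allele_binding_report <- function(x, ...) {
  cat(sprintf("Allele binding report: motif %s, variant %s\n",
              x$motif_id, x$variant_id))
  cat(sprintf("  ref: score %.4f (%s strand, offset %d)\n",
              x$ref_hit$score, x$ref_hit$strand, x$ref_hit$offset))
  cat(sprintf("  alt: score %.4f (%s strand, offset %d)\n",
              x$alt_hit$score, x$alt_hit$strand, x$alt_hit$offset))
  cat(sprintf("  efficiency fold change (alt/ref): %.4g (%.4g-fold favoring %s)\n",
              x$efficiency_fold_change, x$fold_change_favored, x$favored_allele))
  if (!is.na(x$pvalue_fold_change)) {
    cat(sprintf("  motif p-values: ref %.3g, alt %.3g (fold change %.4g, favoring %s)\n",
                x$pvalue_ref, x$pvalue_alt, x$pvalue_fold_change,
                x$pvalue_favored_allele))
  }
  invisible(x)
}

#' Write a motif scan report as TSV
#' @param reports A list of `allele_binding_report` objects (or a single one).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_motif_report <- function(reports, path) {
  if (inherits(reports, "allele_binding_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
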