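#' Annotate variants with accessible-chromatin peak overlap
#'
#' Flags each variant that falls inside a peak interval. Variants use
#' 1-based positions (VCF convention) and peaks 0-based half-open intervals
#' (BED convention); a variant at position `p` is inside peak `[s, e)` iff
#' `s <= p - 1 < e`, so a variant on a peak's closed start is inside and one
#' on its exclusive end is outside. Overlap is computed with
#' GenomicRanges; multiple overlapping peaks set the flag once, with the
#' peak names collected when available. Input order is preserved.
#'
#' @param variants Data.frame of variants (`chrom`, `pos`, `id`, ...).
#' @param peaks Data.frame of intervals (`chrom`, `start`, `end`, optional
#'   `name`); an empty peak set marks every variant `in_peak = FALSE`.
#' @param quiet Suppress the summary message.
#' @return The input data.frame with logical column `in_peak` (and
#'   `peak_names` when peaks are named) appended.
#' @export
intersect_variants_peaks <- function(variants, peaks, quiet = FALSE) {
  out <- variants
  if (is.null(peaks) || nrow(peaks) == 0) {
    out$in_peak <- rep(FALSE, nrow(out))
  } else {
    v_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, width = 1))
    p_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(peaks$start + 1, peaks$end))
    ov <- GenomicRanges::findOverlaps(v_gr, p_gr)
    out$in_peak <- seq_len(nrow(variants)) %in% S4Vectors::queryHits(ov)
    if (!is.null(peaks$name)) {
      nm <- tapply(peaks$name[S4Vectors::subjectHits(ov)],
                   factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(variants))),
                   paste, collapse = ",")
      out$peak_names <- as.character(ifelse(is.na(nm), "", nm))
    }
  }
  if (!quiet) {
    message(sprintf("%d of %d variant(s) map to peaks", sum(out$in_peak),
                    nrow(out)))
  }
  out
}

#' Filter a variant block by LD with the lead variant
#'
#' Keeps variants whose squared correlation (r2) with the block's lead
#' variant is at least `r2_min`, preserving input order.
#'
#' @param variants Data.frame with an `r2_to_lead` column on every record.
#' @param r2_min Minimum r2 in [0, 1].
#' @return Filtered data.frame.
#' @export
filter_by_ld <- function(variants, r2_min) {
  if (is.null(variants$r2_to_lead) || anyNA(variants$r2_to_lead)) {
    missing_ids <- if (is.null(variants$r2_to_lead)) variants$id
                   else variants$id[is.na(variants$r2_to_lead)]
    fm_stop("r2_to_lead missing for variant(s): ",
            paste(missing_ids, collapse = ", "))
  }
  if (!is.numeric(r2_min) || r2_min < 0 || r2_min > 1) {
    fm_stop("r2_min must be in [0, 1]")
  }
  out <- variants[variants$r2_to_lead >= r2_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned mean coverage over a region
#'
#' Computes per-base read depth from read intervals (0-based half-open,
#' e.g. from a BED of aligned fragments), then averages it within
#' consecutive windows of `bin_size` bases tiling the region — the
#' "normalized read depth averaged over N bp windows" display convention
#' for accessibility and ChIP tracks (500 bp for locus overviews, 50 bp for
#' fine structure). `cpm` normalization scales depth by
#' `1e6 / library_size`.
#'
#' @param reads Data.frame of read intervals (`chrom`, `start`, `end`).
#' @param region One interval (list or one-row data.frame with `chrom`,
#'   `start`, `end`) to tile.
#' @param bin_size Window width in bases (>= 1).
#' @param normalization `"raw"` (mean depth) or `"cpm"`.
#' @param library_size Total mapped reads in the library; required for
#'   `"cpm"`.
#' @return A `coverage_track`: data.frame of bins (`chrom`, `start`, `end`,
#'   `value`) with attributes `bin_size` and `normalization`. Every bin has
#'   width `bin_size` except possibly the last.
#' @export
bin_coverage <- function(reads, region, bin_size,
                         normalization = c("raw", "cpm"), library_size = NULL) {
  normalization <- match.arg(normalization)
  region <- as.list(region)
  if (!is_count(bin_size) || bin_size < 1) fm_stop("bin_size must be an integer >= 1")
  if (region$start < 0 || region$start >= region$end) fm_stop("malformed region")
  if (normalization == "cpm") {
    if (is.null(library_size) || library_size == 0) {
      fm_stop("cpm normalization requires a non-zero library_size")
    }
  }
  reads <- reads[reads$chrom == region$chrom, , drop = FALSE]
  rlen <- region$end - region$start
  depth <- numeric(rlen)
  if (nrow(reads) > 0) {
    ir <- IRanges::IRanges(start = reads$start + 1, end = reads$end)
    cov <- IRanges::coverage(ir, width = max(region$end, max(reads$end)))
    depth <- as.numeric(cov)[(region$start + 1):region$end]
  }
  bin_starts <- seq(region$start, region$end - 1, by = bin_size)
  bin_ends <- pmin(bin_starts + bin_size, region$end)
  value <- vapply(seq_along(bin_starts), function(i) {
    mean(depth[(bin_starts[i] - region$start + 1):(bin_ends[i] - region$start)])
  }, numeric(1))
  if (normalization == "cpm") value <- value * 1e6 / library_size
  structure(
    data.frame(chrom = region$chrom, start = as.integer(bin_starts),
               end = as.integer(bin_ends), value = value,
               stringsAsFactors = FALSE),
    bin_size = bin_size, normalization = normalization,
    class = c("coverage_track", "data.frame")
  )
}

#' Prioritize an LD block against accessible chromatin
#'
#' The fine-mapping reduction step: restrict an associated variant block to
#' high-LD members, then to those overlapping accessibility peaks.
#'
#' @param variants Variant data.frame with `r2_to_lead`.
#' @param peaks Peak intervals.
#' @param r2_min LD threshold (required; the block definition depends on it).
#' @param quiet Passed through.
#' @return List with `annotated` (high-LD variants with `in_peak`) and
#'   `prioritized` (the in-peak subset).
#' @export
prioritize_variants <- function(variants, peaks, r2_min, quiet = FALSE) {
  block <- filter_by_ld(variants, r2_min)
  annotated <- intersect_variants_peaks(block, peaks, quiet = quiet)
  list(annotated = annotated,
       prioritized = annotated[annotated$in_peak, , drop = FALSE])
}
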