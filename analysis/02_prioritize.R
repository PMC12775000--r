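#!/usr/bin/env Rscript
# Stage 1 — reduce the LD block to candidates in accessible chromatin.
# Filters the 17-variant block by r2 with the lead variant, intersects with
# the peak set, and writes a binned coverage track of the peak intervals
# (the 500 bp-window normalized-depth display convention) for context.

library(finemotif)

variants <- read_variants("results/fixture/variants.tsv", dialect = "tsv")
peaks <- read_bed("results/fixture/peaks.bed")

res <- prioritize_variants(variants, peaks, r2_min = 0.8, quiet = TRUE)
write.table(res$annotated, "results/prioritized.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d of %d block variants pass r2 >= 0.8; %d map to peaks: %s\n",
            nrow(res$annotated), nrow(variants), nrow(res$prioritized),
            paste(res$prioritized$id, collapse = ", ")))

# coverage context: treat each peak as a stack of idealized fragments
region <- list(chrom = variants$chrom[1],
               start = min(peaks$start) - 500, end = max(peaks$end) + 500)
track <- bin_coverage(peaks, region, bin_size = 500)
write_bedgraph(track, "results/peak_coverage_500bp.bedgraph")
cat(sprintf("coverage track: %d bins of 500 bp over %s:%d-%d\n",
            nrow(track), region$chrom, region$start, region$end))
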