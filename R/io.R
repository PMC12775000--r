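#' Read biallelic SNVs from a minimal VCF or TSV
#'
#' Reads a variant table and keeps one record per biallelic single-nucleotide
#' row. The `vcf` dialect uses the first five mandatory columns (CHROM, POS,
#' ID, REF, ALT; `##` meta lines and the `#CHROM` header are skipped). The
#' `tsv` dialect expects a header with columns `chrom`, `pos`, `id`, `ref`,
#' `alt` and optionally `r2_to_lead` (squared LD with the block's lead
#' variant).
#'
#' Multi-allelic rows (comma in ALT) and indels (REF or ALT longer than one
#' base) are skipped with a warning; the number skipped is recorded in the
#' `"skipped"` attribute so that `rows in = records out + skipped`.
#'
#' @param path Path to the file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return A data.frame with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt` and, when present, `r2_to_lead`; attribute `skipped` counts
#'   dropped rows.
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fm_stop("variant file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  if (dialect == "vcf") {
    lines <- lines[!startsWith(lines, "##")]
    if (length(lines) > 0 && startsWith(lines[1], "#")) lines <- lines[-1]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      return(empty_variant_table())
    }
    fields <- strsplit(lines, "\\s+")
    short <- vapply(fields, length, integer(1)) < 5
    if (any(short)) {
      fm_stop("parse error: VCF row ", which(short)[1],
              " has fewer than the 5 mandatory columns (CHROM POS ID REF ALT)")
    }
    df <- data.frame(
      chrom = vapply(fields, `[[`, character(1), 1),
      pos   = vapply(fields, `[[`, character(1), 2),
      id    = vapply(fields, `[[`, character(1), 3),
      ref   = toupper(vapply(fields, `[[`, character(1), 4)),
      alt   = toupper(vapply(fields, `[[`, character(1), 5)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    names(df) <- tolower(names(df))
    need <- c("chrom", "pos", "id", "ref", "alt")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols) > 0) {
      fm_stop("parse error: TSV is missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
    }
    df <- df[, c(need, intersect("r2_to_lead", names(df)))]
    df$ref <- toupper(df$ref)
    df$alt <- toupper(df$alt)
  }

  pos_num <- suppressWarnings(as.numeric(df$pos))
  bad_pos <- is.na(pos_num) | pos_num != floor(pos_num)
  if (any(bad_pos)) {
    fm_stop("parse error: non-integer POS '", df$pos[which(bad_pos)[1]],
            "' at data row ", which(bad_pos)[1])
  }
  df$pos <- as.integer(pos_num)
  if (any(df$pos < 1)) fm_stop("validation error: POS must be >= 1")

  if ("r2_to_lead" %in% names(df)) {
    df$r2_to_lead <- as.numeric(df$r2_to_lead)
    bad_r2 <- !is.na(df$r2_to_lead) & (df$r2_to_lead < 0 | df$r2_to_lead > 1)
    if (any(bad_r2)) fm_stop("validation error: r2_to_lead outside [0, 1]")
  }

  # keep biallelic SNVs only
  snv <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    warning(sprintf("skipped %d non-SNV or multi-allelic row(s) (ids: %s)",
                    n_skip, paste(df$id[!snv], collapse = ", ")), call. = FALSE)
  }
  out <- df[snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- n_skip
  out
}

empty_variant_table <- function() {
  out <- data.frame(chrom = character(), pos = integer(), id = character(),
                    ref = character(), alt = character(),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- 0L
  out
}

#' Write variants as a minimal VCF
#'
#' @param variants Data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT")
  body <- sprintf("%s\t%d\t%s\t%s\t%s", variants$chrom, variants$pos,
                  variants$id, variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Reads BED3 or better (chrom, start, end, then optional name and score);
#' coordinates are 0-based half-open as in the BED standard.
#'
#' @param path Path to the BED file.
#' @return A data.frame with columns `chrom`, `start`, `end` and, when
#'   present, `name` and `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) fm_stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\\s+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 3)) {
    fm_stop("parse error at line ", lineno[which(nf < 3)[1]],
            ": BED requires at least chrom, start, end")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad_num <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad_num)) {
    fm_stop("parse error at line ", lineno[which(bad_num)[1]],
            ": non-integer start/end")
  }
  if (any(start < 0)) {
    fm_stop("validation error at line ", lineno[which(start < 0)[1]],
            ": negative start")
  }
  bad <- start >= end
  if (any(bad)) {
    fm_stop("validation error at line ", lineno[which(bad)[1]],
            ": start >= end (intervals are 0-based half-open)")
  }
  out <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, character(1), 4)
  if (all(nf >= 5)) out$score <- as.numeric(vapply(fields, `[[`, character(1), 5))
  out
}

#' Write intervals as BED
#' @param intervals Data.frame with `chrom`, `start`, `end`, optional `name`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- sprintf("%s\t%d\t%d", intervals$chrom, intervals$start, intervals$end)
  if (!is.null(intervals$name)) cols <- paste0(cols, "\t", intervals$name)
  writeLines(cols, path)
  invisible(path)
}

#' Write and read bedGraph tracks
#'
#' A bedGraph line is `chrom start end value` with 0-based half-open
#' coordinates. Values are written with 17 significant digits so that a
#' write/read round trip reproduces them bit-exactly.
#'
#' @param track Data.frame with columns `chrom`, `start`, `end`, `value`
#'   (e.g. a coverage track from [bin_coverage()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  writeLines(sprintf("%s\t%d\t%d\t%.17g", track$chrom, track$start,
                     track$end, track$value), path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) fm_stop("bedGraph file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer", "numeric"))
  bad <- df$start >= df$end
  if (any(bad)) {
    fm_stop("validation error at line ", which(bad)[1], ": start >= end")
  }
  df
}

#' Read a per-sample allelic read-count table
#'
#' Expects a TSV with header `sample_id`, `ref_count`, `alt_count`; counts
#' must be non-negative integers and sample ids unique. Zero-depth samples
#' (ref + alt = 0) are kept but flagged in a `zero_depth` column so that
#' downstream tests can exclude them explicitly.
#'
#' @param path Path to the TSV.
#' @return Data.frame with columns `sample_id`, `ref_count`, `alt_count`,
#'   `zero_depth`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) fm_stop("count file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sample_id", "ref_count", "alt_count")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    fm_stop("parse error: count table is missing column(s): ",
            paste(missing_cols, collapse = ", "))
  }
  for (col in c("ref_count", "alt_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) fm_stop("validation error: non-numeric ", col)
    frac <- v != floor(v)
    if (any(frac)) {
      fm_stop("validation error: fractional ", col, " for sample ",
              df$sample_id[which(frac)[1]])
    }
    if (any(v < 0)) fm_stop("validation error: negative ", col)
    df[[col]] <- as.integer(v)
  }
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    fm_stop("validation error: duplicate sample_id: ",
            paste(unique(df$sample_id[dup]), collapse = ", "))
  }
  df <- df[, need]
  df$zero_depth <- df$ref_count + df$alt_count == 0
  df
}

#' Write a per-sample allelic read-count table
#' @param counts Data.frame with `sample_id`, `ref_count`, `alt_count`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts[, c("sample_id", "ref_count", "alt_count")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
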