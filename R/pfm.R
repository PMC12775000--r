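#' Position frequency matrix
#'
#' Constructs a position frequency matrix (PFM) object holding per-position
#' nucleotide counts (or frequencies) for a transcription-factor binding
#' motif, in fixed A, C, G, T row order.
#'
#' @param counts Numeric 4 x L matrix of non-negative counts or frequencies,
#'   rows ordered A, C, G, T.
#' @param motif_id Character scalar naming the motif (e.g. a JASPAR
#'   accession).
#'
#' @return An object of class `pfm` with fields `motif_id`, `counts`,
#'   `length` and `is_frequency` (`TRUE` when every column sums to 1 within
#'   1e-6, i.e. the matrix is already a frequency matrix).
#' @export
#' @examples
#' m <- matrix(c(8, 1, 1, 0), nrow = 4, ncol = 3,
#'             dimnames = list(c("A", "C", "G", "T"), NULL))
#' pfm(m, "toy")
pfm <- function(counts, motif_id = "motif") {
  if (!is.matrix(counts) || nrow(counts) != 4) {
    fm_stop("PFM counts must be a 4-row matrix (A, C, G, T)")
  }
  if (ncol(counts) < 1) fm_stop("PFM must have at least one position")
  if (any(!is.finite(counts))) fm_stop("PFM contains non-finite values")
  if (any(counts < 0)) fm_stop("PFM contains negative values")
  cs <- colSums(counts)
  if (any(cs <= 0)) {
    fm_stop("PFM column ", which(cs <= 0)[1], " has no positive entry")
  }
  rownames(counts) <- BASES
  structure(
    list(
      motif_id = as.character(motif_id),
      counts = counts,
      length = ncol(counts),
      is_frequency = all(abs(cs - 1) <= 1e-6)
    ),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("Position %s matrix '%s' (%d bp)\n",
              if (x$is_frequency) "frequency" else "count",
              x$motif_id, x$length))
  print(round(x$counts, 3))
  invisible(x)
}

#' Read a motif matrix from JASPAR or HOCOMOCO text
#'
#' Parses the common plain-text motif matrix dialects:
#' \itemize{
#'   \item JASPAR bracketed: an optional `>ID name` header, then rows
#'     `A [ 3 10 ... ]` (also accepted with `|` or no delimiter);
#'   \item plain labelled: four whitespace-separated rows starting with the
#'     base letter;
#'   \item HOCOMOCO PCM layout: a `>ID` header followed by one row per motif
#'     position with four columns in A, C, G, T order (the matrix is
#'     transposed relative to JASPAR).
#' }
#' Matrices must be counts or frequencies; HOCOMOCO weight (log-odds) files
#' with negative entries are rejected, since downstream conversion expects
#' counts.
#'
#' @param path Path to the motif file.
#' @return A [pfm] object; `is_frequency` is set when all columns sum to 1
#'   within 1e-6.
#' @export
read_pfm <- function(path) {
  if (!file.exists(path)) fm_stop("motif file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) fm_stop("parse error: empty motif file: ", path)

  motif_id <- sub("\\.[^.]*$", "", basename(path))
  if (startsWith(lines[1], ">")) {
    motif_id <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  if (length(lines) == 0) fm_stop("parse error: motif file has a header but no matrix rows")

  labelled <- grepl("^[ACGTacgt]\\b", lines) | grepl("^[ACGTacgt]\\s*[\\[|]", lines)
  if (all(labelled[seq_len(min(4, length(lines)))]) && length(lines) >= 4) {
    rows <- parse_labelled_rows(lines[1:4])
  } else {
    rows <- parse_positional_rows(lines)
  }
  pfm(rows, motif_id = motif_id)
}

# JASPAR-style: one row per base, label first, brackets/pipes optional.
parse_labelled_rows <- function(lines) {
  vals <- vector("list", 4)
  names(vals) <- BASES
  lens <- integer(4)
  for (i in 1:4) {
    base <- toupper(substr(lines[i], 1, 1))
    body <- gsub("[][|]", " ", sub("^[ACGTacgt]", "", lines[i]))
    v <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (length(v) == 0 || anyNA(v)) {
      fm_stop("parse error in row ", base, ": non-numeric matrix entries")
    }
    vals[[base]] <- v
    lens[i] <- length(v)
  }
  if (any(vapply(vals, is.null, logical(1)))) {
    fm_stop("parse error: expected one row each for A, C, G, T")
  }
  ref_len <- length(vals[["A"]])
  for (base in BASES) {
    if (length(vals[[base]]) != ref_len) {
      fm_stop("parse error: row ", base, " has ", length(vals[[base]]),
              " columns; expected ", ref_len)
    }
  }
  if (any(unlist(vals) < 0)) fm_stop("validation error: negative matrix values")
  do.call(rbind, vals[BASES])
}

# HOCOMOCO-style: one row per position, four columns A C G T.
parse_positional_rows <- function(lines) {
  vals <- lapply(lines, function(l) {
    suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
  })
  n_col <- vapply(vals, length, integer(1))
  if (any(vapply(vals, anyNA, logical(1)))) {
    fm_stop("parse error: non-numeric matrix entries (and rows are not base-labelled)")
  }
  if (any(n_col != 4)) {
    fm_stop("parse error: positional row ", which(n_col != 4)[1],
            " has ", n_col[n_col != 4][1], " columns; expected 4 (A C G T)")
  }
  m <- t(do.call(rbind, vals))
  if (any(m < 0)) {
    fm_stop("validation error: negative matrix values (weight matrices are not accepted)")
  }
  m
}

#' Write a motif matrix in JASPAR bracketed format
#'
#' @param x A [pfm] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pfm <- function(x, path) {
  stopifnot(inherits(x, "pfm"))
  fmt <- function(v) paste(sprintf("%.10g", v), collapse = " ")
  lines <- c(
    paste0(">", x$motif_id),
    vapply(BASES, function(b) sprintf("%s [ %s ]", b, fmt(x$counts[b, ])), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
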