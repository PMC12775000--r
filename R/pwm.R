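#' Convert a position frequency matrix to a log-odds position weight matrix
#'
#' Per-position nucleotide frequencies are formed as
#' `(count + pseudocount) / (column_total + 4 * pseudocount)` and converted
#' to log2 odds against a background composition:
#' `log2(frequency / background)`. For a matrix already holding frequencies
#' the column totals are ~1, so with `pseudocount = 0` the frequencies pass
#' through and only the background division applies.
#'
#' A zero count (or zero frequency) with `pseudocount = 0` would give a
#' log-odds of minus infinity and is rejected with an error naming the
#' offending position.
#'
#' @param x A [pfm] object.
#' @param pseudocount Non-negative value added to every cell before
#'   normalization; default 0.01.
#' @param background Background nucleotide frequencies (A, C, G, T), summing
#'   to 1; default uniform 0.25.
#' @return An object of class `pwm` with fields `motif_id`, `length`,
#'   `log_odds` (4 x L, log2 units), `background` and `pseudocount`.
#' @export
#' @examples
#' p <- pfm(matrix(1, 4, 3, dimnames = list(c("A","C","G","T"), NULL)))
#' pfm_to_pwm(p, pseudocount = 0)$log_odds  # all zero
pfm_to_pwm <- function(x, pseudocount = 0.01, background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount < 0) {
    fm_stop("pseudocount must be a single non-negative number")
  }
  if (length(background) != 4 || any(background <= 0)) {
    fm_stop("background must be 4 positive frequencies (A, C, G, T)")
  }
  if (abs(sum(background) - 1) > 1e-9) {
    fm_stop("background frequencies must sum to 1")
  }
  if (pseudocount == 0 && any(x$counts == 0)) {
    idx <- which(x$counts == 0, arr.ind = TRUE)[1, ]
    fm_stop("zero count at position ", idx[2], ", base ", BASES[idx[1]],
            " with pseudocount 0 would give -Inf log-odds; use pseudocount > 0")
  }
  col_tot <- colSums(x$counts)
  freq <- sweep(x$counts + pseudocount, 2, col_tot + 4 * pseudocount, "/")
  log_odds <- log2(freq / background)
  rownames(log_odds) <- BASES
  structure(
    list(motif_id = x$motif_id, length = x$length, log_odds = log_odds,
         background = background, pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d bp, log2 odds, pseudocount %g)\n",
              x$motif_id, x$length, x$pseudocount))
  print(round(x$log_odds, 3))
  invisible(x)
}

#' Score a k-mer against a position weight matrix
#'
#' The score of a sequence `s` of motif length is the sum over positions of
#' the position-specific log2 odds, `sum_i log2(M[s_i, i] / b[s_i])`; it is
#' additive over positions. `2^score` is the predicted relative binding
#' efficiency.
#'
#' @param pwm A `pwm` object from [pfm_to_pwm()].
#' @param kmer Character scalar of length `pwm$length` over A/C/G/T.
#'   Ambiguous bases (e.g. N) are an error.
#' @return The log2 log-odds score (numeric scalar).
#' @export
score_kmer <- function(pwm, kmer) {
  stopifnot(inherits(pwm, "pwm"))
  kmer <- toupper(kmer)
  if (nchar(kmer) != pwm$length) {
    fm_stop("k-mer length ", nchar(kmer), " does not match motif length ",
            pwm$length)
  }
  idx <- match(strsplit(kmer, "")[[1]], BASES)
  if (anyNA(idx)) fm_stop("ambiguous or invalid base in k-mer: ", kmer)
  sum(pwm$log_odds[cbind(idx, seq_len(pwm$length))])
}
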