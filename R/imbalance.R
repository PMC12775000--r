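#' Exact two-sided binomial test for allelic imbalance
#'
#' Tests whether `k` reference reads out of `n` total are consistent with a
#' null reference-allele proportion `null_p` (0.5 for a balanced diploid or
#' tetraploid heterozygote; 1/3 or 2/3 for the two triploid heterozygous
#' genotypes, see [ploidy_null()]).
#'
#' Two two-sided conventions are offered:
#' \describe{
#'   \item{`minlike`}{the sum of `Binom(j; n, null_p)` over all outcomes `j`
#'     whose point probability is no larger than that of `k` (with a 1e-7
#'     relative slack to avoid float inclusion flips). This matches the
#'     convention of common exact-test implementations.}
#'   \item{`doubled`}{`2 * min(P(X <= k), P(X >= k))`, capped at 1.}
#' }
#' For `null_p = 0.5` the two agree. Point probabilities are handled in log
#' space so extreme imbalances (p-values around 1e-45 and below) remain
#' representable rather than underflowing to zero.
#'
#' @param k Reference-allele read count (0 <= k <= n).
#' @param n Total read count (>= 1).
#' @param null_p Null reference proportion in (0, 1).
#' @param method `"minlike"` (default) or `"doubled"`.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' binom_two_sided(10, 10, 0.5)  # 2 * 2^-10 = 0.001953125
binom_two_sided <- function(k, n, null_p, method = c("minlike", "doubled")) {
  method <- match.arg(method)
  if (!is_count(n) || n < 1) fm_stop("n must be an integer >= 1")
  if (!is_count(k) || k < 0 || k > n) fm_stop("k must be an integer in [0, n]")
  if (!is.numeric(null_p) || null_p <= 0 || null_p >= 1) {
    fm_stop("null_p must lie strictly between 0 and 1")
  }
  if (method == "minlike") {
    ld <- stats::dbinom(0:n, n, null_p, log = TRUE)
    sel <- ld <= ld[k + 1] + log1p(1e-7)
    p <- exp(logsumexp(ld[sel]))
  } else {
    lo <- stats::pbinom(k, n, null_p, log.p = TRUE)
    hi <- stats::pbinom(k - 1, n, null_p, lower.tail = FALSE, log.p = TRUE)
    p <- 2 * exp(min(lo, hi))
  }
  min(p, 1)
}

#' Null reference-allele proportion from copy numbers
#'
#' For a heterozygous site with `total_copies` chromosomal copies of which
#' `ref_copies` carry the reference allele, the expected reference read
#' fraction absent allelic imbalance is `ref_copies / total_copies`:
#' 1/2 for a diploid het, 1/3 or 2/3 for the two triploid heterozygous
#' genotypes, 1/2 for a balanced (2+2) tetraploid het.
#'
#' @param total_copies Total copy number at the locus (>= 2).
#' @param ref_copies Copies carrying the reference allele; must satisfy
#'   `1 <= ref_copies <= total_copies - 1` (a homozygous configuration has
#'   no imbalance test and is an error).
#' @return The null proportion as a numeric scalar.
#' @export
#' @examples
#' ploidy_null(3, 1)  # 1/3
#' ploidy_null(4, 2)  # 0.5
ploidy_null <- function(total_copies, ref_copies) {
  if (!is_count(total_copies) || total_copies < 2) {
    fm_stop("total_copies must be an integer >= 2")
  }
  if (!is_count(ref_copies)) fm_stop("ref_copies must be an integer")
  if (ref_copies < 1 || ref_copies > total_copies - 1) {
    fm_stop("homozygous configuration (ref_copies = ", ref_copies, " of ",
            total_copies, "): no imbalance test is defined")
  }
  ref_copies / total_copies
}

imbalance_row <- function(sample_id, k, n, null_p, method) {
  frac <- if (n > 0) k / n else NA_real_
  direction <- if (n == 0) "none"
               else if (frac > null_p) "ref-biased"
               else if (frac < null_p) "alt-biased" else "none"
  data.frame(
    sample = sample_id, k = as.integer(k), n = as.integer(n),
    fraction = frac, null_p = null_p,
    pvalue = binom_two_sided(k, n, null_p, method),
    direction = direction, method = method,
    stringsAsFactors = FALSE
  )
}

#' Per-sample and pooled allelic-imbalance tests
#'
#' Runs the exact two-sided binomial test on each sample's reference/
#' alternate read counts and on the counts pooled (summed) across samples —
#' the pooled test treats all donors' reads as one library, as is done when
#' calling imbalance "across all donors". Zero-depth samples are dropped
#' with a warning and never counted as evidence. Per-donor heterogeneity is
#' summarized as the maximum pairwise difference in reference fractions,
#' but not tested.
#'
#' @param samples Data.frame with columns `sample_id`, `ref_count`,
#'   `alt_count` (e.g. from [read_counts()]).
#' @param null_p Null reference proportion (see [ploidy_null()]).
#' @param method Passed to [binom_two_sided()].
#' @return List with `per_sample` (one test row per retained sample),
#'   `pooled` (one row on the summed counts), `pooled_fraction`, and
#'   `heterogeneity` (max pairwise fraction difference; 0 with one sample).
#' @export
test_samples <- function(samples, null_p, method = "minlike") {
  need <- c("sample_id", "ref_count", "alt_count")
  if (!all(need %in% names(samples))) {
    fm_stop("samples must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(samples) == 0) fm_stop("empty sample table")
  depth <- samples$ref_count + samples$alt_count
  if (any(depth == 0)) {
    warning(sprintf("dropping %d zero-depth sample(s): %s", sum(depth == 0),
                    paste(samples$sample_id[depth == 0], collapse = ", ")),
            call. = FALSE)
    samples <- samples[depth > 0, , drop = FALSE]
  }
  if (nrow(samples) == 0) fm_stop("all samples have zero depth")

  per_sample <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    imbalance_row(samples$sample_id[i], samples$ref_count[i],
                  samples$ref_count[i] + samples$alt_count[i], null_p, method)
  }))
  k_tot <- sum(samples$ref_count)
  n_tot <- k_tot + sum(samples$alt_count)
  pooled <- imbalance_row("pooled", k_tot, n_tot, null_p, method)
  fr <- per_sample$fraction
  list(per_sample = per_sample, pooled = pooled,
       pooled_fraction = k_tot / n_tot,
       heterogeneity = if (length(fr) > 1) max(stats::dist(fr)) else 0)
}

#' Imbalance significance across a set of null proportions
#'
#' Re-tests the same counts under each candidate null — e.g. `{1/2, 1/3,
#' 2/3}` to show an imbalance call is robust to diploid/tetraploid-balanced
#' versus either triploid heterozygous genotype.
#'
#' @param k,n Reference count and total count.
#' @param null_ps Numeric vector of null proportions; an empty vector gives
#'   an empty result.
#' @param method Passed to [binom_two_sided()].
#' @param sample_id Label for the report rows.
#' @return Data.frame with one test row per null proportion.
#' @export
null_sensitivity <- function(k, n, null_ps, method = "minlike",
                             sample_id = "counts") {
  rows <- lapply(null_ps, function(p0) imbalance_row(sample_id, k, n, p0, method))
  if (length(rows) == 0) {
    return(imbalance_row("x", 0, 1, 0.5, "minlike")[0, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an imbalance report as TSV
#' @param result Result list from [test_samples()] or a data.frame of test rows.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_imbalance_report <- function(result, path) {
  df <- if (is.data.frame(result)) result
        else rbind(result$per_sample, result$pooled)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
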