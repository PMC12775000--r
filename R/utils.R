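# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

fm_stop <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == floor(x)

#' @keywords internal
check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    fm_stop(what, " contains non-ACGT characters: ",
            paste(unique(unlist(strsplit(gsub("[ACGT]", "", x[bad]), ""))), collapse = ", "))
  }
  invisible(x)
}

# log(sum(exp(x))) without intermediate under/overflow; exp() at the end may
# still be subnormal for extreme tails, which is intended behaviour.
logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# chromosome-name normalization ("chr1" vs "1"); default is to leave names
# untouched and require consistency across inputs.
norm_chrom <- function(x, mode = c("none", "strip", "add")) {
  mode <- match.arg(mode)
  switch(mode,
    none  = x,
    strip = sub("^chr", "", x),
    add   = ifelse(grepl("^chr", x), x, paste0("chr", x))
  )
}
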