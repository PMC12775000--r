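# Independent brute-force oracles used to cross-check the dynamic-programming
# score distribution and the exact binomial test. These deliberately avoid
# the code paths they verify.

# All 4^L sequences enumerated explicitly; scores accumulated per-position on
# the same floor grid the DP uses, masses from the background composition.
enum_score_distribution <- function(pwm, grid_step = 0.001) {
  L <- pwm$length
  units <- matrix(as.integer(floor(pwm$log_odds / grid_step + 1e-9)), nrow = 4)
  grids <- rep(list(1:4), L)
  combos <- as.matrix(expand.grid(grids))
  score <- integer(nrow(combos))
  prob <- rep(1, nrow(combos))
  for (j in seq_len(L)) {
    score <- score + units[combos[, j], j]
    prob <- prob * pwm$background[combos[, j]]
  }
  agg <- tapply(prob, score, sum)
  list(units = as.integer(names(agg)), mass = as.numeric(agg))
}

# Total variation distance between a score_distribution object and the
# enumeration oracle, on the union of supports.
tv_against_enum <- function(dist, oracle) {
  all_units <- sort(union(dist$units, oracle$units))
  m1 <- m2 <- numeric(length(all_units))
  m1[match(dist$units, all_units)] <- dist$mass
  m2[match(oracle$units, all_units)] <- oracle$mass
  0.5 * sum(abs(m1 - m2))
}

# Exact minlike two-sided binomial p-value by explicit outcome enumeration.
enum_binom_minlike <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Random count PFM with strictly positive frequencies after pseudocount.
random_pfm <- function(L, max_count = 50) {
  m <- matrix(sample(0:max_count, 4 * L, replace = TRUE), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  bad <- colSums(m) == 0
  m[1, bad] <- 1
  pfm(m, motif_id = sprintf("rand_L%d", L))
}

rev_comp_str <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

random_window <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                   collapse = "")
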