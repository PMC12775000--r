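# Exact two-sided binomial tests with ploidy-aware nulls.

test_that("closed forms: extreme and modal outcomes", {
  expect_identical(binom_two_sided(10, 10, 0.5), 0.001953125)  # 2 * 2^-10
  expect_identical(binom_two_sided(10, 10, 0.5, method = "doubled"), 0.001953125)
  expect_equal(binom_two_sided(5, 10, 0.5), 1)
})

test_that("minlike p-values equal exhaustive enumeration for small n", {
  for (n in c(1, 3, 7, 12)) {
    for (p0 in c(0.5, 1 / 3, 2 / 3)) {
      for (k in 0:n) {
        expect_equal(binom_two_sided(k, n, p0),
                     min(enum_binom_minlike(k, n, p0), 1),
                     tolerance = 1e-12,
                     label = sprintf("k=%d n=%d p0=%.3f", k, n, p0))
      }
    }
  }
})

test_that("minlike agrees with the standard exact-test implementation", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    p0 <- sample(c(0.5, 1 / 3, 2 / 3, 0.1), 1)
    expect_equal(binom_two_sided(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-10,
                 label = sprintf("k=%d n=%d p0=%.3f", k, n, p0))
  }
})

test_that("symmetry at null 0.5 and monotone significance within tails", {
  for (n in c(9, 24, 101)) {
    for (k in 0:n) {
      expect_equal(binom_two_sided(k, n, 0.5), binom_two_sided(n - k, n, 0.5),
                   tolerance = 1e-13)
    }
  }
  n <- 60
  for (p0 in c(0.5, 1 / 3)) {
    ps <- vapply(0:n, function(k) binom_two_sided(k, n, p0), numeric(1))
    mode_k <- floor(n * p0)
    expect_true(all(diff(ps[1:(mode_k + 1)]) >= -1e-13))          # lower tail rises
    expect_true(all(diff(ps[(mode_k + 2):(n + 1)]) <= 1e-13))     # upper tail falls
  }
})

test_that("log-space stability at extreme imbalance", {
  p <- binom_two_sided(150, 150, 0.5)
  expect_gt(p, 0)
  expect_equal(p, 2 * 2^-150, tolerance = 1e-9)
  # severe imbalance stays representable under every ploidy null
  for (p0 in c(0.5, 1 / 3, 2 / 3)) {
    pv <- binom_two_sided(100, 100, p0)
    expect_gt(pv, 0)
    expect_lt(pv, 1e-15)
  }
})

test_that("doubled convention caps at 1 and matches minlike at p0 = 0.5", {
  for (k in c(0, 3, 10, 20)) {
    expect_equal(binom_two_sided(k, 20, 0.5, method = "doubled"),
                 binom_two_sided(k, 20, 0.5), tolerance = 1e-12)
  }
  expect_lte(binom_two_sided(7, 21, 1 / 3, method = "doubled"), 1)
})

test_that("input validation", {
  expect_error(binom_two_sided(5, 0, 0.5), "n must be")
  expect_error(binom_two_sided(11, 10, 0.5), "k must be")
  expect_error(binom_two_sided(1, 10, 0), "null_p")
})

test_that("ploidy_null covers diploid, triploid and tetraploid configurations", {
  expect_equal(ploidy_null(2, 1), 0.5)
  expect_equal(ploidy_null(3, 1), 1 / 3)
  expect_equal(ploidy_null(3, 2), 2 / 3)
  expect_equal(ploidy_null(4, 2), 0.5)
  expect_error(ploidy_null(3, 0), "homozygous")
  expect_error(ploidy_null(3, 3), "homozygous")
})

test_that("test_samples: per-sample tests, pooled test, zero-depth handling", {
  all_ref <- data.frame(sample_id = paste0("d", 1:7),
                        ref_count = rep(6L, 7), alt_count = rep(0L, 7))
  res <- test_samples(all_ref, 0.5)
  expect_true(all(res$per_sample$direction == "ref-biased"))
  expect_equal(res$pooled$pvalue, binom_two_sided(42, 42, 0.5), tolerance = 1e-12)
  expect_equal(res$heterogeneity, 0)

  balanced <- data.frame(sample_id = paste0("d", 1:7),
                         ref_count = rep(3L, 7), alt_count = rep(3L, 7))
  res_b <- test_samples(balanced, 0.5)
  expect_equal(res_b$pooled$pvalue, 1)
  expect_equal(res_b$pooled$direction, "none")

  with_zero <- rbind(all_ref, data.frame(sample_id = "dz", ref_count = 0L,
                                         alt_count = 0L))
  expect_warning(res_z <- test_samples(with_zero, 0.5), "zero-depth")
  expect_equal(nrow(res_z$per_sample), 7)

  all_zero <- data.frame(sample_id = "dz", ref_count = 0L, alt_count = 0L)
  expect_warning(expect_error(test_samples(all_zero, 0.5), "zero depth"))
})

test_that("pooled test detects a strong planted imbalance across donors", {
  cfg <- sim_config(seed = 31, true_ref_fraction = 0.8, depth_mean = 50)
  counts <- gen_allelic_counts(cfg)
  res <- test_samples(counts, 0.5)
  expect_equal(res$pooled$direction, "ref-biased")
  expect_lt(res$pooled$pvalue, 1e-6)
})

test_that("null_sensitivity sweeps ploidy nulls as a robustness check", {
  res <- null_sensitivity(100, 100, c(0.5, 1 / 3, 2 / 3))
  expect_equal(nrow(res), 3)
  expect_true(all(res$pvalue < 1e-15))
  expect_true(all(res$direction == "ref-biased"))

  # balanced counts: exactly null at 0.5, significant departure from 1/3
  res_b <- null_sensitivity(30, 60, c(0.5, 1 / 3))
  expect_equal(res_b$pvalue[1], 1)
  expect_lt(res_b$pvalue[2], 1)

  expect_equal(nrow(null_sensitivity(5, 10, numeric(0))), 0)
})

test_that("imbalance report writes per-sample plus pooled rows", {
  counts <- gen_allelic_counts(sim_config(seed = 3))
  res <- test_samples(counts, 0.5)
  f <- tempfile(fileext = ".tsv")
  write_imbalance_report(res, f)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$sample[8], "pooled")
})
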