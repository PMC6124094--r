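test_that("Hudson per-locus components match hand arithmetic and limits", {
  h <- hudson_fst_locus(0.3, 100, 0.6, 50)
  expect_equal(h$numerator, 0.09 - 0.21 / 99 - 0.24 / 49, tolerance = 1e-12)
  expect_equal(h$denominator, 0.3 * 0.4 + 0.6 * 0.7, tolerance = 1e-12)

  h1 <- hudson_fst_locus(1, 50, 0, 50)       # fixed difference
  expect_equal(h1$numerator, 1)
  expect_equal(h1$denominator, 1)

  h0 <- hudson_fst_locus(0.5, 1e7, 0.5, 1e7) # large-sample null
  expect_lt(abs(h0$numerator), 1e-6)
  expect_equal(h0$denominator, 0.5)

  expect_error(hudson_fst_locus(0.5, 1, 0.5, 10), ">= 2")
  expect_error(hudson_fst_locus(1.2, 10, 0.5, 10), "\\[0, 1\\]")
})

test_that("all-fixed-different loci give Fst exactly 1", {
  counts <- data.frame(locus = rep(1:5, 2),
                       pop = rep(c("A", "B"), each = 5),
                       derived_count = c(rep(20L, 5), rep(0L, 5)),
                       total = 20L)
  expect_equal(fst_pair(counts, "A", "B"), 1)
})

test_that("Balding-Nichols simulation recovers the target differentiation", {
  x <- simulate_snp_counts(0.1, n_loci = 5000, samples_per_pop = 100, seed = 31)
  expect_lt(abs(fst_pair(x, "pop1", "pop2") - 0.1), 0.02)

  x0 <- simulate_snp_counts(0, n_loci = 50000, samples_per_pop = 100, seed = 32)
  expect_lt(abs(fst_pair(x0, "pop1", "pop2")), 0.01)
})

test_that("Fst is label-symmetric and the matrix well formed", {
  x <- simulate_snp_counts(0.05, n_loci = 800, samples_per_pop = 60,
                           n_pops = 3, seed = 33)
  expect_identical(fst_pair(x, "pop1", "pop2"), fst_pair(x, "pop2", "pop1"))
  m <- fst_matrix(x)
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_true(all(is.finite(m)))
})

test_that("region-structured SNP counts give larger Fst between regions", {
  rm_ <- c(a1 = "A", a2 = "A", b1 = "B")
  x <- simulate_snp_counts(0.1, n_loci = 4000, samples_per_pop = 100,
                           n_pops = 3, pop_labels = names(rm_),
                           region_map = rm_, F_within = 0.01, seed = 35)
  within <- fst_pair(x, "a1", "a2")
  between <- mean(c(fst_pair(x, "a1", "b1"), fst_pair(x, "a2", "b1")))
  expect_lt(within, between)
  expect_lt(abs(within - 0.01), 0.02)
  expect_error(simulate_snp_counts(0.1, 10, region_map = c(pop1 = "A")),
               "missing from 'region_map'")
})

test_that("SNP simulation flags monomorphic loci and validates inputs", {
  x <- simulate_snp_counts(0.3, n_loci = 300, samples_per_pop = 10, seed = 34,
                           ancestral_freq = function(n) rep(0.05, n))
  mono <- attr(x, "monomorphic")
  expect_length(mono, 300)
  expect_true(any(mono))   # rare ancestral allele: some loci all-zero
  # flagged loci really are monomorphic everywhere
  wide <- matrix(x$derived_count, ncol = 2)
  expect_true(all(apply(wide[mono, , drop = FALSE], 1,
                        function(z) all(z == 0) || all(z == 10))))
  expect_error(simulate_snp_counts(1, 10), "\\[0, 1\\)")
  expect_error(simulate_snp_counts(-0.1, 10), "\\[0, 1\\)")
  expect_error(simulate_snp_counts(0.1, 0), "n_loci")
  # determinism
  expect_identical(simulate_snp_counts(0.2, 50, 30, seed = 5),
                   simulate_snp_counts(0.2, 50, 30, seed = 5))
})
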