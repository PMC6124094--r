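test_that("TN93 distance: identity, saturation, and oracle agreement", {
  expect_identical(tn93_distance(rep("A", 200), rep("A", 200)), 0)
  s1 <- rep(c("A", "C", "G", "T"), 25)
  s2 <- rep(c("G", "T", "A", "C"), 25)  # every site differs
  expect_error(tn93_distance(s1, s2), class = "mtskyline_saturation")
  expect_error(tn93_distance(c("A", "C"), c("A", "C", "G")), "equal length")

  # agreement with an independent implementation on simulated data
  tr <- ape::read.tree(text = "(a:150000,b:150000);")
  sc <- partition_scheme()
  aln <- simulate_alignment(tr, sc, seed = 21)
  mine <- tn93_distance(aln$PC3[1, ], aln$PC3[2, ])
  oracle <- ape::dist.dna(ape::as.DNAbin(aln$PC3), model = "TN93")[1]
  expect_equal(mine, unname(oracle), tolerance = 1e-9)
})

test_that("TN93 distance recovers the simulated divergence on average", {
  sc <- partition_scheme()
  part <- sc$PC3
  T_half <- 0.01 / (2 * part$rate)
  tr <- ape::read.tree(text = sprintf("(a:%.8f,b:%.8f);", T_half, T_half))
  # single-rate variant of the partition so the plain distance is unbiased
  sc1 <- partition_scheme(gamma_shape = 1e6)
  set.seed(22)
  ds <- replicate(40, {
    aln <- simulate_alignment(tr, sc1)
    tn93_distance(aln$PC3[1, ], aln$PC3[2, ], base_freqs = part$base_freqs)
  })
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 0.01), 3 * se)
})

test_that("UPGMA recovers an exactly ultrametric 4-taxon matrix, beating all rivals", {
  tr <- ultra4()
  D <- ape::cophenetic.phylo(tr)
  est <- upgma_tree(D)
  expect_true(ape::is.ultrametric(est, tol = 1e-8))
  expect_equal(sort(unname(ape::branching.times(est))),
               sort(unname(ape::branching.times(tr))), tolerance = 1e-10)
  # brute force: the recovered topology fits the matrix better than the two
  # alternative quartet resolutions (zero cophenetic error vs positive)
  err <- function(t) sum((ape::cophenetic.phylo(t)[rownames(D), colnames(D)] - D)^2)
  expect_lt(err(est), 1e-16)
  alt1 <- ape::read.tree(text = "((A:1500,C:1500):1500,(B:2500,D:2500):500);")
  alt2 <- ape::read.tree(text = "((A:1500,D:1500):1500,(B:2500,C:2500):500);")
  expect_gt(min(err(alt1), err(alt2)), 1e5)
})

test_that("identical sequences collapse the clock tree to age zero", {
  m <- matrix("A", nrow = 3, ncol = 60,
              dimnames = list(c("a", "b", "c"), NULL))
  aln <- structure(list(HVS = m, rtRNA = m, PC1PC2 = m, PC3 = m),
                   class = "mt_alignment",
                   scheme = partition_scheme(c(60, 60, 60, 60)))
  ct <- build_clock_tree(aln)
  expect_lt(max(ape::branching.times(ct)), 1e-9)
})

test_that("clock trees recover the true root age within 30% in most replicates", {
  sc <- partition_scheme()
  ok <- 0
  n_rep <- 30
  for (i in seq_len(n_rep)) {
    tr <- sample_coalescent_tree(10, const_demog(5000), seed = 3000 + i)
    aln <- simulate_alignment(tr, sc, seed = 4000 + i)
    ct <- build_clock_tree(aln)
    rt <- max(ape::branching.times(tr))
    re <- max(ape::branching.times(ct))
    if (abs(re - rt) / rt < 0.30) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.8)
})
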