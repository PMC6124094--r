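test_that("degenerate trees give identical sequences", {
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  aln <- simulate_alignment(tr0, partition_scheme(), seed = 1)
  for (m in aln) {
    expect_equal(m["a", ], m["b", ], ignore_attr = TRUE)
    expect_equal(m["a", ], m["c", ], ignore_attr = TRUE)
  }

  # fully invariant partitions also change nothing, whatever the branch lengths
  sc <- partition_scheme(prop_invariant = c(1 - 1e-12, 1 - 1e-12, 1 - 1e-12, 1 - 1e-12))
  sc <- lapply(sc, function(p) { p$prop_invariant <- 0.999999; p })
  class(sc) <- "partition_scheme"
  tr <- ape::read.tree(text = "(a:1e6,b:1e6);")
  aln2 <- simulate_alignment(tr, sc, seed = 2)
  frac_diff <- mean(unlist(Map(function(m) m[1, ] != m[2, ], aln2)))
  expect_lt(frac_diff, 0.01)
})

test_that("two-taxon divergence matches the TN93 matrix-exponential expectation", {
  sc <- partition_scheme()
  part <- sc$PC3                       # +G only, no invariant class
  T_half <- 0.01 / (2 * part$rate)     # so path divergence is 0.01 subs/site
  tr <- ape::read.tree(text = sprintf("(a:%.8f,b:%.8f);", T_half, T_half))

  # oracle: expected mismatch probability from P(2rT) per gamma category
  Q <- mtskyline:::.tn93_q(part$base_freqs, part$kappa1, part$kappa2)
  e <- eigen(Q)
  rates <- mtskyline:::.discrete_gamma_rates(part$gamma_shape, 4)
  p_mismatch <- 0
  for (m in rates) {
    P <- Re(e$vectors %*% diag(exp(e$values * 0.01 * m)) %*% solve(e$vectors))
    p_mismatch <- p_mismatch + 0.25 * sum(part$base_freqs * (1 - diag(P)))
  }

  set.seed(3)
  obs <- replicate(20, {
    aln <- simulate_alignment(tr, sc)
    mean(aln$PC3[1, ] != aln$PC3[2, ])
  })
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - p_mismatch), 3 * se)
})

test_that("site patterns on a two-taxon tree follow analytic transition probabilities", {
  # single-category check: one partition, no gamma spread (shape huge), no +I
  sc <- partition_scheme(gamma_shape = 1e6, prop_invariant = c(0, 0, 0, 0))
  part <- sc$HVS
  d_branch <- 0.05 / part$rate / 2
  tr <- ape::read.tree(text = sprintf("(a:%.6f,b:%.6f);", d_branch, d_branch))
  aln <- simulate_alignment(tr, sc, seed = 4)
  # analytic joint pattern probabilities pi_i P_ij(2rT) for the AA and AG cells
  Q <- mtskyline:::.tn93_q(part$base_freqs, part$kappa1, part$kappa2)
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * 0.05)) %*% solve(e$vectors))
  joint <- part$base_freqs * P
  n <- part$n_sites
  for (cell in list(c(1, 1), c(1, 3), c(2, 4))) {
    ab <- c("A", "C", "G", "T")[cell]
    obs <- mean(aln$HVS[1, ] == ab[1] & aln$HVS[2, ] == ab[2])
    pe <- joint[cell[1], cell[2]]
    expect_lt(abs(obs - pe), 3 * sqrt(pe * (1 - pe) / n) + 1e-3)
  }
})

test_that("alignment simulation is seed-deterministic", {
  tr <- sample_coalescent_tree(5, const_demog(2000), seed = 7)
  a1 <- simulate_alignment(tr, partition_scheme(), seed = 11)
  a2 <- simulate_alignment(tr, partition_scheme(), seed = 11)
  expect_identical(a1, a2)
  expect_error(simulate_alignment(NULL, partition_scheme()), "phylo")
})

test_that("subsampling is reproducible, size-checked, and identity at full size", {
  tr <- sample_coalescent_tree(10, const_demog(2000), seed = 8)
  aln <- simulate_alignment(tr, partition_scheme(c(50, 50, 50, 50)), seed = 9)
  s1 <- subsample_alignment(aln, 4, seed = 1)
  s2 <- subsample_alignment(aln, 4, seed = 1)
  expect_identical(s1, s2)
  expect_identical(sort(rownames(subsample_alignment(aln, 10, seed = 2)[[1]])),
                   sort(rownames(aln[[1]])))
  expect_error(subsample_alignment(aln, 11), "cannot subsample")
  # different seeds give different subsets with overwhelming probability
  subs <- vapply(1:5, function(s)
    paste(rownames(subsample_alignment(aln, 4, seed = s)[[1]]), collapse = ","), "")
  expect_gt(length(unique(subs)), 1)
})

test_that("the default scheme carries the four calibrated mtDNA rate classes", {
  sc <- partition_scheme()
  expect_equal(vapply(sc, `[[`, 0, "rate"),
               c(HVS = 31.434e-8, rtRNA = 1.007e-8, PC1PC2 = 0.756e-8,
                 PC3 = 3.323e-8))
  expect_equal(unname(vapply(sc, `[[`, 0L, "gamma_categories")), rep(4L, 4))
  expect_equal(unname(vapply(sc, `[[`, 0, "prop_invariant")), c(0.1, 0.1, 0.1, 0))
  expect_equal(sum(sc$HVS$base_freqs), 1)
  expect_error(partition_scheme(base_freqs = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})
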