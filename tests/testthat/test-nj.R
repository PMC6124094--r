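test_that("three taxa give the closed-form star lengths", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  lb <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "b")]
  lc <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "c")]
  expect_equal(la, (3 + 5 - 6) / 2)
  expect_equal(lb, (3 + 6 - 5) / 2)
  expect_equal(lc, (5 + 6 - 3) / 2)
})

test_that("an additive 4-taxon matrix is recovered exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(tr)
  est <- nj_tree(D)
  # brute force: among the three quartet splits, only AB|CD fits additively
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  path_AB <- ape::cophenetic.phylo(est)["A", "B"]
  expect_equal(path_AB, 3)
})

test_that("random additive matrices reproduce the generating tree against an oracle", {
  set.seed(81)
  for (r in 1:50) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
    D <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(D)
    oracle <- ape::nj(stats::as.dist(D))
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(oracle)), 0)
    expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(tr)), 0)
    # branch lengths reproduce the additive distances
    expect_equal(ape::cophenetic.phylo(mine)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("two well-separated blocks are split and inputs validated", {
  labs <- c("a1", "a2", "a3", "b1", "b2", "b3")
  D <- matrix(1, 6, 6, dimnames = list(labs, labs))
  D[1:3, 1:3] <- 0.01; D[4:6, 4:6] <- 0.01
  diag(D) <- 0
  tr <- nj_tree(D)
  # the split a1a2a3 | b1b2b3 exists: pruning either block leaves a cherry
  coph <- ape::cophenetic.phylo(tr)
  within_a <- max(coph[c("a1","a2","a3"), c("a1","a2","a3")])
  between <- min(coph[c("a1","a2","a3"), c("b1","b2","b3")])
  expect_lt(within_a, between)

  bad <- D; bad[1, 2] <- 9
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
  expect_true(all(tr$edge.length >= 0))
})

test_that("negative branch lengths are clamped with the deficit moved", {
  # classic NJ negative-length case
  D <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 0.2,
                9, 10, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  # total tree length is preserved relative to the unclamped solution
  oracle <- ape::nj(stats::as.dist(D))
  expect_equal(sum(tr$edge.length), sum(oracle$edge.length), tolerance = 1e-9)
})
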