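# Sequence simulation down a genealogy under the partitioned TN93+I+G model.

# Transition probability matrix P(d) = exp(Q d) via eigendecomposition.
.pmat <- function(eig, d) {
  P <- eig$vectors %*% (exp(eig$values * d) * eig$inv)
  P[P < 0] <- 0       # clip tiny negative round-off
  P / rowSums(P)
}

# Simulate one partition: character matrix (tips x sites) over A,C,G,T.
# `tree` must already be in cladewise order so each edge's parent node has
# been assigned before the edge is visited.
.simulate_partition <- function(tree, part) {
  n_tip <- length(tree$tip.label)
  ns <- part$n_sites
  bf <- part$base_freqs
  Q <- .tn93_q(bf, part$kappa1, part$kappa2)
  e <- eigen(Q)
  V <- Re(e$vectors)
  eig <- list(values = Re(e$values), vectors = V, inv = solve(V))

  # site rate multipliers: invariant class w.p. prop_invariant, otherwise one
  # of the equal-weight discrete-gamma categories (multipliers mean one among
  # variable sites)
  gr <- .discrete_gamma_rates(part$gamma_shape, part$gamma_categories)
  cat_rates <- c(0, gr)
  cat_probs <- c(part$prop_invariant,
                 rep((1 - part$prop_invariant) / part$gamma_categories,
                     part$gamma_categories))
  site_cat <- sample.int(length(cat_rates), ns, replace = TRUE, prob = cat_probs)

  states <- matrix(0L, nrow = n_tip + tree$Nnode, ncol = ns)
  root <- n_tip + 1L
  states[root, ] <- sample.int(4L, ns, replace = TRUE, prob = bf)

  edge <- tree$edge
  elen <- tree$edge.length
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1L]; chi <- edge[k, 2L]
    u <- stats::runif(ns)
    child <- states[par, ]          # default: unchanged (rate-0 / zero length)
    for (ci in seq_along(cat_rates)) {
      d <- part$rate * cat_rates[ci] * elen[k]
      if (d == 0) next
      idx <- which(site_cat == ci)
      if (!length(idx)) next
      CP <- t(apply(.pmat(eig, d), 1, cumsum))
      ps <- states[par, idx]
      ui <- u[idx]
      child[idx] <- 1L + (ui > CP[cbind(ps, 1L)]) + (ui > CP[cbind(ps, 2L)]) +
        (ui > CP[cbind(ps, 3L)])
    }
    states[chi, ] <- child
  }
  m <- matrix(c("A", "C", "G", "T")[states[seq_len(n_tip), , drop = FALSE]],
              nrow = n_tip)
  rownames(m) <- tree$tip.label
  m
}

#' Simulate a partitioned mtDNA alignment down a genealogy
#'
#' Evolves each partition independently down the (ultrametric, years-scaled)
#' genealogy under TN93 with discrete-gamma rate heterogeneity and an
#' invariant-site class: a site is invariant with probability
#' `prop_invariant`, otherwise it draws one of the equal-probability gamma
#' categories (multipliers mean one among variable sites). The expected
#' number of substitutions on a branch is `rate * branch_years *
#' site_multiplier`. Root states are drawn from the partition's base
#' frequencies.
#'
#' @param tree A `"phylo"` genealogy with branch lengths in years.
#' @param scheme A [partition_scheme()].
#' @param seed Optional integer seed.
#' @return An object of class `"mt_alignment"`: a named list of character
#'   matrices (`A/C/G/T`, rows = sequences) with the scheme attached as
#'   attribute `"scheme"`.
#' @examples
#' tr <- sample_coalescent_tree(4, demography(0, 2000), seed = 1)
#' aln <- simulate_alignment(tr, partition_scheme(), seed = 1)
#' sapply(aln, ncol)
#' @export
simulate_alignment <- function(tree, scheme = partition_scheme(), seed = NULL) {
  if (is.null(tree) || !inherits(tree, "phylo") || length(tree$tip.label) < 1)
    stop("'tree' must be a nonempty phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  stopifnot(inherits(scheme, "partition_scheme"))
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")
  parts <- lapply(scheme, function(p) .simulate_partition(tree, p))
  structure(parts, class = "mt_alignment", scheme = scheme)
}

#' @export
print.mt_alignment <- function(x, ...) {
  cat("mtDNA alignment:", nrow(x[[1]]), "sequences;",
      paste(sprintf("%s=%d", names(x), vapply(x, ncol, 0L)), collapse = ", "),
      "sites\n")
  invisible(x)
}

#' Randomly subsample sequences from an alignment
#'
#' Selects `n` sequences uniformly at random without replacement across all
#' partitions jointly, the usual protocol of equalising sample sizes
#' across populations (85 here) before demographic inference.
#'
#' @param aln An `"mt_alignment"`.
#' @param n Number of sequences to keep (default 85).
#' @param seed Optional integer seed; the subset is reproducible given it.
#' @return An `"mt_alignment"` with `n` sequences.
#' @export
subsample_alignment <- function(aln, n = 85, seed = NULL) {
  stopifnot(inherits(aln, "mt_alignment"))
  ids <- rownames(aln[[1]])
  if (n > length(ids))
    stop("cannot subsample ", n, " from ", length(ids), " sequences")
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample(ids, n))
  structure(lapply(aln, function(m) m[keep, , drop = FALSE]),
            class = "mt_alignment", scheme = attr(aln, "scheme"))
}
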