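# Hudson's Fst estimator, combined across loci as a ratio of averages.

#' Per-locus components of Hudson's Fst estimator
#'
#' For sample allele frequencies `p1`, `p2` estimated from `n1`, `n2`
#' sampled alleles, returns the numerator and denominator of the
#' finite-sample Hudson estimator:
#' \deqn{\hat N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1},
#'   \qquad \hat D = p_1(1-p_2) + p_2(1-p_1).}
#' No per-locus division is performed; loci are meant to be combined as
#' a ratio of averages (see [fst_pair()]).
#'
#' @param p1,p2 Sample frequencies in `[0, 1]` (vectorised).
#' @param n1,n2 Numbers of sampled alleles (`>= 2`).
#' @return A list with numeric vectors `numerator` and `denominator`.
#' @export
hudson_fst_locus <- function(p1, n1, p2, n2) {
  if (any(n1 <= 1) || any(n2 <= 1)) stop("allele sample sizes must be >= 2")
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) stop("frequencies must be in [0, 1]")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den)
}

# Extract a per-locus (count, total) matrix for one population from the long
# counts table.
.pop_counts <- function(counts, pop) {
  x <- counts[counts$pop == pop, , drop = FALSE]
  if (!nrow(x)) stop("population '", pop, "' not found in counts table")
  x <- x[order(x$locus), , drop = FALSE]
  x
}

#' Hudson Fst between two populations, ratio of averages across loci
#'
#' Combines the per-locus components of [hudson_fst_locus()] as
#' `sum(numerators) / sum(denominators)` over all loci with a positive
#' denominator (loci monomorphic across the pair carry no information and
#' are skipped). The estimate is reported unclamped: slightly negative
#' values are legitimate sampling noise under weak differentiation.
#'
#' @param counts A counts data frame as produced by [simulate_snp_counts()]
#'   or read from TSV: columns `locus`, `pop`, `derived_count`, `total`.
#' @param popA,popB Population labels present in `counts$pop`.
#' @return A single Fst value.
#' @export
fst_pair <- function(counts, popA, popB) {
  a <- .pop_counts(counts, popA)
  b <- .pop_counts(counts, popB)
  if (nrow(a) != nrow(b) || any(a$locus != b$locus))
    stop("loci are not aligned between '", popA, "' and '", popB, "'")
  p1 <- a$derived_count / a$total
  p2 <- b$derived_count / b$total
  h <- hudson_fst_locus(p1, a$total, p2, b$total)
  use <- h$denominator > 0
  if (!any(use)) stop("no polymorphic loci usable for the pair ",
                      popA, " / ", popB)
  sum(h$numerator[use]) / sum(h$denominator[use])
}

#' Pairwise Hudson Fst matrix over all populations in a counts table
#'
#' @param counts Counts data frame (`locus`, `pop`, `derived_count`,
#'   `total`).
#' @return A symmetric matrix with zero diagonal, labelled by population.
#' @export
fst_matrix <- function(counts) {
  pops <- unique(counts$pop)
  if (length(pops) < 2) stop("need at least 2 populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) {
    if (j <= i) next
    m[i, j] <- m[j, i] <- fst_pair(counts, pops[i], pops[j])
  }
  m
}
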