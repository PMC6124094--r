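# TN93 distances and UPGMA clock-tree construction.

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Standard TN93 distance computed from the observed proportions of
#' purine transitions (A<->G), pyrimidine transitions (C<->T) and
#' transversions. Sites containing anything other than A/C/G/T in either
#' sequence are masked. If `prop_invariant > 0`, an invariant-site
#' correction is applied: the observed proportions are rescaled to the
#' variable fraction and the resulting distance scaled back, consistent
#' with a zero-rate invariant class.
#'
#' @param seq1,seq2 Character vectors of equal length over A/C/G/T (case
#'   insensitive).
#' @param base_freqs Equilibrium base frequencies (A, C, G, T); `NULL`
#'   (default) estimates them from the two sequences pooled.
#' @param prop_invariant Proportion of invariant sites assumed by the model
#'   (default 0 = plain TN93).
#' @return Distance in substitutions/site. Identical sequences give exactly
#'   0. If the divergence is beyond what TN93 can invert (a logarithm
#'   argument is nonpositive) an error of class `"mtskyline_saturation"` is
#'   thrown, distinct from ordinary input errors.
#' @export
tn93_distance <- function(seq1, seq2, base_freqs = NULL, prop_invariant = 0) {
  s1 <- toupper(as.character(seq1)); s2 <- toupper(as.character(seq2))
  if (length(s1) != length(s2)) stop("sequences must have equal length")
  ok <- s1 %in% c("A", "C", "G", "T") & s2 %in% c("A", "C", "G", "T")
  s1 <- s1[ok]; s2 <- s2[ok]
  n <- length(s1)
  if (n == 0) stop("no comparable sites after masking")
  if (all(s1 == s2)) return(0)

  if (is.null(base_freqs)) {
    tab <- table(factor(c(s1, s2), levels = c("A", "C", "G", "T")))
    base_freqs <- as.numeric(tab) / sum(tab)
    if (any(base_freqs == 0)) base_freqs <- (base_freqs + 1e-6) / sum(base_freqs + 1e-6)
  }
  names(base_freqs) <- c("A", "C", "G", "T")

  is_pur <- function(x) x == "A" | x == "G"
  diff <- s1 != s2
  P1 <- sum(diff & is_pur(s1) & is_pur(s2)) / n            # A<->G
  P2 <- sum(diff & !is_pur(s1) & !is_pur(s2)) / n          # C<->T
  Q <- sum(diff & (is_pur(s1) != is_pur(s2))) / n          # transversions

  pI <- prop_invariant
  if (pI < 0 || pI >= 1) stop("'prop_invariant' must be in [0, 1)")
  if (pI > 0) { P1 <- P1 / (1 - pI); P2 <- P2 / (1 - pI); Q <- Q / (1 - pI) }

  pA <- base_freqs["A"]; pC <- base_freqs["C"]
  pG <- base_freqs["G"]; pT <- base_freqs["T"]
  pR <- pA + pG; pY <- pC + pT

  w1 <- 1 - pR * P1 / (2 * pA * pG) - Q / (2 * pR)
  w2 <- 1 - pY * P2 / (2 * pC * pT) - Q / (2 * pY)
  w3 <- 1 - Q / (2 * pR * pY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0)
    stop(structure(class = c("mtskyline_saturation", "error", "condition"),
                   list(message = "TN93 distance saturated (log argument <= 0)",
                        call = sys.call(-1))))
  a1 <- -log(w1); a2 <- -log(w2); b <- -log(w3)
  d <- (2 * pA * pG / pR) * (a1 - pY * b) +
       (2 * pC * pT / pY) * (a2 - pR * b) +
       2 * pR * pY * b
  unname(if (pI > 0) (1 - pI) * d else d)
}

# Pairwise divergence-time matrix (years of path length, i.e. 2T for a pair
# whose ancestor is T years back) for one partition: TN93 distance with the
# partition's invariant-site correction, divided by rate (1 - pI). `rate` is
# the rate of the variable-site process (mean multiplier one), so the
# alignment-wide expected divergence over a path of 2T years is
# 2 r T (1 - pI); node ages come out as half the UPGMA heights.
.partition_time_matrix <- function(m, part) {
  ids <- rownames(m)
  n <- length(ids)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- tryCatch(
      tn93_distance(m[i, ], m[j, ], base_freqs = part$base_freqs,
                    prop_invariant = part$prop_invariant),
      mtskyline_saturation = function(e) NA_real_)
    if (is.na(d)) sat <- c(sat, paste(ids[i], ids[j], sep = "/"))
    D[i, j] <- D[j, i] <- d / (part$rate * (1 - part$prop_invariant))
  }
  list(time = D, saturated = sat)
}

#' Build an ultrametric clock tree from a partitioned alignment
#'
#' A fast point-genealogy builder standing in for full Bayesian tree
#' inference: per partition, pairwise TN93 distances (with the partition's
#' invariant-site correction) are converted to pair divergence times via
#' `t_MRCA = d / (2 rate (1 - prop_invariant))`; partitions are averaged
#' with precision weights proportional to `n_sites * rate` (partitions
#' accumulating more substitutions estimate time more precisely); UPGMA
#' (average-linkage clustering) of the year-scaled path distances then
#' yields an ultrametric tree whose node ages are half the cluster heights.
#'
#' @param aln An `"mt_alignment"`.
#' @param scheme A [partition_scheme()]; defaults to the scheme attached to
#'   `aln`.
#' @return An ultrametric `"phylo"` tree with branch lengths in years.
#' @export
build_clock_tree <- function(aln, scheme = attr(aln, "scheme")) {
  stopifnot(inherits(aln, "mt_alignment"))
  if (is.null(scheme)) stop("no partition scheme supplied or attached")
  if (nrow(aln[[1]]) < 2) stop("need at least 2 sequences")
  ws <- vapply(scheme, function(p) p$n_sites * p$rate, 0)
  ws <- ws / sum(ws)
  acc <- NULL
  sat <- character(0)
  for (k in seq_along(scheme)) {
    r <- .partition_time_matrix(aln[[k]], scheme[[k]])
    sat <- union(sat, r$saturated)
    acc <- if (is.null(acc)) ws[k] * r$time else acc + ws[k] * r$time
  }
  if (length(sat))
    stop("TN93 saturation in pair(s): ", paste(sat, collapse = ", "))
  upgma_tree(acc)
}

#' UPGMA tree from a matrix of pairwise divergence times
#'
#' Average-linkage clustering of a symmetric matrix of pairwise divergence
#' times (twice the node ages); the returned tree is ultrametric with node
#' ages equal to half the cluster heights. On a matrix that is exactly
#' ultrametric the generating topology and node ages are recovered exactly.
#'
#' @param D Symmetric numeric matrix with zero diagonal and row/col names.
#' @return An ultrametric `"phylo"` tree.
#' @export
upgma_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)))) stop("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # as.phylo.hclust places nodes at height/2, i.e. ages on the time scale
  ape::as.phylo(hc)
}
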