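#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining with the standard Q-criterion. Two
#' determinism conventions are fixed because published trees rarely state
#' them: Q-ties are broken toward the lexicographically smallest (sorted)
#' label pair — an internal node inherits the smallest leaf label in its
#' subtree for this purpose — and a negative branch length is clamped to
#' zero with the deficit moved to its sister branch so path lengths are
#' preserved.
#'
#' @param dist Symmetric numeric matrix with zero diagonal, unique row/col
#'   labels, `n >= 3` (e.g. an Fst or lambda matrix).
#' @return An unrooted `"phylo"` tree with nonnegative branch lengths.
#' @export
nj_tree <- function(dist) {
  D <- unname(as.matrix(dist))
  n <- nrow(D)
  labs <- rownames(as.matrix(dist))
  if (is.null(labs)) labs <- paste0("x", seq_len(n))
  if (n < 3) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D), check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("diagonal must be zero")
  if (anyDuplicated(labs)) stop("duplicate labels")

  frag <- labs      # newick fragment per active node
  tb <- labs        # tie-break key: smallest leaf label in the subtree
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + abs(qmin) * 1e-12 + 1e-300, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(s) {
      p <- sort(c(tb[cand[s, 1]], tb[cand[s, 2]]))
      paste(p, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]

    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)

    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], bi, frag[j], bj)
    new_tb <- min(tb[i], tb[j])
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], new_frag)
    tb <- c(tb[keep], new_tb)
  }
  # final three nodes: closed-form star lengths
  a <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  b <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  c3 <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  ln <- c(a, b, c3)
  for (k in 1:3) if (ln[k] < 0) {
    sis <- which.min(replace(ln, k, Inf))
    ln[sis] <- ln[sis] + ln[k]
    ln[k] <- 0
  }
  ln <- pmax(ln, 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], ln[1], frag[2], ln[2], frag[3], ln[3])
  ape::read.tree(text = txt)
}
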