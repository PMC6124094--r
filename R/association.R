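#' Association between profile similarity and genetic distance
#'
#' Tests whether demographic-profile distance (lambda) increases with
#' genetic differentiation (Fst) across population pairs: Spearman
#' correlation over the \eqn{n(n-1)/2} pairs, with significance from a
#' Mantel permutation test (matrix entries are not independent, so the
#' permutation null is the honest one; the plain pairwise correlation is
#' reported alongside for transparency). Optionally tags each pair as
#' within- or between-region given a region map.
#'
#' @param lam Lambda similarity matrix (symmetric, labelled).
#' @param fst Fst matrix with the same labels (any order).
#' @param n_permutations Mantel permutations (default 9999).
#' @param regions Optional named character vector mapping population label
#'   to region label.
#' @param seed Optional integer seed for the permutation test.
#' @return A list with `correlation` (Spearman rho), `mantel_p`
#'   (one-sided permutation p-value), and `pairs`, a data frame
#'   (`popA`, `popB`, `lambda`, `fst`, and `within_region` when a region map
#'   is given).
#' @export
profile_fst_association <- function(lam, fst, n_permutations = 9999,
                                    regions = NULL, seed = NULL) {
  lam <- as.matrix(lam); fst <- as.matrix(fst)
  labs <- rownames(lam)
  if (is.null(labs) || is.null(rownames(fst)))
    stop("both matrices must carry labels")
  if (!setequal(labs, rownames(fst)))
    stop("matrix labels do not match")
  fst <- fst[labs, labs]

  ut <- which(upper.tri(lam), arr.ind = TRUE)
  pairs <- data.frame(popA = labs[ut[, 1]], popB = labs[ut[, 2]],
                      lambda = lam[ut], fst = fst[ut],
                      stringsAsFactors = FALSE)
  if (!is.null(regions)) {
    miss <- setdiff(labs, names(regions))
    if (length(miss))
      stop("populations missing from the region map: ",
           paste(miss, collapse = ", "))
    pairs$within_region <- regions[pairs$popA] == regions[pairs$popB]
    rownames(pairs) <- NULL
  }

  if (!is.null(seed)) set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(lam), stats::as.dist(fst),
                      method = "spearman", permutations = n_permutations)
  list(correlation = unname(mt$statistic), mantel_p = unname(mt$signif),
       pairs = pairs)
}
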