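#' Simulate differentiated SNP allele counts (Balding-Nichols model)
#'
#' Generates biallelic allele counts for several populations that share an
#' ancestral allele frequency per locus. Given differentiation `F`, each
#' population's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral `p` (so its variance
#' is `F p (1-p)`), and observed derived-allele counts are binomial in the
#' sampled alleles. `F = 0` means all populations share `p` exactly; between
#' two independently drawn populations the Hudson estimator then targets `F`
#' itself.
#'
#' Optionally, populations can be nested in regions: region-level
#' frequencies drift from the ancestral frequency with parameter `F`, and
#' populations drift from their region's frequency with `F_within`, so
#' between-region pairs are more differentiated than within-region pairs —
#' the structure that makes Fst vary across pairs as in real continental
#' samples.
#'
#' @param F Differentiation parameter in `[0, 1)` (between regions when
#'   `region_map` is given).
#' @param n_loci Number of loci (`>= 1`).
#' @param samples_per_pop Number of sampled alleles per population per locus.
#' @param n_pops Number of populations (labelled `pop1 ...`), default 2.
#' @param ancestral_freq Function drawing ancestral frequencies, taking the
#'   number of loci; default uniform on (0.05, 0.95).
#' @param pop_labels Optional population labels.
#' @param region_map Optional named character vector population -> region;
#'   enables the hierarchical model.
#' @param F_within Within-region drift parameter (used with `region_map`).
#' @param seed Optional integer seed.
#' @return A data frame with columns `locus`, `pop`, `derived_count`,
#'   `total`, plus an attribute `"monomorphic"`: logical per-locus flag, TRUE
#'   where every population is monomorphic.
#' @examples
#' x <- simulate_snp_counts(0.1, n_loci = 100, samples_per_pop = 50, seed = 1)
#' head(x)
#' @export
simulate_snp_counts <- function(F, n_loci, samples_per_pop = 100, n_pops = 2,
                                ancestral_freq = function(n) stats::runif(n, 0.05, 0.95),
                                pop_labels = NULL, region_map = NULL,
                                F_within = 0, seed = NULL) {
  if (!is.numeric(F) || length(F) != 1 || F < 0 || F >= 1)
    stop("'F' must lie in [0, 1)")
  if (F_within < 0 || F_within >= 1) stop("'F_within' must lie in [0, 1)")
  if (n_loci < 1) stop("'n_loci' must be >= 1")
  if (samples_per_pop < 2) stop("need at least 2 sampled alleles per population")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n_pops))
  stopifnot(length(pop_labels) == n_pops, !anyDuplicated(pop_labels))

  bn_draw <- function(p, Fd) {
    if (Fd == 0) return(p)
    # clip away exact 0/1 so the Beta parameters stay valid
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    stats::rbeta(length(p), p * (1 - Fd) / Fd, (1 - p) * (1 - Fd) / Fd)
  }

  p <- ancestral_freq(n_loci)
  counts <- matrix(0L, nrow = n_loci, ncol = n_pops)
  if (!is.null(region_map)) {
    miss <- setdiff(pop_labels, names(region_map))
    if (length(miss))
      stop("populations missing from 'region_map': ", paste(miss, collapse = ", "))
    region_freq <- lapply(unique(region_map[pop_labels]),
                          function(r) bn_draw(p, F))
    names(region_freq) <- unique(region_map[pop_labels])
    for (j in seq_len(n_pops)) {
      pj <- bn_draw(region_freq[[region_map[[pop_labels[j]]]]], F_within)
      counts[, j] <- stats::rbinom(n_loci, samples_per_pop, pj)
    }
  } else {
    for (j in seq_len(n_pops)) {
      pj <- bn_draw(p, F)
      counts[, j] <- stats::rbinom(n_loci, samples_per_pop, pj)
    }
  }
  mono <- apply(counts, 1, function(x)
    all(x == 0L) || all(x == samples_per_pop))
  out <- data.frame(
    locus = rep(seq_len(n_loci), times = n_pops),
    pop = rep(pop_labels, each = n_loci),
    derived_count = as.vector(counts),
    total = samples_per_pop,
    stringsAsFactors = FALSE
  )
  attr(out, "monomorphic") <- mono
  out
}
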