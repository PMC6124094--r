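# Coalescent genealogy simulation under a piecewise-linear demography.

# Solve for the time t >= t0 at which the pairwise intensity accumulated
# since t0, scaled by the combinatorial factor `comb` = k(k-1)/2 and 1/(g f),
# first reaches the exponential deviate E. Segment-by-segment analytic
# inversion; the constant tail guarantees termination.
.next_event_time <- function(d, t0, comb, g, f, E) {
  gf <- g * f
  knots <- d$times
  sizes <- d$sizes
  # walk finite segments after t0
  upper <- c(knots[knots > t0], Inf)
  a <- t0
  for (b in upper) {
    Na <- ne_at(d, a)
    if (is.finite(b)) {
      Nb <- ne_at(d, b)
      seg <- comb * .segment_integral(a, b, Na, Nb) / gf
      if (seg >= E) {
        s <- (Nb - Na) / (b - a)  # slope of Ne(t) on this segment
        if (abs(s) < 1e-12 * Na / (b - a + 1)) {
          return(a + E * gf * Na / comb)
        }
        return(a + (Na / s) * (exp(E * gf * s / comb) - 1))
      }
      E <- E - seg
      a <- b
    } else {
      # constant tail at the oldest size
      return(a + E * gf * Na / comb)
    }
  }
}

#' Simulate a coalescent genealogy under a piecewise-linear demography
#'
#' Draws an ultrametric genealogy of `n` present-day lineages under the
#' standard coalescent: with `k` lineages extant at time `t`, the hazard of
#' the next coalescence is \eqn{k(k-1)/2 \cdot 1/(g f N_e(t))}. Waiting
#' times are generated by analytic inversion of the accumulated intensity on
#' each linear segment of the demography, and the coalescing pair is chosen
#' uniformly. Branch lengths are in years.
#'
#' @param n Number of tips (`>= 2`).
#' @param d A [demography()] object.
#' @param g Generation time in years.
#' @param f Population factor (0.5 for mtDNA).
#' @param seed Optional integer seed; the draw is reproducible given it.
#' @param labels Optional character vector of tip labels (default
#'   `t1 ... tn`).
#' @return An [ape::read.tree()]-style `"phylo"` object, ultrametric with
#'   tips at age 0.
#' @examples
#' d <- demography(0, 5000)
#' tr <- sample_coalescent_tree(10, d, seed = 1)
#' @export
sample_coalescent_tree <- function(n, d, g = 25, f = 0.5, seed = NULL,
                                   labels = NULL) {
  stopifnot(inherits(d, "demography"))
  if (n < 2) stop("need at least 2 lineages")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (length(labels) != n || anyDuplicated(labels))
    stop("'labels' must be ", n, " unique names")

  node_str <- labels   # newick fragment per active lineage
  node_age <- rep(0, n)
  t <- 0
  k <- n
  while (k > 1) {
    comb <- k * (k - 1) / 2
    t <- .next_event_time(d, t, comb, g, f, stats::rexp(1))
    pair <- sample.int(k, 2)
    i <- min(pair); j <- max(pair)
    node_str[i] <- sprintf("(%s:%.10g,%s:%.10g)",
                           node_str[i], t - node_age[i],
                           node_str[j], t - node_age[j])
    node_age[i] <- t
    node_str <- node_str[-j]
    node_age <- node_age[-j]
    k <- k - 1
  }
  ape::read.tree(text = paste0(node_str, ";"))
}

# Coalescent event ages of an ultrametric tree, sorted ascending
# (youngest first), length n-1. Tiny negative ages (floating round-off in
# distance-built trees) are clamped to 0.
.event_times <- function(tree) {
  bt <- sort(unname(ape::branching.times(tree)))
  if (any(bt < -1e-6 * max(abs(bt)))) stop("tree has negative node ages")
  pmax(bt, 0)
}
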