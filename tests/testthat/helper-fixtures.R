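# Shared fixtures: small demographies, trees, and independent oracles.

const_demog <- function(ne = 5000) demography(0, ne)

expansion_demog <- function(ne0 = 10000, fold = 10, t_start = 40000)
  demography(c(0, t_start), c(ne0, ne0 / fold))

# Independent quadrature oracle for the coalescent log-likelihood.
loglik_by_quadrature <- function(tree, d, g = 25, f = 0.5) {
  ev <- sort(unname(ape::branching.times(tree)))
  bounds <- c(0, ev)
  n <- length(ev) + 1
  ll <- 0
  k <- n
  for (i in seq_along(ev)) {
    lam <- stats::integrate(function(t) 1 / (g * f * ne_at(d, t)),
                            bounds[i], bounds[i + 1], rel.tol = 1e-10,
                            subdivisions = 1000L, stop.on.error = FALSE)$value
    ll <- ll - k * (k - 1) / 2 * lam - log(g * f * ne_at(d, ev[i]))
    k <- k - 1
  }
  ll
}

# Brute-force HPD oracle: smallest-width window over all windows of
# round(n * prob) steps, ties toward the smaller lower endpoint.
hpd_brute <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  gap <- max(1, min(n - 1, round(n * prob)))
  best <- c(x[1], x[1 + gap])
  for (i in seq_len(n - gap)) {
    if (x[i + gap] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + gap])
  }
  best
}

# A tiny deterministic ultrametric 4-taxon tree for exact-recovery checks.
ultra4 <- function() ape::read.tree(text = "((A:1000,B:1000):2000,(C:2500,D:2500):500);")
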