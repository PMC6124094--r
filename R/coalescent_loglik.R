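#' Coalescent log-likelihood of a genealogy under a deterministic trajectory
#'
#' The standard coalescent density of an ultrametric genealogy given a
#' deterministic effective-size trajectory \eqn{N_e(t)}: over each
#' inter-event interval with `k` extant lineages the log-density accumulates
#' \eqn{-\binom{k}{2} \int dt/(g f N_e(t))}, and each coalescence at time
#' \eqn{t} contributes \eqn{-\log(g f N_e(t))}. All integrals are exact
#' closed forms on the linear segments of the trajectory.
#'
#' Scaling both the trajectory and all node times by a common factor `c`
#' changes the log-likelihood by `-(n-1) log(c)`, the usual change of
#' variables.
#'
#' @param tree Ultrametric `"phylo"` genealogy, branch lengths in years.
#' @param traj A [demography()] trajectory; must be positive everywhere.
#' @param g Generation time in years.
#' @param f Population factor.
#' @return The log-likelihood (a finite scalar for positive trajectories).
#' @export
coalescent_loglik <- function(tree, traj, g = 25, f = 0.5) {
  stopifnot(inherits(tree, "phylo"), inherits(traj, "demography"))
  if (any(traj$sizes <= 0)) stop("trajectory must be positive")
  ev <- .event_times(tree)
  n <- length(ev) + 1L
  bounds <- c(0, ev)
  k <- n:2                       # lineage count on each inter-event interval
  ll <- 0
  for (i in seq_along(ev)) {
    lam <- coalescent_intensity(traj, bounds[i], bounds[i + 1L], g = g, f = f)
    ll <- ll - k[i] * (k[i] - 1) / 2 * lam
  }
  ll - sum(log(g * f * ne_at(traj, ev)))
}
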