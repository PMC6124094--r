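# Skyline MCMC driver, run combining and posterior summaries.

#' Configuration for the skyline MCMC
#'
#' Defaults are a 1/100 scaling of the full-scale protocol (1e8 states
#' sampled every 1e4): a 1e6-state chain thinned every 100, two replicate
#' runs, a 10% burn-in fraction, and an effective-sample-size threshold of
#' 200 as the convergence gate.
#'
#' @param chain_length Number of MCMC states.
#' @param thin Sampling interval (states between retained samples).
#' @param g Generation time in years.
#' @param f Population factor (0.5 for mtDNA).
#' @param ne_bounds Support of the log-uniform prior on each segment size.
#' @param pois_mean Mean of the Poisson prior on the number of size-change
#'   points (default `log(2)`, placing half the prior mass on zero changes).
#' @param prior_only If `TRUE` the likelihood is switched off and the chain
#'   samples the prior (used for prior-recovery checks).
#' @param burn_in_fraction Fraction of samples discarded by
#'   [combine_traces()].
#' @param n_runs Number of replicate chains in pipeline use.
#' @param ess_threshold Convergence gate applied to designated traces.
#' @param proposal Proposal mixture weights and step sizes; widths are on
#'   the log-size scale.
#' @return A list of class `"skyline_config"`.
#' @export
skyline_config <- function(chain_length = 1e6, thin = 100, g = 25, f = 0.5,
                           ne_bounds = c(1, 1e9), pois_mean = log(2),
                           prior_only = FALSE, burn_in_fraction = 0.10,
                           n_runs = 2, ess_threshold = 200,
                           proposal = list(w_flip = 0.35, w_scale = 0.40,
                                           w_swap = 0.15, w_all = 0.10,
                                           flip_sd = 1.0, scale_width = 0.8,
                                           all_width = 0.4)) {
  stopifnot(chain_length > 0, thin >= 1, g > 0, f > 0,
            length(ne_bounds) == 2, ne_bounds[1] > 0,
            ne_bounds[2] > ne_bounds[1], pois_mean > 0,
            burn_in_fraction >= 0, burn_in_fraction < 1)
  structure(list(chain_length = chain_length, thin = thin, g = g, f = f,
                 ne_bounds = ne_bounds, pois_mean = pois_mean,
                 prior_only = prior_only, burn_in_fraction = burn_in_fraction,
                 n_runs = n_runs, ess_threshold = ess_threshold,
                 proposal = proposal),
            class = "skyline_config")
}

#' Skyline MCMC over piecewise-linear demographies on a fixed genealogy
#'
#' Samples a posterior over effective-size trajectories conditioned on a
#' point genealogy (a deliberate simplification of joint tree-and-demography
#' inference; see the package vignette). The demographic function is
#' piecewise linear with potential change points restricted to the
#' genealogy's coalescent event times, selected by binary indicators with a
#' Poisson prior on their count, and log-uniform priors on segment sizes.
#' Moves: reversible-jump indicator flips (with a trajectory-centred value
#' redraw), random-walk updates of single active sizes, sliding an active
#' change point to an adjacent event, and a joint shift of all active sizes.
#'
#' @param tree Ultrametric `"phylo"` genealogy, branch lengths in years.
#' @param config A [skyline_config()].
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @return An object of class `"skyline_posterior"`: traces (`state`,
#'   `loglik`, `logprior`, `n_changes`), the trajectory samples evaluated at
#'   the fixed knot-time grid (`grid_times`, starting at 0), proposal
#'   acceptance rates, and run metadata.
#' @export
skyline_mcmc <- function(tree, config = skyline_config(), seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "skyline_config"))
  if (config$chain_length < 100 * config$thin)
    stop("chain too short: need chain_length >= 100 * thin")
  if (!is.null(seed)) set.seed(seed)
  ev <- .event_times(tree)
  n_tips <- length(tree$tip.label)

  # init: constant-size maximum-likelihood start
  bounds <- c(0, ev)
  k <- n_tips:2
  tot <- sum(k * (k - 1) / 2 * diff(bounds))
  ne0 <- tot / (config$g * config$f * length(ev))
  ne0 <- min(max(ne0, config$ne_bounds[1] * 1.0001), config$ne_bounds[2] * 0.9999)
  v_init <- rep(log(ne0), length(ev) + 1)

  p <- config$proposal
  res <- .skyline_mcmc_cpp(ev, n_tips, config$g, config$f,
                           config$chain_length, as.integer(config$thin),
                           config$ne_bounds[1], config$ne_bounds[2],
                           config$pois_mean, config$prior_only,
                           p$w_flip, p$w_scale, p$w_swap, p$w_all,
                           p$flip_sd, p$scale_width, p$all_width, v_init)
  structure(list(
    samples = data.frame(state = res$state, loglik = res$loglik,
                         logprior = res$logprior, n_changes = res$n_changes),
    traj = res$traj,
    grid_times = c(0, ev),
    thin = config$thin, chain_length = config$chain_length,
    g = config$g, f = config$f, n_tips = n_tips,
    acceptance = res$acceptance,
    burned_in = FALSE),
    class = "skyline_posterior")
}

#' @export
print.skyline_posterior <- function(x, ...) {
  cat("Skyline posterior:", nrow(x$samples), "samples (thin", x$thin,
      if (x$burned_in) ", burn-in removed" else "", ")\n", sep = " ")
  cat("  n_changes: median", stats::median(x$samples$n_changes),
      " range", paste(range(x$samples$n_changes), collapse = "-"), "\n")
  invisible(x)
}

#' Combine replicate skyline runs after burn-in removal
#'
#' Removes the leading `burn_in_fraction` of samples from each run and
#' concatenates the remainder, the LogCombiner-style protocol used to pool
#' replicate chains after confirming they sample the same stationary
#' distribution.
#'
#' @param runs A list of `"skyline_posterior"` objects sharing a time grid
#'   and thinning (replicate chains on the same genealogy).
#' @param burn_in_fraction Fraction of each run's samples discarded
#'   (default 0.10).
#' @return A `"skyline_posterior"` with `burned_in = TRUE`.
#' @export
combine_traces <- function(runs, burn_in_fraction = 0.10) {
  if (inherits(runs, "skyline_posterior")) runs <- list(runs)
  stopifnot(length(runs) >= 1,
            all(vapply(runs, inherits, TRUE, "skyline_posterior")),
            burn_in_fraction >= 0, burn_in_fraction < 1)
  g0 <- runs[[1]]$grid_times
  for (r in runs) {
    if (length(r$grid_times) != length(g0) || any(r$grid_times != g0))
      stop("runs have mismatched time grids")
    if (r$thin != runs[[1]]$thin) stop("runs have mismatched thinning")
  }
  keep <- lapply(runs, function(r) {
    n <- nrow(r$samples)
    seq.int(floor(burn_in_fraction * n) + 1L, n)
  })
  out <- runs[[1]]
  out$samples <- do.call(rbind, Map(function(r, k) r$samples[k, , drop = FALSE],
                                    runs, keep))
  rownames(out$samples) <- NULL
  out$traj <- do.call(rbind, Map(function(r, k) r$traj[k, , drop = FALSE],
                                 runs, keep))
  out$acceptance <- Reduce(`+`, lapply(runs, `[[`, "acceptance")) / length(runs)
  out$burned_in <- TRUE
  out
}

#' Effective sample size of an MCMC trace
#'
#' Tracer-style estimator: \eqn{N / (1 + 2 \sum_k \rho_k)} with the sum of
#' sample autocorrelations truncated at the first lag where the estimate
#' drops below zero (initial-positive-sequence rule). A constant trace
#' returns `N` by convention, with a warning.
#'
#' @param trace Numeric vector, length `>= 10`, all finite.
#' @return The effective sample size (scalar).
#' @export
ess <- function(trace) {
  trace <- as.numeric(trace)
  if (length(trace) < 10) stop("trace too short (need >= 10 values)")
  if (anyNA(trace) || any(!is.finite(trace))) stop("trace contains non-finite values")
  n <- length(trace)
  if (stats::var(trace) == 0) {
    warning("constant trace: ESS reported as N by convention")
    return(n)
  }
  rho <- stats::acf(trace, lag.max = n - 1, plot = FALSE, demean = TRUE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' Highest posterior density interval (Chen-Shao sliding window)
#'
#' Smallest-width interval among windows of `round(N * prob)` steps over the
#' sorted samples, containing at least `prob` of the sample mass. Ties are
#' broken toward the interval with the smaller lower endpoint. Integer
#' samples yield integer endpoints.
#'
#' @param samples Nonempty numeric vector of posterior samples.
#' @param prob Target probability content, in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  if (!length(samples)) stop("empty sample")
  if (prob <= 0 || prob >= 1) stop("'prob' must be in (0, 1)")
  x <- sort(as.numeric(samples))
  n <- length(x)
  gap <- max(1L, min(n - 1L, round(n * prob)))
  w <- x[(1L + gap):n] - x[seq_len(n - gap)]
  i <- which.min(w)   # which.min takes the first minimum: smallest lower end
  c(x[i], x[i + gap])
}

#' Summarise a skyline posterior into a demographic profile
#'
#' Evaluates every sampled trajectory on an evenly spaced grid of
#' `n_points` times from 0 to the root age and reports the per-point median
#' and central 95% posterior bounds (2.5% and 97.5% quantiles) of
#' \eqn{N_e} — the profile unit that downstream similarity comparisons
#' consume.
#'
#' @param post A `"skyline_posterior"`.
#' @param n_points Number of grid points (first at time 0).
#' @return A `"demographic_profile"` data frame with columns `time`,
#'   `median`, `lower`, `upper`.
#' @export
extract_profile <- function(post, n_points = 100) {
  stopifnot(inherits(post, "skyline_posterior"), n_points >= 2)
  if (!nrow(post$samples)) stop("empty posterior")
  root <- max(post$grid_times)
  grid <- seq(0, root, length.out = n_points)
  vals <- apply(post$traj, 1, function(ne)
    stats::approx(post$grid_times, ne, xout = grid, rule = 2,
                  ties = "ordered")$y)
  qs <- apply(vals, 1, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  demographic_profile(grid, qs[1, ], qs[2, ], qs[3, ])
}
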