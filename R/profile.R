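# Demographic profiles and the lambda curve-similarity statistic.

#' Demographic profile (median trajectory with 95% posterior bounds)
#'
#' The summary unit that profile comparisons consume: ordered time points in
#' years before present with the posterior median effective size and 95%
#' central-posterior-density bounds. The history length `L` is the oldest
#' time point.
#'
#' @param time Nondecreasing times from 0 (years before present).
#' @param median,lower,upper Positive sizes with `lower <= median <= upper`.
#' @return A data frame of class `"demographic_profile"`.
#' @export
demographic_profile <- function(time, median, lower = median, upper = median) {
  stopifnot(length(time) >= 1, length(median) == length(time),
            length(lower) == length(time), length(upper) == length(time))
  if (time[1] != 0) stop("profiles must start at time 0")
  if (any(diff(time) < 0)) stop("times must be nondecreasing")
  if (any(median <= 0) || any(lower <= 0) || any(upper <= 0))
    stop("sizes must be positive")
  if (any(lower > median + 1e-9 * median) || any(median > upper + 1e-9 * upper))
    stop("need lower <= median <= upper")
  structure(data.frame(time = time, median = median, lower = lower,
                       upper = upper),
            class = c("demographic_profile", "data.frame"))
}

#' Profile of a known demography (for tests and synthetic truth)
#'
#' Evaluates a [demography()] on an even grid and wraps it as a degenerate
#' profile whose bounds equal the median.
#'
#' @param d A [demography()].
#' @param L History length in years (default: oldest knot, or 1e5 for a
#'   constant demography).
#' @param n_points Grid size.
#' @return A `"demographic_profile"`.
#' @export
profile_from_demography <- function(d, L = NULL, n_points = 101) {
  stopifnot(inherits(d, "demography"))
  if (is.null(L)) L <- if (length(d$times) > 1) max(d$times) else 1e5
  grid <- seq(0, L, length.out = n_points)
  m <- ne_at(d, grid)
  demographic_profile(grid, m, m, m)
}

#' History length of a profile
#' @param profile A `"demographic_profile"`.
#' @return The oldest time point, in years.
#' @export
profile_length <- function(profile) max(profile$time)

#' Interpolate a profile's median size at a time point
#'
#' Linear interpolation of the median track on the natural size scale
#' between the two immediately flanking profile points; exact at profile
#' points. Times outside `[0, L]` are a domain error — the similarity
#' statistic truncates to the shorter history, so extrapolation is never
#' needed.
#'
#' @param profile A `"demographic_profile"`.
#' @param t Time(s) in years before present, within `[0, L]`.
#' @param log_scale If `TRUE`, interpolate linearly in log size instead (a
#'   sensitivity switch; default off).
#' @return Interpolated size(s).
#' @export
interpolate_size <- function(profile, t, log_scale = FALSE) {
  stopifnot(inherits(profile, "demographic_profile"))
  L <- profile_length(profile)
  if (any(t < 0 | t > L)) stop("t outside the profile's history [0, ", L, "]")
  if (log_scale) {
    exp(stats::approx(profile$time, log(profile$median), xout = t,
                      ties = "ordered")$y)
  } else {
    stats::approx(profile$time, profile$median, xout = t, ties = "ordered")$y
  }
}

#' Lambda similarity between two demographic profiles
#'
#' The profile-distance statistic: with `L` the length of the shorter of
#' the two histories, both median tracks are interpolated at the 21 times
#' `i L / 20`, `i = 0..20`, and
#' \deqn{\lambda = \sum_{i=0}^{20} | \log s_1(iL/20) - \log s_2(iL/20) |}
#' (natural logarithm). Identical tracks give 0; constant profiles `c1`,
#' `c2` give `21 |log(c1/c2)|`. The statistic is symmetric, nonnegative,
#' invariant to rescaling both profiles' sizes by a common factor and to
#' rescaling both time axes by a common factor.
#'
#' @param p1,p2 `"demographic_profile"` objects.
#' @param log_scale Passed to [interpolate_size()].
#' @return The scalar lambda.
#' @export
lambda_similarity <- function(p1, p2, log_scale = FALSE) {
  L <- min(profile_length(p1), profile_length(p2))
  if (L <= 0) stop("profiles must have positive history length")
  grid <- (0:20) * L / 20
  s1 <- interpolate_size(p1, grid, log_scale = log_scale)
  s2 <- interpolate_size(p2, grid, log_scale = log_scale)
  if (any(s1 <= 0) || any(s2 <= 0)) stop("nonpositive interpolated size")
  sum(abs(log(s1) - log(s2)))
}

#' Pairwise lambda matrix over labelled profiles
#'
#' @param profiles Named list of `"demographic_profile"` objects (unique
#'   labels, `>= 2`).
#' @param log_scale Passed through to [lambda_similarity()].
#' @return A symmetric, zero-diagonal matrix of lambda values.
#' @export
lambda_matrix <- function(profiles, log_scale = FALSE) {
  if (length(profiles) < 2) stop("need at least 2 profiles")
  labs <- names(profiles)
  if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs)))
    stop("profiles must carry unique nonempty labels")
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    m[i, j] <- m[j, i] <- lambda_similarity(profiles[[i]], profiles[[j]],
                                            log_scale = log_scale)
  }
  m
}
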