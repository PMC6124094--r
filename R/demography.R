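#' Piecewise-linear demographic history
#'
#' A demographic history is the effective population size \eqn{N_e(t)} as a
#' function of time \eqn{t} in years before present, represented by ordered
#' knots and evaluated by linear interpolation on the natural size scale.
#' Beyond the oldest knot the trajectory is constant at the oldest size; the
#' first knot is required to sit at time 0 so the present-day size is always
#' defined.
#'
#' @param times Numeric vector of knot times in years before present,
#'   strictly increasing, first element 0.
#' @param sizes Numeric vector of effective sizes (haploid-equivalent
#'   individuals) at each knot; all positive and finite.
#'
#' @return An object of class `"demography"`: a list with elements `times`
#'   and `sizes`.
#' @examples
#' d <- demography(c(0, 40000), c(10000, 1000))   # 10-fold linear expansion
#' ne_at(d, c(0, 20000, 1e6))
#' @seealso [ne_at()], [coalescent_intensity()], [sample_coalescent_tree()]
#' @export
demography <- function(times, sizes) {
  if (length(times) != length(sizes) || length(times) < 1L)
    stop("'times' and 'sizes' must be equal-length, nonempty vectors")
  times <- as.numeric(times); sizes <- as.numeric(sizes)
  if (anyNA(times) || anyNA(sizes)) stop("knots must not contain NA")
  if (times[1L] != 0) stop("the first knot must be at time 0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("knot times must be strictly increasing")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("all Ne values must be finite and positive")
  structure(list(times = times, sizes = sizes), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("Piecewise-linear demography with", length(x$times), "knot(s)\n")
  print(data.frame(time_ybp = x$times, Ne = x$sizes), row.names = FALSE)
  invisible(x)
}

#' Evaluate a demographic history
#'
#' Returns \eqn{N_e(t)} by linear interpolation between flanking knots, and
#' constant extrapolation beyond the oldest knot.
#'
#' @param d A [demography()] object.
#' @param t Numeric vector of times in years before present; all `>= 0`.
#' @return Numeric vector of effective sizes, same length as `t`.
#' @export
ne_at <- function(d, t) {
  stopifnot(inherits(d, "demography"))
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0)) stop("evaluation times must be nonnegative")
  if (length(d$times) == 1L) return(rep(d$sizes, length(t)))
  stats::approx(d$times, d$sizes, xout = t, rule = 2)$y
}

# Decompose [t1, t2] at the demography's interior knots; returns a matrix
# with columns a, b, Na, Nb (segment endpoints and sizes). Each segment is
# linear in Ne.
.demog_segments <- function(d, t1, t2) {
  if (t2 <= t1) return(matrix(numeric(0), ncol = 4))
  cuts <- d$times[d$times > t1 & d$times < t2]
  bk <- c(t1, cuts, t2)
  a <- bk[-length(bk)]; b <- bk[-1L]
  cbind(a = a, b = b, Na = ne_at(d, a), Nb = ne_at(d, b))
}

# Exact pairwise-intensity integral of one linear-Ne segment:
# int_a^b dt / Ne(t) with Ne linear from Na to Nb. Stable near Na == Nb.
.segment_integral <- function(a, b, Na, Nb) {
  dt <- b - a
  dN <- Nb - Na
  out <- ifelse(abs(dN) < 1e-9 * pmax(Na, Nb),
                dt * 2 / (Na + Nb),
                dt * log(Nb / Na) / dN)
  out[dt == 0] <- 0
  out
}

#' Pairwise coalescent intensity over a time interval
#'
#' Computes \eqn{\int_{t_1}^{t_2} dt / (g f N_e(t))}, the expected number of
#' coalescences for a single pair of lineages between `t1` and `t2`, where
#' `g` is the generation time in years and `f` the population (ploidy /
#' inheritance) factor — 0.5 for maternally inherited haploid mtDNA, so the
#' reported trajectory stays on the unscaled \eqn{N_e} scale. Exact closed
#' form on each linear segment; additive over abutting intervals.
#'
#' @param d A [demography()] object.
#' @param t1,t2 Interval endpoints in years before present, `0 <= t1 <= t2`.
#' @param g Generation time in years (default 25).
#' @param f Population factor (default 0.5).
#' @return A nonnegative scalar intensity (dimensionless).
#' @export
coalescent_intensity <- function(d, t1, t2, g = 25, f = 0.5) {
  stopifnot(inherits(d, "demography"), g > 0, f > 0)
  if (t1 < 0 || t2 < t1) stop("need 0 <= t1 <= t2")
  if (t2 == t1) return(0)
  seg <- .demog_segments(d, t1, t2)
  sum(.segment_integral(seg[, "a"], seg[, "b"], seg[, "Na"], seg[, "Nb"])) / (g * f)
}
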