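test_that("profiles from a degenerate posterior are flat and well-shaped", {
  tr <- sample_coalescent_tree(5, const_demog(1000), seed = 71)
  post <- skyline_mcmc(tr, skyline_config(chain_length = 2e4, thin = 100), seed = 3)
  # overwrite with a constant-trajectory posterior: every sample Ne = 1234
  post$traj[] <- 1234
  pr <- extract_profile(post, n_points = 40)
  expect_equal(nrow(pr), 40)
  expect_equal(pr$time[1], 0)
  expect_equal(pr$median, rep(1234, 40))
  expect_equal(pr$lower, rep(1234, 40))
  expect_equal(pr$upper, rep(1234, 40))
  expect_true(all(pr$lower <= pr$median & pr$median <= pr$upper))

  # permutation of samples leaves the quantile summaries unchanged
  post2 <- skyline_mcmc(tr, skyline_config(chain_length = 5e4, thin = 100), seed = 4)
  p_a <- extract_profile(post2, 25)
  perm <- sample(nrow(post2$traj))
  post2$traj <- post2$traj[perm, , drop = FALSE]
  post2$samples <- post2$samples[perm, , drop = FALSE]
  p_b <- extract_profile(post2, 25)
  expect_equal(p_a, p_b)
})

test_that("interpolation is linear, exact at points, and domain-checked", {
  p <- demographic_profile(c(0, 1000), c(100, 200))
  expect_equal(interpolate_size(p, 500), 150)
  expect_equal(interpolate_size(p, 1000), 200)
  expect_equal(interpolate_size(p, 0), 100)
  expect_error(interpolate_size(p, 1001), "outside")
  expect_error(interpolate_size(p, -5), "outside")
})

test_that("lambda: identity, constant tracks, and the mixed hand-computed case", {
  p <- profile_from_demography(expansion_demog(), n_points = 41)
  expect_equal(lambda_similarity(p, p), 0)

  c1 <- profile_from_demography(const_demog(100), L = 30000)
  c2 <- profile_from_demography(const_demog(100 * exp(1)), L = 90000)
  expect_equal(lambda_similarity(c1, c2), 21, tolerance = 1e-10)
  expect_equal(lambda_similarity(c1, c1), 0)

  # p1 flat at 100 out to 20 ka; p2 declines 200 -> 100 over 10 ka; L = 10 ka
  pa <- demographic_profile(c(0, 20000), c(100, 100))
  pb <- demographic_profile(c(0, 10000), c(200, 100))
  s2 <- 200 - 100 * (0:20) / 20
  expect_equal(lambda_similarity(pa, pb), sum(abs(log(100) - log(s2))),
               tolerance = 1e-10)
  expect_equal(lambda_similarity(pa, pb), lambda_similarity(pb, pa))
})

test_that("lambda is invariant to joint size and joint time rescaling", {
  set.seed(72)
  for (r in 1:10) {
    t1 <- c(0, sort(runif(3, 1000, 50000)))
    t2 <- c(0, sort(runif(3, 1000, 70000)))
    p1 <- demographic_profile(t1, exp(runif(4, 4, 9)))
    p2 <- demographic_profile(t2, exp(runif(4, 4, 9)))
    base <- lambda_similarity(p1, p2)
    scl <- function(p, cs, ct) demographic_profile(p$time * ct, p$median * cs)
    expect_equal(lambda_similarity(scl(p1, 13.7, 1), scl(p2, 13.7, 1)), base,
                 tolerance = 1e-9)
    expect_equal(lambda_similarity(scl(p1, 1, 0.37), scl(p2, 1, 0.37)), base,
                 tolerance = 1e-9)
  }
})

test_that("lambda is a pseudometric on constant profiles", {
  set.seed(73)
  for (r in 1:100) {
    cs <- exp(runif(3, 0, 12))
    p <- lapply(cs, function(x) profile_from_demography(const_demog(x), L = 5e4))
    l12 <- lambda_similarity(p[[1]], p[[2]])
    l13 <- lambda_similarity(p[[1]], p[[3]])
    l23 <- lambda_similarity(p[[2]], p[[3]])
    expect_lte(l13, l12 + l23 + 1e-9)
    expect_gte(l12, 0)
  }
})

test_that("the lambda matrix is symmetric with the constant-profile entries", {
  c0 <- profile_from_demography(const_demog(500), L = 1e4)
  ce <- profile_from_demography(const_demog(500 * exp(1)), L = 2e4)
  ce2 <- profile_from_demography(const_demog(500 * exp(2)), L = 3e4)
  m <- lambda_matrix(list(a = c0, b = ce, c = ce2))
  expect_identical(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 3))
  expect_equal(unname(m["a", "b"]), 21, tolerance = 1e-9)
  expect_equal(unname(m["b", "c"]), 21, tolerance = 1e-9)
  expect_equal(unname(m["a", "c"]), 42, tolerance = 1e-9)
  expect_error(lambda_matrix(list(c0, ce)), "labels")
  two <- lambda_matrix(list(x = c0, y = c0))
  expect_equal(unname(two), matrix(0, 2, 2))
})
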