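test_that("the skyline chain is seed-deterministic and validates inputs", {
  tr <- sample_coalescent_tree(10, const_demog(3000), seed = 61)
  cfg <- skyline_config(chain_length = 2e4, thin = 100)
  p1 <- skyline_mcmc(tr, cfg, seed = 7)
  p2 <- skyline_mcmc(tr, cfg, seed = 7)
  expect_identical(p1$samples, p2$samples)
  expect_identical(p1$traj, p2$traj)
  expect_error(skyline_mcmc(tr, skyline_config(chain_length = 500, thin = 100)),
               "chain too short")
})

test_that("the recorded log-likelihood trace matches an independent recomputation", {
  tr <- sample_coalescent_tree(8, expansion_demog(), seed = 62)
  post <- skyline_mcmc(tr, skyline_config(chain_length = 2e4, thin = 200), seed = 8)
  for (i in c(1, 33, 66, 100)) {
    d <- demography(post$grid_times, post$traj[i, ])
    expect_equal(post$samples$loglik[i],
                 coalescent_loglik(tr, d, g = 25, f = 0.5), tolerance = 1e-8)
  }
})

test_that("with the likelihood off the change-point count follows its Poisson prior", {
  tr <- sample_coalescent_tree(20, const_demog(5000), seed = 63)
  cfg <- skyline_config(chain_length = 2e6, thin = 100, prior_only = TRUE)
  # prior-only chains mix K mainly through flips; weight them up so the
  # goodness-of-fit draws are effectively independent after subsampling
  cfg$proposal$w_flip <- 0.8
  cfg$proposal$w_scale <- 0.1
  cfg$proposal$w_swap <- 0.05
  cfg$proposal$w_all <- 0.05
  post <- skyline_mcmc(tr, cfg, seed = 9)
  ks <- post$samples$n_changes
  # chi-square GOF against Poisson(log 2), bins 0..2 plus tail; keep every
  # 10th retained sample (1000 iterations apart) to break autocorrelation
  ks <- ks[seq(1, length(ks), by = 10)]
  obs <- tabulate(factor(pmin(ks, 3), levels = 0:3), nbins = 4)
  pr <- c(dpois(0:2, log(2)), 1 - ppois(2, log(2)))
  gof <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("present-day size is recovered within a factor of two under constant truth", {
  ok <- 0
  n_rep <- 20
  for (i in seq_len(n_rep)) {
    tr <- sample_coalescent_tree(40, const_demog(5000), seed = 700 + i)
    post <- skyline_mcmc(tr, skyline_config(chain_length = 2e5, thin = 100),
                         seed = 800 + i)
    comb <- combine_traces(list(post), 0.10)
    med <- stats::median(comb$traj[, 1])
    if (med > 2500 && med < 10000) ok <- ok + 1
  }
  expect_gte(ok / n_rep, 0.9)
})

test_that("replicate chains sample the same stationary distribution", {
  tr <- sample_coalescent_tree(30, const_demog(5000), seed = 64)
  cfg <- skyline_config(chain_length = 3e5, thin = 100)
  r1 <- skyline_mcmc(tr, cfg, seed = 11)
  r2 <- skyline_mcmc(tr, cfg, seed = 12)
  drop_burn <- function(r) r$samples$loglik[-(1:300)]
  x1 <- drop_burn(r1); x2 <- drop_burn(r2)
  se_comb <- sqrt(var(x1) / ess(x1) + var(x2) / ess(x2))
  expect_lt(abs(mean(x1) - mean(x2)), 3 * se_comb)
})

test_that("combining runs removes burn-in and concatenates", {
  tr <- sample_coalescent_tree(6, const_demog(2000), seed = 65)
  cfg <- skyline_config(chain_length = 1e5, thin = 100)  # 1000 samples
  r1 <- skyline_mcmc(tr, cfg, seed = 13)
  expect_equal(nrow(combine_traces(list(r1), 0.10)$samples), 900)
  comb2 <- combine_traces(list(r1, r1), 0.10)
  expect_equal(nrow(comb2$samples), 1800)
  expect_true(comb2$burned_in)
  # convexity: combined mean lies between the two run means
  r2 <- skyline_mcmc(tr, cfg, seed = 14)
  m1 <- mean(combine_traces(list(r1), 0.1)$samples$loglik)
  m2 <- mean(combine_traces(list(r2), 0.1)$samples$loglik)
  mc <- mean(combine_traces(list(r1, r2), 0.1)$samples$loglik)
  expect_gte(mc, min(m1, m2) - 1e-12)
  expect_lte(mc, max(m1, m2) + 1e-12)
  # mismatched grids are refused
  other <- skyline_mcmc(sample_coalescent_tree(6, const_demog(2000), seed = 66),
                        cfg, seed = 15)
  expect_error(combine_traces(list(r1, other)), "mismatched time grids")
})

test_that("a ten-fold expansion leaves constancy outside the 95% HPD", {
  tr <- sample_coalescent_tree(40, expansion_demog(), seed = 2)
  cfg <- skyline_config(chain_length = 5e5, thin = 100)
  comb <- combine_traces(list(skyline_mcmc(tr, cfg, seed = 21),
                              skyline_mcmc(tr, cfg, seed = 22)), 0.10)
  h <- hpd_interval(comb$samples$n_changes, 0.95)
  expect_gte(h[1], 1)
})
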