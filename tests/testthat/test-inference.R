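test_that("hdi finds the narrowest interval", {
  set.seed(14)
  d <- rbeta(1e5, 2, 2)
  expect_equal(hdi(d, 0.95), c(0.094, 0.906), tolerance = 0.02)
  # symmetric unimodal: HDI ~ central interval
  g <- rnorm(5e4)
  expect_equal(hdi(g, 0.9), quantile(g, c(0.05, 0.95), names = FALSE),
               tolerance = 0.05)
  # evenly spaced draws: every width-0.95 window ties; the lowest is returned
  u <- seq(0, 1, length.out = 1001)
  h <- hdi(u, 0.95)
  expect_equal(h[1], 0)
  expect_equal(diff(h), 0.95, tolerance = 1e-3)
  expect_error(hdi(u, 1.2))
})

test_that("categorical KL matches the single-k identification thresholds", {
  kl <- mplearn:::kl_categorical
  u6 <- rep(1 / 6, 6)
  expect_equal(kl(u6, u6), 0)
  expect_equal(kl(c(0.75, rep(0.05, 5)), u6), 0.827, tolerance = 1e-3)
  expect_equal(kl(c(1, rep(0, 5)), u6), log(6))
})

test_that("histogram KL estimator recovers the Beta(2,2)-vs-uniform value", {
  set.seed(6)
  est <- mplearn:::kl_hist_vs_uniform(rbeta(1e5, 2, 2), c(0, 1))
  # analytic value: log 6 - 5/6... = 0.125 nats
  expect_equal(est, 0.125, tolerance = 0.02)
  # uniform sample has (near) zero divergence
  expect_lt(mplearn:::kl_hist_vs_uniform(runif(1e5), c(0, 1)), 0.01)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(15)
  good <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(rhat(good), 1.05)
  bad <- cbind(rnorm(2000), rnorm(2000) + 3)
  expect_gt(rhat(bad), 1.5)
})

test_that("mixture marginalization equals brute-force averaging", {
  set.seed(16)
  x <- gen_bernoulli(0.7, 10)
  y <- gen_bernoulli(0.5, 10)
  llk <- sapply(0:5, function(k)
    loglik_mpl(mpl_agent(k, 0.8, 0.9, 1.2), trial_data(x, y)))
  q <- c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1)
  expect_equal(mplearn:::logsumexp(log(q) + llk),
               log(sum(q * exp(llk))), tolerance = 1e-12)
})

test_that("an uninformative agent leaves the flat priors unchanged", {
  set.seed(17)
  x <- gen_bernoulli(0.7, 300)
  y <- simulate_mpl(mpl_agent(2, 0.5, 0.5, 0), x)$choices
  fit <- fit_individual_mpl(trial_data(x, y),
                            control = mcmc_control(chains = 2, iter = 1500,
                                                   warmup = 600))
  # random choices carry no information about memory, forgetting or recency
  expect_lt(kl_prior_posterior(fit, "k"), 0.25)
  expect_lt(kl_prior_posterior(fit, "A"), 0.25)
  expect_lt(kl_prior_posterior(fit, "rho"), 0.25)
  expect_gte(kl_prior_posterior(fit, "Arho"), 0)
})

test_that("a strongly exploiting pattern searcher has identifiable k", {
  set.seed(18)
  x <- gen_bernoulli(0.7, 300)
  y <- simulate_mpl(mpl_agent(1, 1, 1, 4), x)$choices
  fit <- fit_individual_mpl(trial_data(x, y),
                            control = mcmc_control(chains = 2, iter = 1500,
                                                   warmup = 600))
  expect_gt(fit$k_prob[2], 1 / 6)        # posterior P(k = 1) beats the prior
  expect_gt(kl_prior_posterior(fit, "k"), 0.827)
})

test_that("hierarchical MPL fit recovers a point-mass memory distribution", {
  set.seed(19)
  hy <- population_hyperparams(mu = c(2, 2, 0), tau = c(0.5, 0.5, 0.3),
                               Omega = diag(3), q = c(0, 1, 0, 0, 0, 0))
  coh <- gen_population_cohort(hy, n = 16, n_trials = 300)
  fit <- fit_hier_mpl(coh, control = mcmc_control(chains = 1, iter = 1500,
                                                  warmup = 750))
  expect_gt(mean(fit$draws$q[, 2]), 0.8)
  est <- coef(fit)
  expect_equal(unname(est["A"]), plogis(2), tolerance = 0.12)
  expect_equal(unname(est["theta"]), 1, tolerance = 0.35)
  # diagnostics exist for every population and participant parameter
  expect_true(all(is.finite(fit$diagnostics)))
  expect_gte(length(fit$diagnostics), 6 + 3 + 6 + 16 * 3)
})

test_that("PVL hierarchical fit recovers the decay product of k = 0 agents", {
  set.seed(20)
  coh <- make_mpl_cohort(12, mpl_agent(0, A = 0.9, rho = 0.7, theta = 2),
                         n_trials = 300)
  fit <- fit_hier_pvl(coh, control = mcmc_control(chains = 1, iter = 1200,
                                                  warmup = 600))
  expect_equal(unname(coef(fit)["A"]), 0.9 * 0.7, tolerance = 0.1)
})

test_that("WSLS hierarchical fit matches empirical stay/shift rates when frozen", {
  set.seed(22)
  ag <- wsls_agent(p_w1 = 0.8, p_l1 = 0.6, theta_w = 0, theta_l = 0)
  coh <- make_wsls_cohort(12, ag, n_trials = 200)
  # closed-form oracle: pooled stay-after-win and shift-after-loss frequencies
  stay <- shift <- c(0, 0)
  for (td in coh) {
    for (t in 2:td$n_trials) {
      win <- td$choices[t - 1] == td$outcomes[t - 1]
      if (win) stay <- stay + c(td$choices[t] == td$choices[t - 1], 1)
      else shift <- shift + c(td$choices[t] != td$choices[t - 1], 1)
    }
  }
  fit <- fit_hier_wsls(coh, control = mcmc_control(chains = 1, iter = 2500,
                                                   warmup = 1250))
  est <- coef(fit)
  expect_equal(unname(est["p_w1"]), stay[1] / stay[2], tolerance = 0.08)
  expect_equal(unname(est["p_l1"]), shift[1] / shift[2], tolerance = 0.08)
})

test_that("hierarchical smoke run returns a complete, bounded posterior", {
  set.seed(23)
  coh <- gen_population_cohort(example_population(), n = 5, n_trials = 40)
  fit <- fit_hier_mpl(coh, control = mcmc_control(chains = 1, iter = 200,
                                                  warmup = 100))
  expect_s3_class(fit, "hier_fit")
  expect_equal(nrow(fit$draws$mu), 100)
  expect_true(all(abs(rowSums(fit$draws$q) - 1) < 1e-8))
  expect_true(all(fit$draws$tau > 0))
  expect_true(all(abs(fit$draws$omega) < 1))
  expect_equal(dim(fit$k_prob), c(5L, 6L))
  expect_true(all(abs(rowSums(fit$k_prob) - 1) < 1e-8))
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("Population medians", out)))
})
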