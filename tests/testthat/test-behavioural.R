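test_that("mean response summarises majority-option choice frequencies", {
  coh <- list(trial_data(c(0, 1, 1, 0), c(1, 1, 1, 1), id = "a"),
              trial_data(c(1, 0, 1, 1), c(1, 1, 1, 1), id = "b"))
  mr <- mean_response(coh)
  expect_equal(mr$per_trial, rep(1, 4))
  expect_equal(mr$mean, 1)
  expect_error(mean_response(coh, c(1, 9)))

  # a probability-matching chooser sits near p
  set.seed(30)
  coh2 <- lapply(1:20, function(i)
    trial_data(gen_bernoulli(0.7, 300), gen_bernoulli(0.7, 300),
               id = as.character(i)))
  expect_equal(mean_response(coh2, c(201, 300))$mean, 0.7, tolerance = 0.02)
})

test_that("cross-correlation identifies strict stay/shift strategies", {
  set.seed(31)
  x <- gen_bernoulli(0.7, 300)
  wsls_y <- c(0L, x[-300])
  expect_equal(cross_correlation(trial_data(x, wsls_y)), 1)
  expect_equal(cross_correlation(trial_data(x, 1L - wsls_y)), -1)
  expect_error(cross_correlation(trial_data(x, wsls_y), window = c(1, 100)))

  # algebraic identity: (c + 1) / 2 is the fraction of stay-type predictions
  y <- gen_bernoulli(0.5, 300)
  cc <- cross_correlation(trial_data(x, y))
  frac <- mean(y[201:300] == x[200:299])
  expect_equal((cc + 1) / 2, frac)
})

test_that("recency grouping assigns lags and conserves trials", {
  td <- trial_data(c(0, 1, 1, 1), c(1, 1, 0, 1))
  g <- recency_group(td, c(1, 4))
  expect_equal(g$c[1:3], c(1L, 1L, 1L))  # lags 1, 2, 3 for trials 2, 3, 4
  expect_equal(g$s[1:3], c(1L, 0L, 1L))

  # all-majority outcomes: no 0 outcome ever, all groups empty
  g2 <- recency_group(trial_data(rep(1L, 10), rep(1L, 10)))
  expect_equal(sum(g2$c), 0L)

  # conservation: grouped trials + trials with no prior 0 = window length
  set.seed(32)
  for (rep in 1:10) {
    x <- gen_bernoulli(0.7, 100)
    td <- trial_data(x, gen_bernoulli(0.5, 100))
    g <- recency_group(td)
    first0 <- which(x == 0)[1]
    expect_equal(sum(g$c) + first0, 100L)
  }

  # mean per-lag counts on the standard task are about 16 per participant
  set.seed(33)
  cs <- replicate(200, {
    x <- gen_bernoulli(0.7, 100)
    g <- recency_group(trial_data(x, gen_bernoulli(0.5, 100)))
    mean(g$c[1:5])
  })
  expect_equal(mean(cs), 16.3, tolerance = 0.05)
})

test_that("the beta-binomial recency model recovers a flat response profile", {
  set.seed(34)
  # 30 synthetic participants choosing 1 with probability 0.6 at every lag
  coh <- lapply(1:30, function(i)
    trial_data(gen_bernoulli(0.7, 100), gen_bernoulli(0.6, 100),
               id = as.character(i)))
  fit <- fit_recency_model(coh, control = mcmc_control(chains = 1,
                                                       iter = 2000,
                                                       warmup = 1000))
  expect_equal(fit$summary$mean, rep(0.6, nrow(fit$summary)),
               tolerance = 0.05)
  expect_true(all(fit$summary$hdi_low < 0.6 & fit$summary$hdi_high > 0.6))
})

test_that("greedy k = 3 pattern searchers stall below trend at lag k + 1", {
  set.seed(35)
  ag <- mpl_agent(3, 1, 1, Inf)
  coh <- make_mpl_cohort(800, ag, n_trials = 300)
  pooled <- Reduce(function(a, b) {a$c <- a$c + b$c; a$s <- a$s + b$s; a},
                   lapply(coh, recency_group, trial_range = c(1, 100)))
  rate <- pooled$s / pooled$c
  # nonmonotonic recency signature: the otherwise increasing response curve
  # breaks at lag k + 1 = 4, falling below the trend of its neighbours
  expect_lt(rate[4], (rate[3] + rate[5]) / 2)
  # and before the history window clears the 0, responses rise with the lag
  expect_true(all(diff(rate[1:3]) > 0))
})

test_that("counterfactual overrides are pure and the optimal agent maximises", {
  hy <- example_population()
  set.seed(36)
  expected <- mplearn:::draw_population_params(hy, 50)
  set.seed(36)
  ce <- counterfactual_experiment(hy, "replication", n = 50, n_trials = 30)
  expect_equal(ce$params$A, expected$A)
  expect_equal(ce$params$k, expected$k)

  set.seed(37)
  opt <- counterfactual_experiment(hy, "optimal", n = 80, n_trials = 200)
  expect_true(all(opt$params$theta == Inf))
  expect_gt(opt$mean, 0.99)
  expect_error(counterfactual_experiment(hy, "no_such_thing"))
})
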