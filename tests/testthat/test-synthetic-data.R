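test_that("recovery agents are reproducible and flat-prior distributed", {
  set.seed(100)
  d1 <- gen_recovery_agents(5, n_trials = 40)
  set.seed(100)
  d2 <- gen_recovery_agents(5, n_trials = 40)
  expect_identical(d1$truth, d2$truth)
  expect_identical(lapply(d1$trials, `[[`, "choices"),
                   lapply(d2$trials, `[[`, "choices"))

  set.seed(101)
  big <- gen_recovery_agents(3000, n_trials = 1)
  # k uniform on {0..5}: each cell within 4 binomial SEs of 500
  counts <- tabulate(big$truth$k + 1L, 6)
  expect_true(all(abs(counts - 500) < 4 * sqrt(3000 * (1 / 6) * (5 / 6))))
  expect_true(all(big$truth$A >= 0 & big$truth$A <= 1))
  expect_true(all(big$truth$theta >= 0 & big$truth$theta <= 5))
  expect_lt(abs(mean(big$truth$theta) - 2.5), 0.15)
})

test_that("population cohorts respect the hierarchical law", {
  # degenerate population: everyone shares (almost) the same parameters
  hy <- population_hyperparams(mu = c(1, 1, 0), tau = rep(1e-6, 3),
                               Omega = diag(3), q = c(0, 0, 1, 0, 0, 0))
  set.seed(7)
  coh <- gen_population_cohort(hy, n = 10, n_trials = 20)
  expect_true(all(coh$truth$k == 2L))
  expect_lt(diff(range(coh$truth$A)), 1e-5)
  expect_lt(diff(range(coh$truth$theta)), 1e-5)

  # moments of the transformed draws match the t4 law: median = mu and
  # variance = Sigma * nu / (nu - 2) = 2 * tau^2 on the diagonal
  hy2 <- population_hyperparams(mu = c(1, -1, 0.5), tau = c(0.5, 0.3, 0.4),
                                Omega = diag(3), q = rep(1 / 6, 6))
  set.seed(8)
  coh2 <- gen_population_cohort(hy2, n = 20000, n_trials = 1)
  z <- cbind(qlogis(coh2$truth$A), qlogis(coh2$truth$rho),
             log(coh2$truth$theta))
  expect_equal(unname(apply(z, 2, median)), hy2$mu, tolerance = 0.05)
  expect_equal(unname(apply(z, 2, var)), 2 * hy2$tau^2, tolerance = 0.15)
  expect_true(all(coh2$truth$A > 0 & coh2$truth$A < 1))
  expect_true(all(coh2$truth$theta > 0))
})

test_that("cohorts can reuse supplied outcome sequences", {
  hy <- example_population()
  xs <- list(gen_repeating("01", 30), gen_repeating("0011", 30))
  set.seed(2)
  coh <- gen_population_cohort(hy, n = 4, n_trials = 30, outcomes = xs)
  expect_identical(coh$trials[[1]]$outcomes, xs[[1]])
  expect_identical(coh$trials[[3]]$outcomes, xs[[1]])  # recycled
  expect_identical(coh$trials[[4]]$outcomes, xs[[2]])
})

test_that("labelled datasets round-trip through the CSV sidecar format", {
  set.seed(33)
  d <- gen_recovery_agents(3, n_trials = 10)
  tf <- tempfile(fileext = ".csv"); sf <- tempfile(fileext = ".csv")
  write_labelled_dataset(d, tf, sf)
  back <- read_trials(tf)
  expect_identical(back, d$trials)
  truth <- read.csv(sf, colClasses = c(participant_id = "character"))
  expect_equal(truth$k, d$truth$k)
  expect_equal(truth$theta, d$truth$theta)
})
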