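test_that("utility credits exactly the option matching the outcome", {
  expect_equal(unname(outcome_utility(1)), c(0, 1))
  expect_equal(unname(outcome_utility(0)), c(1, 0))
  expect_equal(sum(outcome_utility(1)), 1)
  expect_error(outcome_utility(2), "0/1")
})

test_that("step-wise MPL replay reproduces the alternating-pattern worked example", {
  # suboptimal agent (k = 1, A = 0.9, rho = 0.9, theta = 0.3) on 0,1,0,1,...
  ag <- mpl_agent(k = 1, A = 0.9, rho = 0.9, theta = 0.3)
  x <- gen_repeating("01", 8)
  st <- mpl_state(1)
  p1 <- numeric(8)
  E10 <- E01 <- numeric(8)  # E_1^{eta=0} and E_0^{eta=1} before each trial
  for (t in 1:8) {
    p1[t] <- mpl_choice_prob(st, ag)
    E10[t] <- st$E[2L, 1L]
    E01[t] <- st$E[1L, 2L]
    st <- mpl_update(st, x[t], ag)
  }
  expect_equal(round(p1, 2), c(0.50, 0.50, 0.50, 0.57, 0.43, 0.61, 0.39, 0.65))
  # printed expected-utility entries along the same rows
  expect_equal(round(E10[5:8], 2), c(1.73, 1.56, 2.26, 2.03))
  expect_equal(round(E01[6:8], 2), c(1.73, 1.56, 2.26))

  # the fast replay agrees with the step-wise one exactly
  expect_equal(mpl_probs(ag, x)$probs, p1)
})

test_that("greedy no-decay agent masters the alternating pattern from trial 4", {
  ag <- mpl_agent(k = 1, A = 1, rho = 1, theta = Inf)
  x <- gen_repeating("01", 50)
  pr <- mpl_probs(ag, x)$probs
  # from t = 4 on the probability of the (alternating) correct outcome is 1
  expect_true(all(pr[seq(4, 50, 2)] == 1))  # even trials: outcome 1
  expect_true(all(pr[seq(5, 49, 2)] == 0))  # odd trials: outcome 0
  sim <- simulate_mpl(ag, x)
  expect_identical(sim$choices[4:50], x[4:50])
})

test_that("MPL with k = 0 is the PVL model with decay A*rho", {
  set.seed(31)
  for (rep in 1:20) {
    x <- gen_bernoulli(0.7, 120)
    y <- gen_bernoulli(0.5, 120)
    td <- trial_data(x, y)
    A <- runif(1); rho <- runif(1); theta <- runif(1, 0, 3)
    m <- mpl_agent(0, A, rho, theta)
    p <- pvl_agent(A * rho, theta)
    expect_equal(mpl_probs(m, x)$probs, mpl_probs(p, x)$probs,
                 tolerance = 1e-12)
    expect_equal(loglik_mpl(m, td), loglik_pvl(p, td), tolerance = 1e-12)
  }
})

test_that("the Aρ = 0 greedy limit is strict win-stay lose-shift", {
  set.seed(4)
  x <- gen_bernoulli(0.7, 300)
  sim <- simulate_mpl(mpl_agent(0, A = 0, rho = 1, theta = Inf), x)
  expect_identical(sim$choices[2:300], x[1:299])
  expect_equal(cross_correlation(trial_data(x, sim$choices)), 1)
})

test_that("with A = rho = 1 expected utilities are history-outcome counts", {
  set.seed(8)
  for (k in 0:3) {
    x <- gen_bernoulli(0.6, 150)
    E <- mpl_probs(mpl_agent(k, 1, 1, 1), x)$E
    expect_equal(E, count_oracle(x, k))
  }
})

test_that("MPL choice probabilities are proper and match the softmax", {
  st <- mpl_state(1)
  ag <- mpl_agent(1, 0.9, 0.9, 0.3)
  expect_equal(mpl_choice_prob(st, ag), 0.5)  # all-zero table
  st$E[2L, 1L] <- 0.9
  st$window <- 0L
  expect_equal(round(mpl_choice_prob(st, ag), 2), 0.57)
  st$E <- st$E[2:1, , drop = FALSE]  # flip: difference becomes -0.9
  expect_equal(round(mpl_choice_prob(st, ag), 2), 0.43)
  # ties under the greedy flag resolve to 0.5
  expect_equal(mpl_choice_prob(mpl_state(1), mpl_agent(1, 1, 1, Inf)), 0.5)
})

test_that("theta = 0 gives pure exploration everywhere", {
  set.seed(5)
  x <- gen_bernoulli(0.7, 100)
  sim <- simulate_mpl(mpl_agent(3, 0.5, 0.5, 0), x)
  expect_true(all(sim$probs == 0.5))
  td <- trial_data(x, sim$choices)
  expect_equal(loglik_mpl(mpl_agent(3, 0.5, 0.5, 0), td), 100 * log(0.5))
})

test_that("fast MPL log-likelihood matches the step-wise replay oracle", {
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(0:3, 1)
    ag <- mpl_agent(k, runif(1), runif(1), runif(1, 0, 4))
    x <- gen_bernoulli(0.7, 60)
    td <- trial_data(x, gen_bernoulli(0.5, 60))
    expect_equal(loglik_mpl(ag, td), loglik_replay_oracle(ag, td),
                 tolerance = 1e-10)
  }
})

test_that("WSLS choice probabilities follow the four stay/shift cases", {
  ag <- wsls_agent(p_w1 = 0.8, p_l1 = 0.6, theta_w = 0, theta_l = 0)
  st <- wsls_state(ag)
  expect_equal(wsls_choice_prob(st), 0.5)  # first trial
  # win on option 1 -> stay on 1 with p_w
  s1 <- wsls_update(st, outcome = 1, choice = 1, params = ag)
  expect_equal(wsls_choice_prob(s1), 0.8)
  # win on option 0 -> stay on 0, so P(choose 1) = 1 - p_w
  s2 <- wsls_update(st, outcome = 0, choice = 0, params = ag)
  expect_equal(wsls_choice_prob(s2), 1 - 0.8)
  # loss on option 0 -> shift to 1 with p_l
  s3 <- wsls_update(st, outcome = 1, choice = 0, params = ag)
  expect_equal(wsls_choice_prob(s3), 0.6)
  # loss on option 1 -> shift away from 1, P(choose 1) = 1 - p_l
  s4 <- wsls_update(st, outcome = 0, choice = 1, params = ag)
  expect_equal(wsls_choice_prob(s4), 1 - 0.6)
})

test_that("WSLS learning pulls stay/shift probabilities as specified", {
  ag <- wsls_agent(0.5, 0.5, theta_w = 0.2, theta_l = 0.2)
  st <- wsls_state(ag)
  win <- wsls_update(st, 1, 1, ag)
  expect_equal(win$p_w, 0.6)          # p_w + 0.2 * (1 - p_w)
  expect_equal(win$p_l, 0.4)          # (1 - 0.2) * p_l
  loss <- wsls_update(st, 0, 1, ag)
  expect_equal(loss$p_l, 0.6)
  expect_equal(loss$p_w, 0.4)
  # zero learning rates freeze the state
  frozen <- wsls_agent(0.7, 0.3, 0, 0)
  s <- wsls_state(frozen)
  for (t in 1:5) s <- wsls_update(s, rbinom(1, 1, 0.5), rbinom(1, 1, 0.5),
                                  frozen)
  expect_equal(c(s$p_w, s$p_l), c(0.7, 0.3))
})

test_that("fast WSLS likelihood and simulator agree with a step-wise replay", {
  set.seed(21)
  ag <- wsls_agent(0.7, 0.6, 0.15, 0.25)
  x <- gen_bernoulli(0.7, 80)
  y <- simulate_wsls(ag, x)$choices
  st <- wsls_state(ag)
  ll <- 0
  for (t in seq_along(x)) {
    p1 <- wsls_choice_prob(st)
    ll <- ll + log(if (y[t] == 1) p1 else 1 - p1)
    st <- wsls_update(st, x[t], y[t], ag)
  }
  expect_equal(loglik_wsls(ag, trial_data(x, y)), ll, tolerance = 1e-10)
})

test_that("choice probabilities stay in [0, 1] across random parameters", {
  set.seed(77)
  for (rep in 1:25) {
    k <- sample(0:5, 1)
    ag <- mpl_agent(k, runif(1), runif(1), runif(1, 0, 5))
    pr <- mpl_probs(ag, gen_bernoulli(0.7, 80))$probs
    expect_true(all(pr >= 0 & pr <= 1))
  }
})
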