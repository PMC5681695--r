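# Shared fixture builders (everything generated in code, seeded per test).

# cohort of MPL agents with identical parameters on fresh Bernoulli tasks
make_mpl_cohort <- function(n, params, n_trials = 100L, p = 0.7) {
  lapply(seq_len(n), function(i) {
    x <- gen_bernoulli(p, n_trials)
    trial_data(x, simulate_mpl(params, x)$choices, id = as.character(i))
  })
}

make_wsls_cohort <- function(n, params, n_trials = 100L, p = 0.7) {
  lapply(seq_len(n), function(i) {
    x <- gen_bernoulli(p, n_trials)
    trial_data(x, simulate_wsls(params, x)$choices, id = as.character(i))
  })
}

# brute-force counter oracle: with A = rho = 1 every E_j^eta entry must
# equal the number of trials where history eta was followed by outcome j
count_oracle <- function(x, k) {
  E <- matrix(0, 2L, 2L^k)
  if (length(x) > k) {
    for (t in (k + 1L):length(x)) {
      idx <- if (k == 0L) 1L
             else sum(x[(t - k):(t - 1L)] * 2L^(seq_len(k) - 1L)) + 1L
      E[x[t] + 1L, idx] <- E[x[t] + 1L, idx] + 1L
    }
  }
  E
}

# independent replay oracle for the MPL log-likelihood, built on the
# step-wise public API rather than the C++ path
loglik_replay_oracle <- function(params, td) {
  st <- mpl_state(params$k)
  ll <- 0
  for (t in seq_len(td$n_trials)) {
    p1 <- mpl_choice_prob(st, params)
    ll <- ll + log(if (td$choices[t] == 1) p1 else 1 - p1)
    st <- mpl_update(st, td$outcomes[t], params)
  }
  ll
}

quick_ctl <- function(iter = 600L, chains = 1L)
  mcmc_control(chains = chains, iter = iter, warmup = floor(iter / 2))
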