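#' Mean response of a cohort
#'
#' The mean response is the frequency of choosing the majority option
#' (option 1). Computed per trial across participants and per participant
#' across a trial range.
#'
#' @param cohort A list of [trial_data] objects (or a `"labelled_dataset"`).
#' @param trial_range Integer vector `c(first, last)` of 1-based trials;
#'   default: the whole task.
#' @return A list with `per_trial` (mean of y over participants at each
#'   trial in the range), `per_participant` (each participant's mean over
#'   the range) and `mean` (grand mean over participants).
#' @examples
#' set.seed(1)
#' coh <- gen_population_cohort(example_population(), 20, n_trials = 300)
#' mean_response(coh, c(201, 300))$mean
#' @export
mean_response <- function(cohort, trial_range = NULL) {
  cohort <- cohort_trials(cohort)
  T_len <- cohort[[1L]]$n_trials
  if (is.null(trial_range)) trial_range <- c(1L, T_len)
  stopifnot(length(trial_range) == 2L, trial_range[1L] >= 1L,
            trial_range[2L] <= T_len, trial_range[1L] <= trial_range[2L])
  rng <- trial_range[1L]:trial_range[2L]
  Y <- vapply(cohort, function(td) td$choices[rng], numeric(length(rng)))
  Y <- matrix(Y, nrow = length(rng))
  per_participant <- colMeans(Y)
  list(per_trial = rowMeans(Y), per_participant = per_participant,
       mean = mean(per_participant))
}

#' Win-stay/lose-shift cross-correlation
#'
#' The windowed mean of `[2x(t-1) - 1][2y(t) - 1]`, by default over trials
#' 201-300. A value of +1 means every prediction equals the previous
#' outcome (strict win-stay/lose-shift); -1 means strict win-shift/
#' lose-stay. `(c + 1) / 2` is exactly the fraction of predictions equal to
#' the previous outcome.
#'
#' @param data A [trial_data] object with outcomes and choices.
#' @param window Integer vector `c(first, last)`; `first` must be at least 2
#'   since the statistic references the previous outcome.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' x <- gen_repeating("01", 300)
#' y <- c(0L, x[-300])  # strict win-stay/lose-shift
#' cross_correlation(trial_data(x, y))
#' @export
cross_correlation <- function(data, window = c(201L, 300L)) {
  stopifnot(inherits(data, "trial_data"), !is.null(data$choices))
  stopifnot(length(window) == 2L, window[1L] >= 2L,
            window[2L] <= data$n_trials, window[1L] <= window[2L])
  t <- window[1L]:window[2L]
  mean((2 * data$outcomes[t - 1L] - 1) * (2 * data$choices[t] - 1))
}

#' Group trials by lag since the most recent minority outcome
#'
#' For the nonmonotonic recency analysis, each trial `t` in the range is
#' assigned lag `n` if trial `t - n` was the most recent trial with a 0
#' (minority) outcome. Trials before the first observed 0 outcome have no
#' defined lag and are excluded. Lags of `lag_cap` or more are pooled into
#' one open-ended group.
#'
#' @param data A [trial_data] object.
#' @param trial_range Integer `c(first, last)` range to analyse.
#' @param lag_cap Lags `>= lag_cap` are pooled (default 6, the "6+" group).
#' @return A data frame with one row per lag group: `lag` (`"1"` to `"5"`
#'   and `"6+"` by default), `c` (number of trials at that lag) and `s`
#'   (number of those trials where the participant chose 1).
#' @examples
#' recency_group(trial_data(c(0, 1, 1, 1), c(1, 1, 0, 1)), c(1, 4))
#' @export
recency_group <- function(data, trial_range = NULL, lag_cap = 6L) {
  stopifnot(inherits(data, "trial_data"), !is.null(data$choices),
            lag_cap >= 1L)
  if (is.null(trial_range)) trial_range <- c(1L, data$n_trials)
  stopifnot(trial_range[1L] >= 1L, trial_range[2L] <= data$n_trials)
  labs <- c(as.character(seq_len(lag_cap - 1L)), paste0(lag_cap, "+"))
  cc <- ss <- integer(lag_cap)
  last0 <- NA_integer_
  for (t in seq_len(trial_range[2L])) {
    if (t >= trial_range[1L] && !is.na(last0)) {
      n <- min(t - last0, lag_cap)
      if (t > last0) {
        cc[n] <- cc[n] + 1L
        ss[n] <- ss[n] + data$choices[t]
      }
    }
    if (data$outcomes[t] == 0L) last0 <- t
  }
  data.frame(lag = labs, c = cc, s = ss, stringsAsFactors = FALSE)
}

pool_recency <- function(cohort, trial_range = NULL, lag_cap = 6L) {
  cohort <- cohort_trials(cohort)
  lapply(cohort, recency_group, trial_range = trial_range, lag_cap = lag_cap)
}

#' Beta-binomial model of the recency-lag response profile
#'
#' For each lag `n`, each participant's count of majority choices `s_i^n`
#' out of `c_i^n` trials is modelled as Binomial(`c_i^n`, `pi_i^n`) with
#' `pi_i^n ~ Beta(a_n, b_n)` and weak Half-Cauchy(0, 100) priors on `a_n`
#' and `b_n`. The participant-level `pi` are marginalized analytically
#' (beta-binomial likelihood) and `(a_n, b_n)` are sampled by adaptive
#' random-walk Metropolis on the log scale, independently per lag. The
#' quantity of interest is the population mean response
#' `a_n / (a_n + b_n)` per lag, with 95% HDI.
#'
#' @param cohort A list of [trial_data] (or `"labelled_dataset"`).
#' @param trial_range,lag_cap Passed to [recency_group()].
#' @param control An [mcmc_control()] (a single chain is used per lag).
#' @return An object of class `"recency_fit"`: a data frame `summary` with
#'   columns `lag`, `mean`, `hdi_low`, `hdi_high`, `c_mean` (mean trials
#'   per participant at that lag), plus the posterior draws per lag.
#'   Lags observed in no participant are dropped with a warning.
#' @examples
#' set.seed(2)
#' coh <- gen_population_cohort(example_population(), 15, n_trials = 100)
#' fit <- fit_recency_model(coh, control = mcmc_control(chains = 1,
#'                                                      iter = 1000,
#'                                                      warmup = 500))
#' fit$summary
#' @export
fit_recency_model <- function(cohort, trial_range = NULL, lag_cap = 6L,
                              control = mcmc_control(chains = 1L,
                                                     iter = 4000L,
                                                     warmup = 2000L)) {
  groups <- pool_recency(cohort, trial_range, lag_cap)
  if (!is.null(control$seed)) set.seed(control$seed)
  labs <- groups[[1L]]$lag
  draws <- vector("list", length(labs))
  names(draws) <- labs
  keep_lag <- logical(length(labs))
  for (g in seq_along(labs)) {
    cc <- vapply(groups, function(df) df$c[g], 1L)
    ss <- vapply(groups, function(df) df$s[g], 1L)
    use <- cc > 0L
    if (!any(use)) {
      warning("lag ", labs[g], " observed in no participant; dropped",
              call. = FALSE)
      next
    }
    draws[[g]] <- sample_beta_binomial(cc[use], ss[use], control)
    keep_lag[g] <- TRUE
  }
  summ <- do.call(rbind, lapply(which(keep_lag), function(g) {
    mr <- draws[[g]][, "mean_response"]
    h <- hdi(mr, 0.95)
    data.frame(lag = labs[g], mean = mean(mr), hdi_low = h[1L],
               hdi_high = h[2L],
               c_mean = mean(vapply(groups, function(df) df$c[g], 1L)),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, draws = draws[keep_lag], lag_cap = lag_cap),
            class = "recency_fit")
}

# single-lag beta-binomial sampler; Half-Cauchy(0, 100) priors on a and b
sample_beta_binomial <- function(cc, ss, control) {
  logpost <- function(la, lb) {
    a <- exp(la); b <- exp(lb)
    sum(lbeta(a + ss, b + cc - ss) - lbeta(a, b)) +
      stats::dcauchy(a, 0, 100, log = TRUE) +
      stats::dcauchy(b, 0, 100, log = TRUE) +
      la + lb  # Jacobian of the log transform
  }
  la <- 0; lb <- 0
  lp <- logpost(la, lb)
  scale <- 0.5; acc <- 0L; batch <- 0L
  n_keep <- control$iter - control$warmup
  out <- matrix(NA_real_, n_keep, 3L,
                dimnames = list(NULL, c("a", "b", "mean_response")))
  for (it in seq_len(control$iter)) {
    lap <- la + scale * stats::rnorm(1)
    lbp <- lb + scale * stats::rnorm(1)
    lpp <- logpost(lap, lbp)
    if (log(stats::runif(1)) < lpp - lp) {
      la <- lap; lb <- lbp; lp <- lpp; acc <- acc + 1L
    }
    batch <- batch + 1L
    if (it <= control$warmup && batch == 50L) {
      scale <- min(max(scale * exp(acc / 50 - 0.3), 1e-3), 10)
      acc <- 0L; batch <- 0L
    }
    if (it > control$warmup) {
      a <- exp(la); b <- exp(lb)
      out[it - control$warmup, ] <- c(a, b, a / (a + b))
    }
  }
  out
}

#' @export
print.recency_fit <- function(x, ...) {
  cat("<recency_fit> posterior mean response by lag since last 0 outcome:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Counterfactual population simulation experiments
#'
#' Simulates cohorts of MPL agents whose parameters are drawn from a
#' population law (a [population_hyperparams] object or a fitted
#' hierarchical MPL model) with one behaviour switched off:
#'
#' * `"replication"`: no override -- a straight replication draw.
#' * `"no_pattern_search"`: `k := 0`.
#' * `"no_recency"`: `rho := 1`.
#' * `"no_exploration"`: `theta := Inf` (greedy choice).
#' * `"optimal"`: `k := 0`, `A := 1`, `rho := 1`, `theta := Inf`.
#' * `"p_sweep"`: replication draws across a grid of majority-outcome
#'   probabilities `p`.
#'
#' Overrides replace the drawn parameter deterministically and leave the
#' joint draw of the others untouched. Forgetting `A` is never overridden
#' except in the `"optimal"` scenario, on the rationale that forgetting is
#' not under strategic control.
#'
#' @param source A [population_hyperparams] or `"mpl_hier_fit"` object.
#' @param scenario Scenario name (see above).
#' @param n Number of simulated participants (per `p` value for
#'   `"p_sweep"`).
#' @param n_trials Trials per participant.
#' @param p Majority-outcome probability (scalar; for `"p_sweep"`, the grid
#'   of probabilities, default `seq(0.5, 1, 0.1)`).
#' @param summary_range Trial range for the summary mean response (default:
#'   the last 100 trials).
#' @return For ordinary scenarios, a list with the scenario name, the
#'   simulated `cohort`, the drawn `params`, the per-trial mean-response
#'   `curve` and `mean` over `summary_range`. For `"p_sweep"`, a data frame
#'   with one row per `p` (`p`, `mean`).
#' @examples
#' set.seed(3)
#' counterfactual_experiment(example_population(), "optimal", n = 50,
#'                           n_trials = 150)$mean
#' @export
counterfactual_experiment <- function(source, scenario, n = 1000L,
                                      n_trials = 300L, p = 0.7,
                                      summary_range = NULL) {
  scenarios <- c("replication", "no_pattern_search", "no_recency",
                 "no_exploration", "optimal", "p_sweep")
  if (!scenario %in% scenarios)
    stop("unknown scenario: ", scenario, call. = FALSE)
  if (is.null(summary_range))
    summary_range <- c(max(1L, n_trials - 99L), n_trials)

  if (scenario == "p_sweep") {
    if (identical(p, 0.7)) p <- seq(0.5, 1, 0.1)
    out <- lapply(p, function(pp)
      counterfactual_experiment(source, "replication", n, n_trials, pp,
                                summary_range)$mean)
    return(data.frame(p = p, mean = unlist(out)))
  }

  params <- posterior_population_draws(source, n)
  params <- switch(scenario,
    replication = params,
    no_pattern_search = transform(params, k = 0L),
    no_recency = transform(params, rho = 1),
    no_exploration = transform(params, theta = Inf),
    optimal = transform(params, k = 0L, A = 1, rho = 1, theta = Inf))

  cohort <- lapply(seq_len(n), function(i) {
    x <- gen_bernoulli(p, n_trials)
    ag <- mpl_agent(params$k[i], params$A[i], params$rho[i], params$theta[i])
    trial_data(x, simulate_mpl(ag, x)$choices, id = as.character(i))
  })
  mr <- mean_response(cohort, summary_range)
  full <- mean_response(cohort)
  list(scenario = scenario, cohort = cohort, params = params,
       curve = full$per_trial, mean = mr$mean, summary_range = summary_range)
}
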