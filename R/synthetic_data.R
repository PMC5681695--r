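#' Population distribution of MPL parameters
#'
#' The hierarchical MPL population law: memory length `k` follows a
#' categorical distribution `q` over `0..k_max`, and the transformed
#' continuous parameters (logit A, logit rho, log theta) follow a
#' multivariate Student-t distribution with 4 degrees of freedom, location
#' `mu` and scale matrix `Sigma = diag(tau) %*% Omega %*% diag(tau)`.
#'
#' @param mu Length-3 location of (logit A, logit rho, log theta).
#' @param tau Length-3 positive scale vector.
#' @param Omega 3 x 3 correlation matrix (symmetric positive definite, unit
#'   diagonal).
#' @param q Probability vector over `k = 0, 1, ..., length(q) - 1`; must sum
#'   to 1.
#' @return An object of class `"population_hyperparams"`.
#' @seealso [example_population()] for a ready-made parameterisation,
#'   [gen_population_cohort()] to simulate a cohort from it.
#' @export
population_hyperparams <- function(mu, tau, Omega, q) {
  stopifnot(length(mu) == 3L, length(tau) == 3L, all(tau > 0),
            is.matrix(Omega), all(dim(Omega) == 3L),
            max(abs(Omega - t(Omega))) < 1e-8,
            max(abs(diag(Omega) - 1)) < 1e-8,
            all(q >= 0), abs(sum(q) - 1) < 1e-8)
  ch <- tryCatch(chol(Omega), error = function(e) NULL)
  if (is.null(ch))
    stop("'Omega' must be positive definite", call. = FALSE)
  structure(list(mu = as.numeric(mu), tau = as.numeric(tau), Omega = Omega,
                 q = as.numeric(q) / sum(q), nu = 4),
            class = "population_hyperparams")
}

#' @export
print.population_hyperparams <- function(x, ...) {
  nat <- c(A = stats::plogis(x$mu[1L]), rho = stats::plogis(x$mu[2L]),
           theta = exp(x$mu[3L]))
  cat("<population_hyperparams> multivariate t4 over (logit A, logit rho, log theta)\n")
  cat("  mu (natural-scale medians):",
      paste(sprintf("%s = %.3g", names(nat), nat), collapse = ", "), "\n")
  cat("  tau:", paste(signif(x$tau, 3), collapse = ", "), "\n")
  cat("  q(k):", paste(signif(x$q, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Population hyperparameters matching published estimates for this task
#'
#' A plausible population law for young adults performing a 300-trial,
#' p = 0.7 probability learning task, centred on the population medians
#' A = 0.99, rho = 0.96, theta = 0.23 and the memory-length distribution
#' q = (0.15, 0.39, 0.45) over k = 0, 1, 2 that hierarchical MPL analyses
#' of such experiments report. Scales are chosen so that about half of the
#' simulated participants have theta between 0.15 and 0.37, and the
#' correlations reflect the reported negative association of theta with A
#' and rho.
#'
#' @return A [population_hyperparams] object with `k_max = 5`.
#' @examples
#' example_population()
#' @export
example_population <- function() {
  Omega <- matrix(c(1.00, 0.14, -0.50,
                    0.14, 1.00, -0.70,
                    -0.50, -0.70, 1.00), 3L, 3L)
  population_hyperparams(
    mu = c(stats::qlogis(0.99), stats::qlogis(0.96), log(0.23)),
    tau = c(0.8, 0.5, 0.6),
    Omega = Omega,
    q = c(0.15, 0.39, 0.44, 0.01, 0.005, 0.005))
}

# Draws from a d-dimensional Student-t with nu df, location mu, scale Sigma
# (chol factor passed as upper-triangular R with Sigma = R'R).
rmvt_chol <- function(n, mu, R, nu = 4) {
  d <- length(mu)
  z <- matrix(stats::rnorm(n * d), n, d) %*% R
  w <- sqrt(nu / stats::rchisq(n, df = nu))
  sweep(z * w, 2L, mu, "+")
}

draw_population_params <- function(hyper, n) {
  Sigma <- diag(hyper$tau) %*% hyper$Omega %*% diag(hyper$tau)
  z <- rmvt_chol(n, hyper$mu, chol(Sigma), nu = hyper$nu)
  data.frame(
    k = sample(seq_along(hyper$q) - 1L, n, replace = TRUE, prob = hyper$q),
    A = stats::plogis(z[, 1L]),
    rho = stats::plogis(z[, 2L]),
    theta = exp(z[, 3L]))
}

#' Synthetic labelled datasets of simulated MPL participants
#'
#' `gen_recovery_agents()` reproduces the parameter-recovery design: each
#' agent receives independent flat-prior parameters (`k` uniform on
#' `{0, ..., k_max}`, `A` and `rho` uniform on `[0, 1]`, `theta` uniform on
#' `[0, theta_max]`), a fresh Bernoulli(`p`) outcome sequence, and simulated
#' MPL choices. `gen_population_cohort()` instead draws parameters from a
#' hierarchical population law, emulating a replication cohort.
#'
#' Truth labels are returned beside (never inside) the trial data, so that
#' recovery analyses cannot leak them.
#'
#' @param n_agents,n Number of simulated participants.
#' @param n_trials Trials per participant (the standard task uses 300).
#' @param p Majority-outcome probability (standard task: 0.7).
#' @param k_max Largest memory length considered.
#' @param theta_max Upper bound of the flat prior on theta.
#' @return A list of class `"labelled_dataset"` with elements `trials`
#'   (list of [trial_data]), `truth` (data frame of true parameters,
#'   aligned 1:1 with `trials`) and `meta`.
#' @examples
#' set.seed(42)
#' d <- gen_recovery_agents(3, n_trials = 50)
#' d$truth
#' @export
gen_recovery_agents <- function(n_agents, n_trials = 300L, p = 0.7,
                                k_max = 5L, theta_max = 5) {
  stopifnot(n_agents >= 1L)
  truth <- data.frame(
    participant_id = as.character(seq_len(n_agents)),
    k = sample(0:k_max, n_agents, replace = TRUE),
    A = stats::runif(n_agents),
    rho = stats::runif(n_agents),
    theta = stats::runif(n_agents, 0, theta_max),
    stringsAsFactors = FALSE)
  trials <- lapply(seq_len(n_agents), function(i) {
    x <- gen_bernoulli(p, n_trials)
    ag <- mpl_agent(truth$k[i], truth$A[i], truth$rho[i], truth$theta[i])
    trial_data(x, simulate_mpl(ag, x)$choices, id = truth$participant_id[i])
  })
  structure(list(trials = trials, truth = truth,
                 meta = list(generator = "recovery", n_trials = n_trials,
                             p = p, k_max = k_max, theta_max = theta_max)),
            class = "labelled_dataset")
}

#' @rdname gen_recovery_agents
#' @param hyper A [population_hyperparams] object.
#' @param outcomes Optional list of pre-generated outcome sequences (one per
#'   participant, recycled if shorter), so that posterior-predictive runs can
#'   reuse the same x sequences real participants faced. Default: fresh
#'   Bernoulli(`p`) sequences.
#' @export
gen_population_cohort <- function(hyper, n, n_trials = 300L, p = 0.7,
                                  outcomes = NULL) {
  stopifnot(inherits(hyper, "population_hyperparams"), n >= 1L)
  truth <- draw_population_params(hyper, n)
  truth <- cbind(participant_id = as.character(seq_len(n)), truth,
                 stringsAsFactors = FALSE)
  trials <- lapply(seq_len(n), function(i) {
    x <- if (is.null(outcomes)) gen_bernoulli(p, n_trials)
         else check_binary(outcomes[[(i - 1L) %% length(outcomes) + 1L]],
                           "outcomes")
    ag <- mpl_agent(truth$k[i], truth$A[i], truth$rho[i], truth$theta[i])
    trial_data(x, simulate_mpl(ag, x)$choices, id = truth$participant_id[i])
  })
  structure(list(trials = trials, truth = truth,
                 meta = list(generator = "population", n_trials = n_trials,
                             p = p)),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf("<labelled_dataset> %d simulated participants x %d trials (%s)\n",
              length(x$trials), x$trials[[1L]]$n_trials, x$meta$generator))
  invisible(x)
}

#' @rdname gen_recovery_agents
#' @param dataset A `"labelled_dataset"`.
#' @param trials_path,truth_path Output CSV paths; the truth sidecar holds
#'   (participant_id, k, A, rho, theta) and is written separately from the
#'   trial file handed to inference.
#' @export
write_labelled_dataset <- function(dataset, trials_path, truth_path) {
  stopifnot(inherits(dataset, "labelled_dataset"))
  write_trials(dataset$trials, trials_path)
  utils::write.csv(dataset$truth, truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(trials = trials_path, truth = truth_path))
}
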