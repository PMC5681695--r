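#' MCMC settings
#'
#' Settings for the package's adaptive random-walk Metropolis-within-Gibbs
#' samplers. Proposal scales are tuned during warmup (in batches, towards an
#' acceptance rate of about 0.3) and held fixed afterwards.
#'
#' @param chains Number of independent chains.
#' @param iter Total iterations per chain (including warmup).
#' @param warmup Iterations discarded as warmup/adaptation.
#' @param seed Optional integer seed set once before sampling.
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 2L, iter = 2000L, warmup = floor(iter / 2),
                         seed = NULL) {
  stopifnot(chains >= 1L, iter > warmup, warmup >= 0L)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = seed),
            class = "mcmc_control")
}

# ---- small numerical helpers ----------------------------------------------

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Running-moment (Welford) accumulator for Haario-style adaptive Metropolis:
# during warmup the proposal covariance tracks 2.38^2/d times the sample
# covariance of the chain, with a global scale tuned towards ~0.3 acceptance.
amh_new <- function(d, scale0) {
  list(n = 0, mean = numeric(d), M2 = matrix(0, d, d),
       L = diag(scale0, d), lambda = 1)
}

amh_learn <- function(st, x) {
  st$n <- st$n + 1
  delta <- x - st$mean
  st$mean <- st$mean + delta / st$n
  st$M2 <- st$M2 + outer(delta, x - st$mean)
  st
}

amh_refresh <- function(st) {
  d <- length(st$mean)
  if (st$n > 2 * d + 10) {
    cov <- st$M2 / (st$n - 1) * (2.38^2 / d) + diag(1e-8, d)
    ch <- tryCatch(chol(cov), error = function(e) NULL)
    if (!is.null(ch)) st$L <- t(ch)
  }
  st
}

amh_propose <- function(st, x)
  x + st$lambda * drop(st$L %*% stats::rnorm(length(x)))

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

# log density of a multivariate t (nu df) at the rows of Z;
# R is the upper Cholesky factor of Sigma (Sigma = R'R)
dmvt_rows <- function(Z, mu, R, nu = 4) {
  d <- length(mu)
  W <- backsolve(R, t(Z) - mu, transpose = TRUE)
  m <- colSums(W * W)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi) -
    sum(log(diag(R))) - ((nu + d) / 2) * log1p(m / nu)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' @param draws A matrix of posterior draws with one column per chain (or a
#'   vector, treated as a single chain). Each chain is split in half, so the
#'   diagnostic is informative even for single-chain runs.
#' @return The split R-hat statistic (1 at perfect mixing; values above
#'   about 1.1 indicate non-convergence).
#' @export
rhat <- function(draws) {
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  half <- floor(n / 2)
  pieces <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Highest-density interval of a sample
#'
#' The narrowest interval containing the requested posterior mass. When
#' several windows tie in width (e.g. uniform draws) the lowest one is
#' returned.
#'
#' @param draws Numeric vector of posterior draws.
#' @param mass Probability mass to cover, in (0, 1). Default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hdi(rbeta(1e5, 2, 2))  # about [0.094, 0.906]
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(is.numeric(draws), length(draws) >= 2L,
            length(mass) == 1L, mass > 0, mass < 1)
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  if (m >= n) return(c(s[1L], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  # lowest window among (numerical) ties for the narrowest
  tol <- 1e-9 * max(diff(range(s)), 1)
  i <- which(widths <= min(widths) + tol)[1L]
  c(s[i], s[i + m - 1L])
}

# ---- individual flat-prior MPL fit ----------------------------------------

#' Individual Bayesian MPL fit under flat recovery priors
#'
#' Samples the posterior of a single agent's MPL parameters under the
#' recovery priors: `k` uniform on `{0, ..., k_max}`, `A` and `rho` uniform
#' on `[0, 1]`, `theta` uniform on `[0, theta_max]`. The discrete `k` is
#' marginalized out of the likelihood (the posterior is a mixture over `k`)
#' and its posterior probabilities are recovered from the normalized mixture
#' terms at each draw. Sampling uses an adaptive random-walk Metropolis
#' scheme on the natural scale.
#'
#' @param data A [trial_data] object with outcomes and choices.
#' @param k_max,theta_max Prior support bounds.
#' @param control An [mcmc_control()]; the production default mirrors the
#'   recovery study (4 chains of 3500 iterations, warmup 1000).
#' @return An object of class `"mpl_individual_fit"` with elements `draws`
#'   (pooled post-warmup draws of A, rho, theta and the product Arho),
#'   `k_prob` (posterior probabilities of each k), `diagnostics` (split
#'   R-hat per parameter), `converged`, and the prior description needed by
#'   [kl_prior_posterior()].
#' @examples
#' set.seed(7)
#' x <- gen_bernoulli(0.7, 100)
#' y <- simulate_mpl(mpl_agent(k = 0, A = 0.8, rho = 1, theta = 2), x)$choices
#' fit <- fit_individual_mpl(trial_data(x, y),
#'                           control = mcmc_control(chains = 2, iter = 600,
#'                                                  warmup = 200))
#' fit$k_prob
#' @export
fit_individual_mpl <- function(data, k_max = 5L, theta_max = 5,
                               control = mcmc_control(chains = 4L,
                                                      iter = 3500L,
                                                      warmup = 1000L)) {
  stopifnot(inherits(data, "trial_data"), !is.null(data$choices))
  if (!is.null(control$seed)) set.seed(control$seed)
  x <- data$outcomes; y <- data$choices
  nk <- k_max + 1L
  log_prior_k <- -log(nk)
  lower <- c(0, 0, 0); upper <- c(1, 1, theta_max)

  post_allk <- function(par) {
    if (any(par < lower) || any(par > upper)) return(NULL)
    cpp_mpl_loglik_allk(x, y, par[1L], par[2L], par[3L], k_max)
  }

  n_keep <- control$iter - control$warmup
  draws <- vector("list", control$chains)
  kprob_sum <- numeric(nk)
  for (ch in seq_len(control$chains)) {
    par <- c(stats::runif(2), stats::runif(1, 0, theta_max))
    llk <- post_allk(par)
    lp <- logsumexp(llk + log_prior_k)
    amh <- amh_new(3L, 0.1)
    acc <- 0L; n_rw <- 0L; batch <- 0L
    out <- matrix(NA_real_, n_keep, 4L,
                  dimnames = list(NULL, c("A", "rho", "theta", "Arho")))
    for (it in seq_len(control$iter)) {
      # mixture kernel: adaptive random walk, plus flat-prior independence
      # proposals that jump freely across likelihood plateaus
      rw <- stats::runif(1) < 0.5
      prop <- if (rw) amh_propose(amh, par)
              else c(stats::runif(2), stats::runif(1, 0, theta_max))
      llk_p <- post_allk(prop)
      if (!is.null(llk_p)) {
        lp_p <- logsumexp(llk_p + log_prior_k)
        # for the independence kernel the flat prior cancels in the ratio
        if (log(stats::runif(1)) < lp_p - lp) {
          par <- prop; llk <- llk_p; lp <- lp_p
          if (rw) acc <- acc + 1L
        }
      }
      if (rw) n_rw <- n_rw + 1L
      batch <- batch + 1L
      if (it <= control$warmup) {
        amh <- amh_learn(amh, par)
        if (batch == 50L) {
          if (n_rw > 0L)
            amh$lambda <-
              min(max(amh$lambda * exp(acc / n_rw - 0.3), 1e-3), 50)
          amh <- amh_refresh(amh)
          acc <- 0L; n_rw <- 0L; batch <- 0L
        }
      }
      if (it > control$warmup) {
        out[it - control$warmup, ] <- c(par, par[1L] * par[2L])
        w <- exp(llk - max(llk)); kprob_sum <- kprob_sum + w / sum(w)
      }
    }
    draws[[ch]] <- out
  }
  pooled <- do.call(rbind, draws)
  diag_rhat <- vapply(colnames(pooled), function(p)
    rhat(sapply(draws, function(d) d[, p])), numeric(1))
  structure(list(
    draws = pooled, chain_draws = draws,
    k_prob = kprob_sum / (control$chains * n_keep),
    diagnostics = diag_rhat,
    converged = all(diag_rhat <= 1.1, na.rm = TRUE),
    prior = list(k_max = k_max, theta_max = theta_max),
    control = control, model = "mpl_individual"),
    class = "mpl_individual_fit")
}

#' @export
print.mpl_individual_fit <- function(x, ...) {
  cat("<mpl_individual_fit> flat-prior posterior,",
      nrow(x$draws), "pooled draws\n")
  cat("  posterior medians:",
      paste(sprintf("%s = %.3f", c("A", "rho", "theta"),
                    apply(x$draws[, 1:3], 2L, stats::median)),
            collapse = ", "), "\n")
  cat("  P(k):", paste(sprintf("%.2f", x$k_prob), collapse = " "), "\n")
  if (!x$converged)
    cat("  WARNING: split R-hat above 1.1 for some parameter(s)\n")
  invisible(x)
}

#' Kullback-Leibler divergence from prior to posterior
#'
#' Measures how much was learned about one MPL parameter from a single
#' agent's data, as the KL divergence KL(posterior || prior) in nats. For
#' `k` this is the exact categorical divergence of the posterior
#' probabilities from the uniform prior. For the continuous parameters the
#' posterior is summarised by a fixed-width 50-bin histogram on the prior's
#' support with add-one smoothing, compared against the flat prior density.
#' Following the recovery analysis convention, report `A` and `rho`
#' separately when the agent searches for patterns, and their product
#' `"Arho"` when `k = 0` (with `k = 0` only the product is identified).
#'
#' @param samples An `"mpl_individual_fit"` object.
#' @param parameter One of `"A"`, `"rho"`, `"theta"`, `"Arho"`, `"k"`.
#' @param bins Number of histogram bins for continuous parameters.
#' @return Nonnegative divergence in nats.
#' @examples
#' # A point-mass posterior on one of six k values gives log(6) = 1.79 nats;
#' # the 0.75/0.05x5 posterior gives 0.827 nats (single-k identification
#' # thresholds).
#' @export
kl_prior_posterior <- function(samples, parameter, bins = 50L) {
  stopifnot(inherits(samples, "mpl_individual_fit"))
  if (parameter == "k") {
    p <- samples$k_prob
    return(kl_categorical(p, rep(1 / length(p), length(p))))
  }
  support <- switch(parameter,
    A = c(0, 1), rho = c(0, 1), Arho = c(0, 1),
    theta = c(0, samples$prior$theta_max),
    stop("unknown parameter: ", parameter, call. = FALSE))
  v <- samples$draws[, parameter]
  kl_hist_vs_uniform(v, support, bins)
}

# exact KL between two categorical distributions (terms with p = 0 vanish)
kl_categorical <- function(p, q) {
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

# histogram estimate of KL(sample distribution || uniform on support)
kl_hist_vs_uniform <- function(v, support, bins = 50L) {
  br <- seq(support[1L], support[2L], length.out = bins + 1L)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = bins)
  p <- (counts + 1) / (length(v) + bins)  # add-one smoothing
  sum(p * log(p * bins))
}

# ---- hierarchical fits -----------------------------------------------------

# Shared Metropolis-within-Gibbs engine for the three hierarchical models.
#
# Each participant has a d-vector z_i of transformed parameters following a
# multivariate t4(mu, Sigma = diag(tau) Omega diag(tau)) population law, with
# mu ~ Normal(0, mu_var), tau ~ Half-Normal(0, 1), Omega ~ LKJ(1) (i.e. flat
# over positive-definite correlation matrices). For the MPL model, the
# discrete k_i is marginalized out of the per-participant likelihood as a
# q-weighted mixture; q gets a Dirichlet(alpha) prior and is refreshed by a
# conjugate Gibbs step after sampling latent k_i from the per-draw mixture
# responsibilities.
#
# loglik_fn(i, z) returns the log-likelihood of participant i at transformed
# parameters z -- a vector over k = 0..k_max for the mixture model, a scalar
# otherwise.
run_hier_chain <- function(cohort, d, loglik_fn, mu_var, k_max, alpha,
                           control, chain_id) {
  N <- length(cohort)
  mixture <- !is.null(k_max)
  nk <- if (mixture) k_max + 1L else 0L

  # state
  Z <- matrix(stats::rnorm(N * d, 0, 0.5), N, d)
  mu <- rep(0, d); tau <- rep(0.5, d); Omega <- diag(d)
  q <- if (mixture) rep(1 / nk, nk) else NULL
  R <- chol(diag(tau) %*% Omega %*% diag(tau))
  off <- which(upper.tri(Omega))

  LL <- if (mixture) t(vapply(seq_len(N), function(i) loglik_fn(i, Z[i, ]),
                              numeric(nk)))
        else matrix(vapply(seq_len(N), function(i) loglik_fn(i, Z[i, ]),
                           numeric(1L)), ncol = 1L)
  mix_ll <- function(llv) if (mixture) logsumexp(log(q) + llv) else llv[1L]
  ll_i <- vapply(seq_len(N), function(i) mix_ll(LL[i, ]), numeric(1))
  pop_i <- dmvt_rows(Z, mu, R)

  # adaptation bookkeeping (per-participant adaptive-covariance proposals)
  amh <- lapply(seq_len(N), function(i) amh_new(d, 0.3))
  s_mu <- 0.3; s_tau <- 0.3; s_om <- 0.15
  acc <- list(z = numeric(N), mu = 0, tau = 0, om = 0)
  batch <- 0L

  n_keep <- control$iter - control$warmup
  keep <- list(
    mu = matrix(NA_real_, n_keep, d),
    tau = matrix(NA_real_, n_keep, d),
    omega = matrix(NA_real_, n_keep, length(off)),
    q = if (mixture) matrix(NA_real_, n_keep, nk) else NULL,
    z = array(NA_real_, c(n_keep, N, d)),
    k = if (mixture) matrix(NA_integer_, n_keep, N) else NULL)
  kprob_sum <- if (mixture) matrix(0, N, nk) else NULL

  for (it in seq_len(control$iter)) {
    # 1. per-participant transformed parameters
    for (i in seq_len(N)) {
      zp <- amh_propose(amh[[i]], Z[i, ])
      llp <- loglik_fn(i, zp)
      mlp <- mix_ll(llp)
      popp <- dmvt_rows(matrix(zp, 1L), mu, R)
      if (log(stats::runif(1)) < (mlp + popp) - (ll_i[i] + pop_i[i])) {
        Z[i, ] <- zp; LL[i, ] <- llp; ll_i[i] <- mlp; pop_i[i] <- popp
        acc$z[i] <- acc$z[i] + 1
      }
    }

    # 2. latent k and conjugate Dirichlet refresh of q
    if (mixture) {
      lw <- sweep(LL, 2L, -log(q), "-")  # log q_k + LL_ik
      ks <- integer(N)
      for (i in seq_len(N)) {
        w <- exp(lw[i, ] - max(lw[i, ]))
        ks[i] <- sample.int(nk, 1L, prob = w)
      }
      counts <- tabulate(ks, nbins = nk)
      q <- pmax(rdirichlet1(alpha + counts), 1e-300)
      ll_i <- vapply(seq_len(N), function(i) mix_ll(LL[i, ]), numeric(1))
    }

    # 3. population location mu
    mup <- mu + s_mu * stats::rnorm(d)
    popp <- dmvt_rows(Z, mup, R)
    dpr <- sum(stats::dnorm(mup, 0, sqrt(mu_var), log = TRUE)) -
           sum(stats::dnorm(mu, 0, sqrt(mu_var), log = TRUE))
    if (log(stats::runif(1)) < sum(popp) - sum(pop_i) + dpr) {
      mu <- mup; pop_i <- popp; acc$mu <- acc$mu + 1
    }

    # 4. population scales tau (log-scale walk; Half-Normal(0,1) prior)
    taup <- tau * exp(s_tau * stats::rnorm(d))
    Rp <- chol(diag(taup) %*% Omega %*% diag(taup))
    popp <- dmvt_rows(Z, mu, Rp)
    dpr <- sum(-taup^2 / 2 + log(taup)) - sum(-tau^2 / 2 + log(tau))
    if (log(stats::runif(1)) < sum(popp) - sum(pop_i) + dpr) {
      tau <- taup; R <- Rp; pop_i <- popp; acc$tau <- acc$tau + 1
    }

    # 5. correlation matrix Omega (walk on off-diagonals; LKJ(1) is flat)
    Op <- Omega
    Op[off] <- Omega[off] + s_om * stats::rnorm(length(off))
    Op[lower.tri(Op)] <- t(Op)[lower.tri(Op)]
    if (all(abs(Op[off]) < 1)) {
      Rp <- tryCatch(chol(diag(tau) %*% Op %*% diag(tau)),
                     error = function(e) NULL)
      if (!is.null(Rp)) {
        popp <- dmvt_rows(Z, mu, Rp)
        if (log(stats::runif(1)) < sum(popp) - sum(pop_i)) {
          Omega <- Op; R <- Rp; pop_i <- popp; acc$om <- acc$om + 1
        }
      }
    }

    # warmup adaptation in batches of 50
    batch <- batch + 1L
    if (it <= control$warmup) {
      for (i in seq_len(N)) amh[[i]] <- amh_learn(amh[[i]], Z[i, ])
      if (batch == 50L) {
        tune <- function(s, a) pmin(pmax(s * exp(a / 50 - 0.3), 1e-3), 10)
        for (i in seq_len(N)) {
          amh[[i]]$lambda <-
            min(max(amh[[i]]$lambda * exp(acc$z[i] / 50 - 0.3), 1e-3), 50)
          amh[[i]] <- amh_refresh(amh[[i]])
        }
        s_mu <- tune(s_mu, acc$mu)
        s_tau <- tune(s_tau, acc$tau); s_om <- tune(s_om, acc$om)
        acc <- list(z = numeric(N), mu = 0, tau = 0, om = 0)
        batch <- 0L
      }
    }

    if (it > control$warmup) {
      j <- it - control$warmup
      keep$mu[j, ] <- mu; keep$tau[j, ] <- tau; keep$omega[j, ] <- Omega[off]
      keep$z[j, , ] <- Z
      if (mixture) {
        keep$q[j, ] <- q
        keep$k[j, ] <- ks - 1L
        resp <- exp(sweep(lw, 1L, apply(lw, 1L, max), "-"))
        kprob_sum <- kprob_sum + resp / rowSums(resp)
      }
    }
  }
  list(keep = keep, kprob_sum = kprob_sum)
}

assemble_hier_fit <- function(chains_out, cohort, d, par_names, transforms,
                              k_max, control, model) {
  mixture <- !is.null(k_max)
  N <- length(cohort)
  n_keep <- control$iter - control$warmup

  # convergence: split R-hat across chains for population parameters and
  # each participant's transformed parameters
  pull <- function(extract) sapply(chains_out, extract)
  rh <- c()
  for (j in seq_len(d)) {
    rh[paste0("mu[", j, "]")] <- rhat(pull(function(c) c$keep$mu[, j]))
    rh[paste0("tau[", j, "]")] <- rhat(pull(function(c) c$keep$tau[, j]))
  }
  noff <- ncol(chains_out[[1L]]$keep$omega)
  for (j in seq_len(noff))
    rh[paste0("omega[", j, "]")] <- rhat(pull(function(c) c$keep$omega[, j]))
  if (mixture)
    for (j in seq_len(k_max + 1L))
      rh[paste0("q[", j - 1L, "]")] <- rhat(pull(function(c) c$keep$q[, j]))
  for (i in seq_len(N))
    for (j in seq_len(d))
      rh[paste0("z[", i, ",", j, "]")] <-
        rhat(pull(function(c) c$keep$z[, i, j]))

  pooled <- list(
    mu = do.call(rbind, lapply(chains_out, function(c) c$keep$mu)),
    tau = do.call(rbind, lapply(chains_out, function(c) c$keep$tau)),
    omega = do.call(rbind, lapply(chains_out, function(c) c$keep$omega)),
    q = if (mixture) do.call(rbind, lapply(chains_out,
                                           function(c) c$keep$q)) else NULL,
    z = do.call(abind_first, lapply(chains_out, function(c) c$keep$z)))
  kprob <- if (mixture) {
    s <- Reduce(`+`, lapply(chains_out, function(c) c$kprob_sum))
    s / (length(chains_out) * n_keep)
  } else NULL

  structure(list(
    model = model, draws = pooled, k_prob = kprob,
    diagnostics = rh, converged = all(rh <= 1.1, na.rm = TRUE),
    par_names = par_names, transforms = transforms, k_max = k_max,
    n_participants = N, control = control),
    class = c(paste0(model, "_hier_fit"), "hier_fit"))
}

abind_first <- function(...) {
  arrs <- list(...)
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1L], 1L)),
                           dim(arrs[[1L]])[2:3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Hierarchical Bayesian fits of the MPL, PVL and WSLS models
#'
#' Fits one of the three choice models to a cohort of participants under a
#' hierarchical population law: each participant's transformed parameters
#' follow a multivariate Student-t distribution with 4 degrees of freedom,
#' location `mu` (Normal(0, 1e4) prior for MPL/PVL, Normal(0, 25) for WSLS)
#' and scale `Sigma = diag(tau) Omega diag(tau)` with `tau` Half-Normal(0,1)
#' and `Omega` LKJ(1). For the MPL model the memory length `k` additionally
#' follows a categorical law `q` with a Dirichlet(0.001) prior; `k` is
#' marginalized out of each participant's likelihood (computed in log space
#' as a q-weighted mixture over `k = 0..k_max`) and per-participant
#' posterior probabilities P(k_i = k) are recovered from the normalized
#' mixture terms at each draw.
#'
#' Sampling uses the package's adaptive Metropolis-within-Gibbs engine.
#' Non-convergence (any split R-hat above 1.1) flags the result but never
#' discards or reruns it.
#'
#' @param cohort A list of [trial_data] objects sharing a task length (or a
#'   `"labelled_dataset"`, whose trials are used).
#' @param k_max Largest memory length in the MPL mixture.
#' @param control An [mcmc_control()]. The defaults are desk-scale; for
#'   production-quality posteriors increase `iter` by one to two orders of
#'   magnitude.
#' @return An object of class `c("<model>_hier_fit", "hier_fit")` with
#'   pooled posterior `draws` (population `mu`, `tau`, `omega`
#'   off-diagonals, `q`, and per-participant transformed parameters `z`),
#'   per-participant `k_prob` (MPL only), split R-hat `diagnostics` and a
#'   `converged` flag.
#' @examples
#' set.seed(11)
#' coh <- gen_population_cohort(example_population(), n = 6, n_trials = 60)
#' fit <- fit_hier_mpl(coh, control = mcmc_control(chains = 1, iter = 200,
#'                                                 warmup = 100))
#' summary(fit)
#' @export
fit_hier_mpl <- function(cohort, k_max = 5L,
                         control = mcmc_control(chains = 2L, iter = 2000L,
                                                warmup = 1000L)) {
  cohort <- cohort_trials(cohort)
  if (!is.null(control$seed)) set.seed(control$seed)
  loglik_fn <- function(i, z)
    cpp_mpl_loglik_allk(cohort[[i]]$outcomes, cohort[[i]]$choices,
                        stats::plogis(z[1L]), stats::plogis(z[2L]),
                        exp(z[3L]), k_max)
  chains_out <- lapply(seq_len(control$chains), function(ch)
    run_hier_chain(cohort, 3L, loglik_fn, mu_var = 1e4, k_max = k_max,
                   alpha = rep(0.001, k_max + 1L), control = control,
                   chain_id = ch))
  assemble_hier_fit(chains_out, cohort, 3L,
                    par_names = c("A", "rho", "theta"),
                    transforms = c("logit", "logit", "log"),
                    k_max = k_max, control = control, model = "mpl")
}

#' @rdname fit_hier_mpl
#' @export
fit_hier_pvl <- function(cohort,
                         control = mcmc_control(chains = 2L, iter = 2000L,
                                                warmup = 1000L)) {
  cohort <- cohort_trials(cohort)
  if (!is.null(control$seed)) set.seed(control$seed)
  loglik_fn <- function(i, z)
    cpp_mpl_loglik(cohort[[i]]$outcomes, cohort[[i]]$choices, 0L,
                   stats::plogis(z[1L]), 1, exp(z[2L]))
  chains_out <- lapply(seq_len(control$chains), function(ch)
    run_hier_chain(cohort, 2L, loglik_fn, mu_var = 1e4, k_max = NULL,
                   alpha = NULL, control = control, chain_id = ch))
  assemble_hier_fit(chains_out, cohort, 2L,
                    par_names = c("A", "theta"),
                    transforms = c("logit", "log"),
                    k_max = NULL, control = control, model = "pvl")
}

#' @rdname fit_hier_mpl
#' @export
fit_hier_wsls <- function(cohort,
                          control = mcmc_control(chains = 2L, iter = 2000L,
                                                 warmup = 1000L)) {
  cohort <- cohort_trials(cohort)
  if (!is.null(control$seed)) set.seed(control$seed)
  loglik_fn <- function(i, z)
    cpp_wsls_loglik(cohort[[i]]$outcomes, cohort[[i]]$choices,
                    stats::plogis(z[1L]), stats::plogis(z[2L]),
                    stats::plogis(z[3L]), stats::plogis(z[4L]))
  chains_out <- lapply(seq_len(control$chains), function(ch)
    run_hier_chain(cohort, 4L, loglik_fn, mu_var = 25, k_max = NULL,
                   alpha = NULL, control = control, chain_id = ch))
  assemble_hier_fit(chains_out, cohort, 4L,
                    par_names = c("p_w1", "p_l1", "theta_w", "theta_l"),
                    transforms = rep("logit", 4L),
                    k_max = NULL, control = control, model = "wsls")
}

cohort_trials <- function(cohort) {
  if (inherits(cohort, "labelled_dataset")) cohort <- cohort$trials
  cohort <- as_cohort(cohort)
  lens <- vapply(cohort, function(td) td$n_trials, 1L)
  if (length(unique(lens)) != 1L)
    stop("all participants must share the same task length", call. = FALSE)
  for (td in cohort)
    if (is.null(td$choices))
      stop("participant ", td$id, " has no choices", call. = FALSE)
  cohort
}

back_transform <- function(v, transform) {
  switch(transform, logit = stats::plogis(v), log = exp(v),
         stop("unknown transform"))
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> hierarchical %s model, %d participants, %d draws\n",
              toupper(x$model), x$n_participants, nrow(x$draws$mu)))
  print(coef(x))
  if (!is.null(x$k_prob))
    cat("  posterior mean q:",
        paste(sprintf("%.2f", colMeans(x$draws$q)), collapse = " "), "\n")
  if (!x$converged)
    cat("  WARNING: split R-hat above 1.1 for some parameter(s)\n")
  invisible(x)
}

#' @export
coef.hier_fit <- function(object, ...) {
  med <- apply(object$draws$mu, 2L, stats::median)
  out <- mapply(back_transform, med, object$transforms)
  names(out) <- object$par_names
  out
}

#' @export
summary.hier_fit <- function(object, mass = 0.95, ...) {
  med <- apply(object$draws$mu, 2L, stats::median)
  tab <- data.frame(
    parameter = object$par_names,
    median = mapply(back_transform, med, object$transforms),
    hdi_low = NA_real_, hdi_high = NA_real_)
  for (j in seq_along(object$par_names)) {
    h <- hdi(object$draws$mu[, j], mass)
    tab$hdi_low[j] <- back_transform(h[1L], object$transforms[j])
    tab$hdi_high[j] <- back_transform(h[2L], object$transforms[j])
  }
  res <- list(population = tab,
              q = if (!is.null(object$draws$q)) colMeans(object$draws$q),
              converged = object$converged,
              max_rhat = max(object$diagnostics, na.rm = TRUE))
  class(res) <- "summary.hier_fit"
  res
}

#' @export
print.summary.hier_fit <- function(x, ...) {
  cat("Population medians (back-transformed mu) with HDIs:\n")
  print(x$population, row.names = FALSE, digits = 3)
  if (!is.null(x$q))
    cat("Posterior mean q(k):", paste(sprintf("%.3f", x$q), collapse = " "),
        "\n")
  cat(sprintf("Max split R-hat: %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Draw agent parameter sets from a fitted population
#'
#' Generates random `(k, A, rho, theta)` vectors from the population law
#' encoded either in posterior draws of a hierarchical MPL fit (a new
#' hyperparameter draw is selected for each vector) or in a fixed
#' [population_hyperparams] object.
#'
#' @param source A `"mpl_hier_fit"` or [population_hyperparams] object.
#' @param n Number of parameter vectors.
#' @return A data frame with columns `k`, `A`, `rho`, `theta`.
#' @export
posterior_population_draws <- function(source, n) {
  if (inherits(source, "population_hyperparams"))
    return(draw_population_params(source, n))
  stopifnot(inherits(source, "hier_fit"), source$model == "mpl")
  nd <- nrow(source$draws$mu)
  idx <- sample.int(nd, n, replace = TRUE)
  out <- data.frame(k = integer(n), A = numeric(n), rho = numeric(n),
                    theta = numeric(n))
  d <- ncol(source$draws$mu)
  Om <- diag(d)
  off <- which(upper.tri(Om))
  for (j in seq_len(n)) {
    s <- idx[j]
    Om[off] <- source$draws$omega[s, ]
    Om[lower.tri(Om)] <- t(Om)[lower.tri(Om)]
    tau <- source$draws$tau[s, ]
    R <- chol(diag(tau) %*% Om %*% diag(tau))
    z <- rmvt_chol(1L, source$draws$mu[s, ], R)
    out$k[j] <- sample.int(source$k_max + 1L, 1L,
                           prob = source$draws$q[s, ]) - 1L
    out$A[j] <- stats::plogis(z[1L])
    out$rho[j] <- stats::plogis(z[2L])
    out$theta[j] <- exp(z[3L])
  }
  out
}
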